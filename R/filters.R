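# Acquisition-chain filtering for synthetic traces.
#
# Two stages mirror the recording hardware: a first-order series-RC smoothing
# (series resistance x membrane capacitance) and an n-pole low-pass Bessel
# filter. Both have exactly unity DC gain and are applied from rest relative
# to the first sample, so a constant trace passes through unchanged.

# Reverse Bessel polynomial coefficients, ascending powers.
# theta_0 = 1; theta_1 = s + 1; theta_n = (2n-1) theta_{n-1} + s^2 theta_{n-2}
reverse_bessel_poly <- function(n) {
  if (n == 0) return(1)
  th_prev <- 1           # theta_0
  th <- c(1, 1)          # theta_1
  if (n >= 2) for (k in 2:n) {
    a <- (2 * k - 1) * th
    b <- c(0, 0, th_prev)
    len <- max(length(a), length(b))
    th_new <- c(a, rep(0, len - length(a))) + c(b, rep(0, len - length(b)))
    th_prev <- th
    th <- th_new
  }
  th
}

# -3 dB frequency (rad/s) of the unity-DC analog prototype H(s) = theta(0)/theta(s)
bessel_w3db <- function(coefs) {
  h2 <- function(w) {
    s <- 1i * w
    num <- coefs[1]
    den <- sum(coefs * s^(seq_along(coefs) - 1))
    Mod(num / den)^2
  }
  stats::uniroot(function(w) h2(w) - 0.5, c(1e-3, 100), tol = 1e-12)$root
}

# Digital Bessel low-pass as an Arma filter (b, a), unity DC gain,
# bilinear transform with cutoff prewarping.
bessel_lowpass_coef <- function(cutoff_kHz, dt_ms, order = 4L) {
  coefs <- reverse_bessel_poly(order)
  poles <- polyroot(coefs)                      # prototype poles (rad/s scale)
  w3 <- bessel_w3db(coefs)
  Tsamp <- dt_ms * 1e-3                         # s
  wc <- 2 * pi * cutoff_kHz * 1e3               # rad/s target
  wc_warp <- (2 / Tsamp) * tan(wc * Tsamp / 2)  # prewarp so -3 dB lands on cutoff
  if (wc * Tsamp >= pi)
    stop_pc("filter cutoff %g kHz is at or above Nyquist for dt = %g ms",
            cutoff_kHz, dt_ms)
  sp <- poles * (wc_warp / w3)
  zpg <- signal::bilinear(Sz = numeric(0), Sp = sp, Sg = abs(prod(sp)), T = Tsamp)
  arma <- signal::as.Arma(zpg)
  b <- Re(arma$b); a <- Re(arma$a)
  b <- b * (sum(a) / sum(b))                    # pin DC gain to exactly 1
  list(b = b, a = a)
}

# Apply a (b, a) digital filter from rest relative to the first sample, so
# DC is preserved exactly.
apply_ba <- function(x, ba) {
  x0 <- x[1]
  y <- signal::filter(ba$b, ba$a, x - x0)
  as.numeric(y) + x0
}

# First-order RC smoothing, exact zero-order-hold discretization.
apply_series_rc <- function(x, tau_ms, dt_ms) {
  if (tau_ms <= 0) return(x)
  al <- exp(-dt_ms / tau_ms)
  apply_ba(x, list(b = 1 - al, a = c(1, -al)))
}

# Full acquisition chain per a noise_filter_spec (filtering only; noise is
# injected by the generators before this call chain).
apply_acquisition_chain <- function(x, nf, dt_ms) {
  tau <- rc_tau_ms(nf)
  if (tau > 0) x <- apply_series_rc(x, tau, dt_ms)
  if (!is.null(nf$filter_cutoff_kHz)) {
    ba <- bessel_lowpass_coef(nf$filter_cutoff_kHz, dt_ms, nf$filter_order)
    x <- apply_ba(x, ba)
  }
  x
}
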