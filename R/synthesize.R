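#' Light-driven conductance time course
#'
#' Evaluates the membrane conductance g(t) implied by photoswitch kinetics
#' and an illumination protocol. Before any illumination g(t) = `g_trans`.
#' During a UV window the conductance relaxes toward `g_cis` as a
#' two-exponential rise (time constants `tau1`, `tau2`, amplitude split
#' `frac1`); after the window closes it holds its value, since the *cis*
#' photostationary state does not decay in the dark. During a blue window it
#' relaxes back toward `g_trans` as a single exponential at rate `k_blue`.
#' All rates scale linearly with the channel's relative irradiance.
#'
#' @param kin A [photoswitch_kinetics()] object.
#' @param light A [light_protocol()] object.
#' @param t_ms Numeric vector of sample times (ms from sweep start).
#' @return Conductance (nS) at each time in `t_ms`.
#' @examples
#' kin <- photoswitch_kinetics(g_trans_nS = 1, g_cis_nS = 7.5)
#' g <- conductance_timecourse(kin, light_protocol(uv_ms = c(100, 150)),
#'                             t_ms = seq(0, 300, by = 1))
#' @export
conductance_timecourse <- function(kin, light, t_ms) {
  stopifnot(inherits(kin, "photoswitch_kinetics"), inherits(light, "light_protocol"))
  if (light$uv_irradiance < 0 || light$blue_irradiance < 0)
    stop_pc("irradiance must be >= 0")
  g <- rep(kin$g_trans_nS, length(t_ms))

  # state entering each segment, propagated through windows in time order
  segs <- list()
  if (!is.null(light$uv_ms)) segs <- c(segs, list(list(kind = "uv", w = light$uv_ms)))
  if (!is.null(light$blue_ms)) segs <- c(segs, list(list(kind = "blue", w = light$blue_ms)))
  if (length(segs) == 0) return(g)
  segs <- segs[order(vapply(segs, function(s) s$w[1], numeric(1)))]

  g_at_entry <- kin$g_trans_nS
  # biexponential relaxation bookkeeping: amplitudes of the two modes at entry
  for (s in segs) {
    t0 <- s$w[1]; t1 <- s$w[2]
    if (s$kind == "uv") {
      irr <- light$uv_irradiance
      r1 <- irr / kin$tau1_ms
      r2 <- irr / kin$tau2_ms
      dg <- g_at_entry - kin$g_cis_nS
      relax <- function(dt) kin$g_cis_nS +
        dg * (kin$frac1 * exp(-r1 * dt) + (1 - kin$frac1) * exp(-r2 * dt))
    } else {
      irr <- light$blue_irradiance
      kb <- kin$k_blue_per_s * irr / 1000   # 1/ms
      dg <- g_at_entry - kin$g_trans_nS
      relax <- function(dt) kin$g_trans_nS + dg * exp(-kb * dt)
    }
    in_win <- t_ms >= t0 & t_ms < t1
    g[in_win] <- relax(t_ms[in_win] - t0)
    g_exit <- relax(t1 - t0)
    g[t_ms >= t1] <- g_exit
    g_at_entry <- g_exit
  }
  g
}

new_sweep_set <- function(traces, protocol, light = NULL, kinetics = NULL,
                          nf = NULL, seed = NULL, conditions = list()) {
  structure(list(traces = traces, protocol = protocol, light = light,
                 kinetics = kinetics, nf = nf, seed = seed,
                 conditions = conditions),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  ids <- unique(x$traces$sweep_id)
  cat(sprintf("<sweep_set> %d sweeps, %d samples each%s\n",
              length(ids), sum(x$traces$sweep_id == ids[1]),
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  invisible(x)
}

light_annotation <- function(light, t_ms) {
  lab <- rep("none", length(t_ms))
  if (!is.null(light$uv_ms))
    lab[t_ms >= light$uv_ms[1] & t_ms < light$uv_ms[2]] <- "uv"
  if (!is.null(light$blue_ms))
    lab[t_ms >= light$blue_ms[1] & t_ms < light$blue_ms[2]] <- "blue"
  lab
}

#' Synthesize a voltage-clamp sweep set
#'
#' Generates one current sweep per step level of the protocol according to
#' the supralinear conductance model
#' \deqn{I(t) = g(t) (1 + \alpha V(t)^2) V(t) + o + \epsilon(t)}
#' with g(t) from [conductance_timecourse()], additive white Gaussian noise
#' of standard deviation `nf$noise_sd_pA`, and the acquisition chain
#' (series-RC then Bessel low-pass) of `nf` applied last. Identical seeds and
#' parameters give bit-identical output. V enters the supralinear term in
#' volts, so `alpha` is in 1/V^2.
#'
#' @param proto A [step_protocol()] object.
#' @param light A [light_protocol()] object.
#' @param kin A [photoswitch_kinetics()] object.
#' @param alpha_per_V2 Supralinearity factor (1/V^2).
#' @param offset_pA Constant current offset (pA).
#' @param nf A [noise_filter_spec()] object.
#' @param seed Integer seed; required whenever `nf$noise_sd_pA > 0`.
#' @param conditions Optional named list of free-form condition labels
#'   (carrier, salt, pH per side, ...).
#' @return A `sweep_set` whose `$traces` tibble has columns
#'   `sweep_id, t_ms, V_mV, I_pA, light`.
#' @examples
#' ss <- synthesize_sweeps(step_protocol(dt_ms = 0.1),
#'                         light_protocol(uv_ms = c(100, 150), blue_ms = c(200, 250)),
#'                         photoswitch_kinetics(1, 7.5), seed = 1)
#' @export
synthesize_sweeps <- function(proto, light, kin, alpha_per_V2 = 0,
                              offset_pA = 0, nf = noise_filter_spec(),
                              seed = NULL, conditions = list()) {
  stopifnot(inherits(proto, "voltage_protocol"), inherits(nf, "noise_filter_spec"))
  if (nf$noise_sd_pA > 0 && is.null(seed))
    stop_pc("`seed` is required when noise_sd_pA > 0")
  dt <- proto$dt_ms
  t_ms <- (seq_len(round(proto$sweep_ms / dt)) - 0.5) * dt  # sample-centered
  g <- conductance_timecourse(kin, light, t_ms)
  lab <- light_annotation(light, t_ms)
  n <- length(t_ms)
  levels <- proto$step_levels_mV

  make_sweep <- function(i, v_level, noise) {
    V <- ifelse(t_ms < proto$hold_ms, proto$hold_mV, v_level)
    I <- g * (1 + alpha_per_V2 * (V / 1000)^2) * V + offset_pA + noise
    I <- apply_acquisition_chain(I, nf, dt)
    # id sorts lexicographically in ladder order, keeping files canonical
    tibble::tibble(sweep_id = sprintf("S%02d_V%+04d", i, as.integer(round(v_level))),
                   t_ms = t_ms, V_mV = V, I_pA = I, light = lab)
  }

  noise_mat <- if (nf$noise_sd_pA > 0) {
    withr::with_seed(seed, matrix(stats::rnorm(n * length(levels), sd = nf$noise_sd_pA),
                                  nrow = n))
  } else matrix(0, nrow = n, ncol = length(levels))

  traces <- do.call(rbind, lapply(seq_along(levels), function(i)
    make_sweep(i, levels[i], noise_mat[, i])))
  new_sweep_set(traces, proto, light, kin, nf, seed, conditions)
}

#' Synthesize a hydrophobic-anion redistribution transient
#'
#' At low bulk concentration, a voltage step redistributes membrane-adsorbed
#' hydrophobic anions (e.g. tetraphenylborate) between the two leaflets,
#' producing an exponentially decaying current `I(t) = I0 exp(-t/tau)`. The
#' ideal transient is smoothed by the acquisition chain in `nf` (series-RC
#' plus low-pass filtering), which is why fits are restricted to a window
#' past the initial samples.
#'
#' @param I0_pA Initial (t = 0) current of the ideal transient (pA).
#' @param tau_ms Decay time constant (ms), > 0.
#' @param nf A [noise_filter_spec()] object.
#' @param duration_ms Trace duration (ms).
#' @param dt_ms Sampling interval (ms).
#' @param seed Integer seed; required when `nf$noise_sd_pA > 0`.
#' @return A tibble with columns `t_ms, I_pA`.
#' @export
synthesize_tpb_transient <- function(I0_pA, tau_ms, nf = noise_filter_spec(),
                                     duration_ms = 20, dt_ms = 0.02,
                                     seed = NULL) {
  check_number(tau_ms, "tau_ms", positive = TRUE)
  check_number(duration_ms, "duration_ms", positive = TRUE)
  if (nf$noise_sd_pA > 0 && is.null(seed))
    stop_pc("`seed` is required when noise_sd_pA > 0")
  t_ms <- (seq_len(round(duration_ms / dt_ms)) - 0.5) * dt_ms
  I <- I0_pA * exp(-t_ms / tau_ms)
  if (nf$noise_sd_pA > 0)
    I <- I + withr::with_seed(seed, stats::rnorm(length(I), sd = nf$noise_sd_pA))
  I <- apply_acquisition_chain(I, nf, dt_ms)
  tibble::tibble(t_ms = t_ms, I_pA = I)
}

#' Synthesize a capacitance--voltage parabola
#'
#' Membrane capacitance depends quadratically on the applied DC voltage,
#' `Cm(V) = a V^2 + b V + c`; the vertex voltage marks the point where the
#' external field cancels the intramembrane field and therefore reports the
#' transmembrane boundary-potential difference. This generator samples the
#' parabola on a voltage grid with optional Gaussian noise.
#'
#' @param a Curvature (capacitance / mV^2); must be > 0 for a physical
#'   minimum unless `allow_nonconvex = TRUE`.
#' @param b Linear coefficient (capacitance / mV).
#' @param c Capacitance at 0 mV.
#' @param v_levels_mV Voltage grid (mV); default -100..100 in 20 mV steps.
#' @param noise_sd Gaussian noise SD in capacitance units.
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @param allow_nonconvex Permit `a <= 0` (no capacitance minimum exists).
#' @return A `cmv_curve`: tibble with columns `V_mV, C`.
#' @export
synthesize_cmv <- function(a, b, c, v_levels_mV = seq(-100, 100, by = 20),
                           noise_sd = 0, seed = NULL, allow_nonconvex = FALSE) {
  check_number(a, "a")
  if (a <= 0 && !allow_nonconvex)
    stop_pc("`a` must be > 0 for a capacitance minimum (set allow_nonconvex = TRUE to override)")
  if (noise_sd > 0 && is.null(seed)) stop_pc("`seed` is required when noise_sd > 0")
  C <- a * v_levels_mV^2 + b * v_levels_mV + c
  if (noise_sd > 0)
    C <- C + withr::with_seed(seed, stats::rnorm(length(C), sd = noise_sd))
  cmv_curve(v_levels_mV, C)
}

#' Construct a capacitance--voltage curve
#'
#' @param V_mV Applied DC voltages (mV); at least 3 distinct values.
#' @param C Measured capacitances (pF or normalized).
#' @param conditions Optional named list of condition labels.
#' @return A tibble of class `cmv_curve`.
#' @export
cmv_curve <- function(V_mV, C, conditions = list()) {
  if (length(V_mV) != length(C)) stop_pc("`V_mV` and `C` must have equal length")
  if (length(unique(V_mV)) < 3) stop_pc("need >= 3 distinct voltages")
  out <- tibble::tibble(V_mV = V_mV, C = C)
  attr(out, "conditions") <- conditions
  class(out) <- c("cmv_curve", class(out))
  out
}
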