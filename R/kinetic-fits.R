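# Kinetic fits: monoexponential transients and global biexponential
# light-response fits.

#' Monoexponential fit on a time window
#'
#' Fits `I(t) = I0 exp(-t / tau)` to the samples of one trace in the
#' half-open window `[t0, t1)`, with `I0` extrapolated back to t = 0.
#' Intended for hydrophobic-anion redistribution transients, where the
#' acquisition chain smooths the earliest milliseconds and the fit is
#' therefore restricted to a later window (classically 1 to 8 ms).
#'
#' Starting values come from a log-linear regression on the window; the
#' final estimate is a Levenberg--Marquardt refinement. When the windowed
#' data do not decay, the returned fit carries `decaying = FALSE`.
#'
#' @param sweep A tibble with columns `t_ms`, `I_pA`.
#' @param t0_ms,t1_ms Fit window (ms), at least 5 samples.
#' @return An object of class `transient_fit` with `I0_pA`, `tau_ms`,
#'   `fit_window_ms`, `decaying`.
#' @export
fit_monoexp_window <- function(sweep, t0_ms, t1_ms) {
  sel <- sweep$t_ms >= t0_ms & sweep$t_ms < t1_ms
  if (sum(sel) < 5)
    stop_pc("fit window [%g, %g) ms holds %d samples; need >= 5", t0_ms, t1_ms, sum(sel))
  t <- sweep$t_ms[sel]; I <- sweep$I_pA[sel]
  sgn <- sign(mean(I))
  if (sgn == 0) sgn <- 1
  pos <- sgn * I
  decaying <- stats::coef(stats::lm(pos ~ t))[2] < 0
  # log-linear start (guard nonpositive values after sign folding)
  ok <- pos > 0
  if (sum(ok) >= 3) {
    lf <- stats::lm(log(pos[ok]) ~ t[ok])
    tau0 <- unname(-1 / stats::coef(lf)[2])
    I00 <- unname(sgn * exp(stats::coef(lf)[1]))
    if (!is.finite(tau0) || tau0 <= 0) { tau0 <- diff(range(t)); I00 <- I[1] }
  } else { tau0 <- diff(range(t)); I00 <- I[1] }
  fit <- minpack.lm::nlsLM(I ~ I0 * exp(-t / tau),
                           start = list(I0 = I00, tau = tau0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(I0_pA = unname(cf["I0"]), tau_ms = unname(cf["tau"]),
                 fit_window_ms = c(t0_ms, t1_ms), decaying = unname(decaying)),
            class = "transient_fit")
}

#' @export
print.transient_fit <- function(x, ...) {
  cat(sprintf("<transient_fit> I0 = %.4g pA, tau = %.4g ms (window %g-%g ms%s)\n",
              x$I0_pA, x$tau_ms, x$fit_window_ms[1], x$fit_window_ms[2],
              if (!x$decaying) "; WARNING: non-decaying data" else ""))
  invisible(x)
}

# profiled SSE for the global biexponential fit: for fixed (tau1, tau2) the
# per-sweep amplitudes are linear and solved exactly.
biexp_profile <- function(log_taus, tlist, ylist) {
  tau1 <- exp(log_taus[1]); tau2 <- exp(log_taus[2])
  sse <- 0
  amps <- vector("list", length(tlist))
  for (i in seq_along(tlist)) {
    t <- tlist[[i]]; y <- ylist[[i]]
    X <- cbind(1, 1 - exp(-t / tau1), 1 - exp(-t / tau2))
    cf <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(NA_real_, 3))
    if (any(is.na(cf))) cf <- c(mean(y), 0, 0)
    r <- y - X %*% cf
    sse <- sse + sum(r^2)
    amps[[i]] <- cf
  }
  attr(sse, "amps") <- amps
  sse
}

#' Global biexponential fit of light-response kinetics
#'
#' Fits the rise of current upon illumination with
#' \deqn{I(t) = I_0 + \Delta I_1 (1 - e^{-t'/\tau_1}) + \Delta I_2 (1 - e^{-t'/\tau_2})}
#' (`t'` measured from `fit_start_ms`) globally across the sweeps of a set:
#' the two time constants are shared, the amplitudes `I0`, `dI1`, `dI2` are
#' free per sweep. Sweeps recorded at low voltages (|V| at or below
#' `exclude_abs_v_le_mV`) are excluded, since their small currents carry
#' little kinetic information.
#'
#' The time constants are profiled: for fixed `(tau1, tau2)` the amplitudes
#' are exact linear solves, and the outer 2-parameter optimization runs on
#' log time constants with deterministic starts from a log-linear regression
#' on the residual tail of the largest-amplitude sweep.
#'
#' @param sweeps A `sweep_set`.
#' @param fit_start_ms Start of the fitted window (ms), typically the UV
#'   onset.
#' @param fit_end_ms End of the fitted window (ms); defaults to the end of
#'   the UV window when the sweep set has one, else the sweep end.
#' @param exclude_abs_v_le_mV Exclusion threshold on |V| (mV), default 30.
#' @return An object of class `biexp_fit` with shared `tau1_ms <= tau2_ms`,
#'   a per-sweep tibble of amplitudes, and `effective_monoexp` set when the
#'   second component is degenerate.
#' @export
fit_biexp <- function(sweeps, fit_start_ms, fit_end_ms = NULL,
                      exclude_abs_v_le_mV = 30) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (is.null(fit_end_ms)) {
    fit_end_ms <- if (!is.null(sweeps$light) && !is.null(sweeps$light$uv_ms))
      sweeps$light$uv_ms[2] else max(sweeps$traces$t_ms)
  }
  ids <- unique(sweeps$traces$sweep_id)
  tlist <- list(); ylist <- list(); keep_ids <- character(0); volts <- numeric(0)
  for (id in ids) {
    sw <- sweeps$traces[sweeps$traces$sweep_id == id, ]
    sel <- sw$t_ms >= fit_start_ms & sw$t_ms < fit_end_ms
    v <- sw$V_mV[sel][1]
    if (abs(v) <= exclude_abs_v_le_mV) next
    keep_ids <- c(keep_ids, id); volts <- c(volts, v)
    tlist <- c(tlist, list(sw$t_ms[sel] - fit_start_ms))
    ylist <- c(ylist, list(sw$I_pA[sel]))
  }
  if (length(keep_ids) < 2)
    stop_pc("fewer than 2 sweeps retained after excluding |V| <= %g mV",
            exclude_abs_v_le_mV)

  # deterministic starts: tau2 from log-linear regression on the residual
  # tail (last half) of the largest-amplitude retained sweep; tau1 = tau2/10
  i_big <- which.max(vapply(ylist, function(y) abs(y[length(y)] - y[1]), numeric(1)))
  t <- tlist[[i_big]]; y <- ylist[[i_big]]
  y_inf <- mean(y[t >= stats::quantile(t, 0.9)])
  resid0 <- abs(y_inf - y)
  tail_sel <- t >= stats::median(t) & resid0 > max(resid0) * 1e-8
  tau2_0 <- if (sum(tail_sel) >= 3) {
    sl <- unname(stats::coef(stats::lm(log(resid0[tail_sel]) ~ t[tail_sel]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  start <- log(c(tau2_0 / 10, tau2_0))

  opt <- stats::optim(start, function(p) as.numeric(biexp_profile(p, tlist, ylist)),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  taus <- sort(exp(opt$par))
  sse <- biexp_profile(log(taus), tlist, ylist)
  amps <- attr(sse, "amps")
  per_sweep <- tibble::tibble(
    sweep_id = keep_ids, V_mV = volts,
    I0_pA = vapply(amps, `[`, numeric(1), 1),
    dI1_pA = vapply(amps, `[`, numeric(1), 2),
    dI2_pA = vapply(amps, `[`, numeric(1), 3))
  tot <- abs(per_sweep$dI1_pA) + abs(per_sweep$dI2_pA)
  mono <- all(abs(per_sweep$dI2_pA) <= 1e-6 * pmax(tot, 1e-300)) ||
    abs(taus[2] - taus[1]) < 1e-6 * taus[2]
  structure(list(tau1_ms = taus[1], tau2_ms = taus[2], per_sweep = per_sweep,
                 sse = as.numeric(sse), effective_monoexp = mono,
                 fit_window_ms = c(fit_start_ms, fit_end_ms)),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("<biexp_fit> tau1 = %.4g ms, tau2 = %.4g ms over %d sweeps%s\n",
              x$tau1_ms, x$tau2_ms, nrow(x$per_sweep),
              if (x$effective_monoexp) " (effectively monoexponential)" else ""))
  invisible(x)
}
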