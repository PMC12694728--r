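# Epoch-averaged I-V reduction and steady-state fitting.

#' Mean current over an epoch
#'
#' Arithmetic mean of the current samples falling in the half-open window
#' `[t0, t1)` of a single sweep.
#'
#' @param sweep A tibble with columns `t_ms` and `I_pA` (one sweep).
#' @param t0_ms,t1_ms Window bounds (ms), `t0 < t1`, both within the sweep.
#' @return Mean current (pA).
#' @export
epoch_mean <- function(sweep, t0_ms, t1_ms) {
  if (t0_ms >= t1_ms) stop_pc("empty epoch: t0 (%g) must be < t1 (%g)", t0_ms, t1_ms)
  tr <- range(sweep$t_ms)
  if (t0_ms > tr[2] || t1_ms < tr[1])
    stop_pc("epoch [%g, %g) ms lies outside the sweep (%g to %g ms)",
            t0_ms, t1_ms, tr[1], tr[2])
  sel <- sweep$t_ms >= t0_ms & sweep$t_ms < t1_ms
  if (!any(sel))
    stop_pc("epoch [%g, %g) ms contains no samples", t0_ms, t1_ms)
  mean(sweep$I_pA[sel])
}

#' Construct an I-V curve
#'
#' @param V_mV Voltages (mV); must be unique. Points are stored sorted by
#'   voltage.
#' @param I_pA Currents (pA).
#' @param SD_pA Optional per-point standard deviation (pA).
#' @param n Optional per-point replicate count.
#' @param epoch Optional epoch label (e.g. `"uv"`, `"blue"`).
#' @param conditions Optional named list of condition labels.
#' @return A tibble of class `iv_curve`, sorted by voltage.
#' @export
iv_curve <- function(V_mV, I_pA, SD_pA = NULL, n = NULL,
                     epoch = NULL, conditions = list()) {
  if (anyDuplicated(V_mV)) stop_pc("voltages in an I-V curve must be unique")
  if (!is.null(SD_pA) && any(SD_pA < 0, na.rm = TRUE)) stop_pc("SD must be >= 0")
  ord <- order(V_mV)
  out <- tibble::tibble(V_mV = V_mV[ord], I_pA = I_pA[ord])
  if (!is.null(SD_pA)) out$SD_pA <- SD_pA[ord]
  if (!is.null(n)) out$n <- n[ord]
  attr(out, "epoch") <- epoch
  attr(out, "conditions") <- conditions
  class(out) <- c("iv_curve", class(out))
  out
}

#' Build an I-V curve from a sweep set by epoch averaging
#'
#' One point per sweep: the voltage is the command level (which must be
#' constant inside the window) and the current is the epoch mean.
#'
#' @param sweeps A `sweep_set`.
#' @param window Length-2 numeric `c(t0, t1)` in ms, half-open.
#' @param epoch Label attached to the curve (e.g. `"uv"`, `"blue"`).
#' @return An `iv_curve` with one point per sweep.
#' @examples
#' ss <- synthesize_sweeps(step_protocol(dt_ms = 0.1),
#'                         light_protocol(uv_ms = c(100, 150), blue_ms = c(200, 250)),
#'                         photoswitch_kinetics(1, 7.5), seed = 1)
#' iv_uv <- build_iv(ss, c(125, 150), epoch = "uv")
#' @export
build_iv <- function(sweeps, window, epoch = NULL) {
  stopifnot(inherits(sweeps, "sweep_set"), length(window) == 2L)
  ids <- unique(sweeps$traces$sweep_id)
  pts <- lapply(ids, function(id) {
    sw <- sweeps$traces[sweeps$traces$sweep_id == id, ]
    sel <- sw$t_ms >= window[1] & sw$t_ms < window[2]
    if (!any(sel))
      stop_pc("epoch [%g, %g) ms contains no samples in sweep %s",
              window[1], window[2], id)
    v <- unique(sw$V_mV[sel])
    if (length(v) != 1L)
      stop_pc("command voltage is not constant inside [%g, %g) ms in sweep %s (levels: %s)",
              window[1], window[2], id, paste(v, collapse = ", "))
    c(V = v, I = mean(sw$I_pA[sel]))
  })
  m <- do.call(rbind, pts)
  iv_curve(m[, "V"], m[, "I"], epoch = epoch, conditions = sweeps$conditions)
}

#' Average replicate I-V curves point-wise
#'
#' Combines curves measured at identical voltage grids into one curve whose
#' points carry mean current, across-replicate SD, and replicate count.
#'
#' @param curves A list of `iv_curve` objects on the same voltage grid.
#' @return An `iv_curve` with `SD_pA` and `n` columns.
#' @export
aggregate_iv <- function(curves) {
  stopifnot(length(curves) >= 1)
  V <- curves[[1]]$V_mV
  for (cv in curves)
    if (!isTRUE(all.equal(cv$V_mV, V)))
      stop_pc("all replicate curves must share the same voltage grid")
  I <- sapply(curves, function(cv) cv$I_pA)
  if (is.null(dim(I))) I <- matrix(I, nrow = 1)
  iv_curve(V,
           rowMeans(I),
           SD_pA = apply(I, 1, stats::sd),
           n = rep(length(curves), length(V)),
           epoch = attr(curves[[1]], "epoch"))
}

#' Fit the supralinear conductance model to an I-V curve
#'
#' Least-squares fit of \deqn{I(V) = g_0 (1 + \alpha V^2) V + o} where `g0`
#' (nS) is the conductance at V = 0, `alpha` (1/V^2) the supralinearity
#' factor expected for ion translocation over a broad energy barrier, and
#' `o` (pA) a small current offset. The model is linear in `(g0, g0*alpha,
#' o)`, so the fit is an exact linear least-squares solve; the covariance of
#' `(g0, alpha, o)` is obtained by the delta method.
#'
#' @param iv An `iv_curve` with at least 4 points spanning both polarities
#'   (3 points suffice when `fix_alpha` is given).
#' @param fix_alpha Optional fixed supralinearity (e.g. 0 for an ohmic fit).
#' @return An object of class `iv_fit` with elements `g0_nS`,
#'   `alpha_per_V2`, `offset_pA`, `cov` (3x3, order g0/alpha/offset),
#'   `r_squared`, and `converged`.
#' @export
fit_supralinear <- function(iv, fix_alpha = NULL) {
  V <- iv$V_mV; I <- iv$I_pA
  npar <- if (is.null(fix_alpha)) 3L else 2L
  if (length(V) < max(npar + 1L, 4L) && is.null(fix_alpha))
    stop_pc("need >= 4 I-V points to fit (g0, alpha, o); got %d", length(V))
  if (length(V) < npar)
    stop_pc("need >= %d I-V points; got %d", npar, length(V))
  if (is.null(fix_alpha) && (all(V >= 0) || all(V <= 0)))
    stop_pc("I-V points must span both polarities to constrain alpha")

  if (is.null(fix_alpha)) {
    x1 <- V                      # pA/mV coefficient = nS
    x3 <- V * (V / 1000)^2       # carries g0*alpha
    fit <- stats::lm(I ~ x1 + x3)
    cf <- stats::coef(fit)
    sfit <- suppressWarnings(summary(fit))   # noiseless fixtures trip the
    vc <- sfit$sigma^2 * sfit$cov.unscaled   # "essentially perfect fit" warning
    g0 <- unname(cf["x1"]); b3 <- unname(cf["x3"]); o <- unname(cf["(Intercept)"])
    alpha <- b3 / g0
    # delta method: params (o, b1, b3) -> (g0, alpha, o)
    J <- rbind(g0    = c(0, 1, 0),
               alpha = c(0, -b3 / g0^2, 1 / g0),
               off   = c(1, 0, 0))
    cov <- J %*% vc %*% t(J)
  } else {
    xf <- V * (1 + fix_alpha * (V / 1000)^2)
    fit <- stats::lm(I ~ xf)
    cf <- stats::coef(fit)
    g0 <- unname(cf["xf"]); o <- unname(cf["(Intercept)"]); alpha <- fix_alpha
    sfit <- suppressWarnings(summary(fit))
    vc <- sfit$sigma^2 * sfit$cov.unscaled
    cov <- matrix(0, 3, 3)
    cov[c(1, 3), c(1, 3)] <- vc[c(2, 1), c(2, 1)]
  }
  dimnames(cov) <- list(c("g0", "alpha", "offset"), c("g0", "alpha", "offset"))
  structure(list(g0_nS = g0, alpha_per_V2 = alpha, offset_pA = o,
                 cov = cov, r_squared = sfit$r.squared,
                 converged = !any(is.na(cf)), epoch = attr(iv, "epoch")),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("<iv_fit%s> g0 = %.4g nS, alpha = %.4g /V^2, offset = %.4g pA (R^2 = %.4f)\n",
              if (!is.null(x$epoch)) paste0(" ", x$epoch) else "",
              x$g0_nS, x$alpha_per_V2, x$offset_pA, x$r_squared))
  invisible(x)
}

#' Weighted linear fit of a background I-V curve
#'
#' Linear model with offset, each point weighted by `1/SD^2` — the standard
#' reduction for carrier-free background conductance measured over
#' replicates. The slope is the background conductance in nS.
#'
#' @param iv An `iv_curve` whose points carry `SD_pA` (> 0 for every point).
#' @return A list with `slope_nS`, `offset_pA`, `r_squared` and the
#'   underlying `lm` fit.
#' @export
fit_linear_weighted <- function(iv) {
  if (!"SD_pA" %in% names(iv) || any(is.na(iv$SD_pA)))
    stop_pc("every point needs an SD for weighting; use an unweighted lm() fit otherwise")
  if (any(iv$SD_pA == 0))
    stop_pc("SD of 0 gives infinite weight; drop the point or fall back to an unweighted fit")
  fit <- stats::lm(I_pA ~ V_mV, data = iv, weights = 1 / iv$SD_pA^2)
  cf <- stats::coef(fit)
  list(slope_nS = unname(cf["V_mV"]), offset_pA = unname(cf["(Intercept)"]),
       r_squared = suppressWarnings(summary(fit))$r.squared, fit = fit)
}

#' Reversal potential by interpolation
#'
#' Finds the zero crossing of an I-V curve by linear interpolation between
#' the adjacent points that bracket the sign change. When several crossings
#' exist, the one nearest 0 mV is returned.
#'
#' @param iv An `iv_curve`.
#' @return Reversal potential (mV), or `NA` (with a warning) when the
#'   current never changes sign.
#' @export
reversal_potential <- function(iv) {
  V <- iv$V_mV; I <- iv$I_pA
  crossings <- numeric(0)
  for (i in seq_len(length(V) - 1L)) {
    if (I[i] == 0) crossings <- c(crossings, V[i])
    else if (I[i] * I[i + 1L] < 0)
      crossings <- c(crossings, V[i] - I[i] * (V[i + 1L] - V[i]) / (I[i + 1L] - I[i]))
  }
  if (I[length(I)] == 0) crossings <- c(crossings, V[length(V)])
  if (length(crossings) == 0) {
    warning("no sign change in the I-V curve: reversal potential undefined")
    return(NA_real_)
  }
  crossings[which.min(abs(crossings))]
}

#' Conductance state ratio over paired replicates
#'
#' Per-replicate ratio `g0_a / g0_b` (typically UV over blue photostationary
#' state), summarized as mean and SEM over replicates. The SEM is computed
#' on the per-replicate ratios (sd/sqrt(N)), matching the convention
#' "mean +/- SEM, N replicates".
#'
#' @param fits_a,fits_b Paired lists of `iv_fit` objects of equal length.
#' @return An object of class `state_ratio` with `ratio_mean`, `ratio_sem`
#'   (`NA` for a single replicate), `n_replicates`, `per_replicate`.
#' @export
state_ratio <- function(fits_a, fits_b) {
  if (length(fits_a) != length(fits_b))
    stop_pc("unpaired replicates: %d vs %d fits", length(fits_a), length(fits_b))
  if (length(fits_a) < 1) stop_pc("need at least one replicate pair")
  ga <- vapply(fits_a, function(f) f$g0_nS, numeric(1))
  gb <- vapply(fits_b, function(f) f$g0_nS, numeric(1))
  if (any(gb == 0)) stop_pc("denominator g0 of 0 in replicate %s", which(gb == 0)[1])
  r <- ga / gb
  n <- length(r)
  structure(list(ratio_mean = mean(r),
                 ratio_sem = if (n >= 2) stats::sd(r) / sqrt(n) else NA_real_,
                 n_replicates = n, per_replicate = r),
            class = "state_ratio")
}

#' @export
print.state_ratio <- function(x, ...) {
  cat(sprintf("<state_ratio> %.3g +/- %.3g (mean +/- SEM, N = %d)\n",
              x$ratio_mean, x$ratio_sem, x$n_replicates))
  invisible(x)
}

#' Percent change between two quantities
#'
#' `100 * (x_to - x_from) / x_from`; e.g. a background conductance moving
#' from 12.1 pS to 20.7 pS is a 71% increase.
#'
#' @param x_from Baseline value (nonzero).
#' @param x_to New value.
#' @return Percent change.
#' @export
percent_change <- function(x_from, x_to) {
  if (x_from == 0) stop_pc("percent change is undefined for a zero baseline")
  100 * (x_to - x_from) / x_from
}
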