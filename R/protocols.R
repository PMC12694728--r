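#' Build a step-voltage protocol
#'
#' Defines the command-voltage protocol of a sweep family: a holding segment
#' followed by a per-sweep voltage step, one sweep per ladder level. The
#' default arguments reproduce the standard PLB protocol used throughout the
#' package: hold at 0 mV for 50 ms, then step to 130 ... -130 mV in -20 mV
#' increments for the remainder of a 300 ms sweep.
#'
#' @param hold_mV Holding voltage before the step (mV).
#' @param hold_ms Duration of the holding segment (ms).
#' @param v_start_mV,v_stop_mV First and last step level (mV), inclusive.
#' @param v_step_mV Signed ladder increment (mV); must divide the span exactly.
#' @param sweep_ms Total sweep duration (ms); must exceed `hold_ms`.
#' @param dt_ms Sampling interval (ms).
#' @param inter_sweep_s Delay between consecutive sweeps (s); metadata only.
#' @return An object of class `voltage_protocol` with the enumerated
#'   `step_levels_mV`.
#' @examples
#' proto <- step_protocol()
#' length(proto$step_levels_mV) # 14 levels, 130 to -130 mV
#' @export
step_protocol <- function(hold_mV = 0, hold_ms = 50,
                          v_start_mV = 130, v_stop_mV = -130, v_step_mV = -20,
                          sweep_ms = 300, dt_ms = 0.02, inter_sweep_s = 1) {
  check_number(dt_ms, "dt_ms", positive = TRUE)
  check_number(sweep_ms, "sweep_ms", positive = TRUE)
  check_number(hold_ms, "hold_ms")
  if (hold_ms < 0) stop_pc("`hold_ms` must be >= 0")
  if (sweep_ms <= hold_ms) stop_pc("`sweep_ms` must exceed `hold_ms`")
  if (v_step_mV == 0) stop_pc("`v_step_mV` must be nonzero: a zero step defines no ladder")
  n_steps <- (v_stop_mV - v_start_mV) / v_step_mV
  if (n_steps < 0)
    stop_pc("`v_step_mV` points away from `v_stop_mV`; the ladder never reaches it")
  residue <- abs(n_steps - round(n_steps))
  if (residue > 1e-9)
    stop_pc("ladder is not commensurate: (v_stop - v_start)/v_step = %g leaves residue %g",
            n_steps, residue)
  levels <- v_start_mV + v_step_mV * seq(0L, round(n_steps))
  structure(
    list(hold_mV = hold_mV, hold_ms = hold_ms,
         step_levels_mV = levels, sweep_ms = sweep_ms,
         dt_ms = dt_ms, inter_sweep_s = inter_sweep_s),
    class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> hold %g mV for %g ms; %d steps %g..%g mV; %g ms sweeps @ dt = %g ms\n",
              x$hold_mV, x$hold_ms, length(x$step_levels_mV),
              x$step_levels_mV[1], x$step_levels_mV[length(x$step_levels_mV)],
              x$sweep_ms, x$dt_ms))
  invisible(x)
}

#' Define illumination windows within a sweep
#'
#' UV light drives the photolipid toward its photostationary *cis* state,
#' blue light back toward *trans*. Windows are half-open `[t0, t1)` intervals
#' in ms from sweep start and must not overlap.
#'
#' @param uv_ms,blue_ms Length-2 numeric `c(t0, t1)` in ms, or `NULL` for no
#'   illumination on that channel.
#' @param uv_irradiance,blue_irradiance Relative irradiance (dimensionless,
#'   >= 0); photoisomerization rates scale linearly with irradiance.
#' @return An object of class `light_protocol`.
#' @examples
#' light_protocol(uv_ms = c(100, 150), blue_ms = c(200, 250))
#' @export
light_protocol <- function(uv_ms = NULL, blue_ms = NULL,
                           uv_irradiance = 1, blue_irradiance = 1) {
  check_window <- function(w, name) {
    if (is.null(w)) return(NULL)
    if (!is.numeric(w) || length(w) != 2L || any(!is.finite(w)) || w[1] >= w[2])
      stop_pc("`%s` must be c(t0, t1) with t0 < t1", name)
    w
  }
  uv <- check_window(uv_ms, "uv_ms")
  blue <- check_window(blue_ms, "blue_ms")
  if (uv_irradiance < 0 || blue_irradiance < 0)
    stop_pc("irradiance must be >= 0")
  if (!is.null(uv) && !is.null(blue) && uv[1] < blue[2] && blue[1] < uv[2])
    stop_pc("UV and blue windows overlap ([%g, %g) vs [%g, %g))",
            uv[1], uv[2], blue[1], blue[2])
  structure(list(uv_ms = uv, blue_ms = blue,
                 uv_irradiance = uv_irradiance,
                 blue_irradiance = blue_irradiance),
            class = "light_protocol")
}

#' @export
print.light_protocol <- function(x, ...) {
  fmt <- function(w, irr) if (is.null(w)) "off" else sprintf("[%g, %g) ms x%g", w[1], w[2], irr)
  cat(sprintf("<light_protocol> UV %s; blue %s\n",
              fmt(x$uv_ms, x$uv_irradiance), fmt(x$blue_ms, x$blue_irradiance)))
  invisible(x)
}

#' Photoswitch conductance kinetics
#'
#' Parameters of the light-driven conductance relaxation between the two
#' photostationary states: a biexponential rise from `g_trans` toward `g_cis`
#' under UV (time constants `tau1 <= tau2`, amplitude fraction `frac1` on the
#' fast component) and a fast single-exponential return toward `g_trans`
#' under blue light at rate `k_blue`.
#'
#' @param g_trans_nS,g_cis_nS Conductance in the blue- and UV-adapted
#'   photostationary states (nS); both >= 0.
#' @param tau1_ms,tau2_ms UV-rise time constants at unit irradiance (ms),
#'   `tau1 <= tau2`.
#' @param frac1 Fraction of the rise amplitude carried by `tau1` (0..1).
#' @param k_blue_per_s Blue-light return rate at unit irradiance (1/s);
#'   default 7000, the millisecond-scale shutoff seen on PLBs.
#' @return An object of class `photoswitch_kinetics`.
#' @export
photoswitch_kinetics <- function(g_trans_nS, g_cis_nS,
                                 tau1_ms = 2, tau2_ms = 15, frac1 = 0.7,
                                 k_blue_per_s = 7000) {
  check_number(g_trans_nS, "g_trans_nS")
  check_number(g_cis_nS, "g_cis_nS")
  if (g_trans_nS < 0 || g_cis_nS < 0) stop_pc("conductances must be >= 0")
  check_number(tau1_ms, "tau1_ms", positive = TRUE)
  check_number(tau2_ms, "tau2_ms", positive = TRUE)
  if (tau1_ms > tau2_ms) stop_pc("`tau1_ms` must be <= `tau2_ms`")
  check_number(frac1, "frac1")
  if (frac1 < 0 || frac1 > 1) stop_pc("`frac1` must lie in [0, 1]")
  check_number(k_blue_per_s, "k_blue_per_s", positive = TRUE)
  structure(list(g_trans_nS = g_trans_nS, g_cis_nS = g_cis_nS,
                 tau1_ms = tau1_ms, tau2_ms = tau2_ms, frac1 = frac1,
                 k_blue_per_s = k_blue_per_s),
            class = "photoswitch_kinetics")
}

#' @export
print.photoswitch_kinetics <- function(x, ...) {
  cat(sprintf("<photoswitch_kinetics> g_trans %g nS -> g_cis %g nS; tau1 %g ms (f %g), tau2 %g ms; k_blue %g /s\n",
              x$g_trans_nS, x$g_cis_nS, x$tau1_ms, x$frac1, x$tau2_ms, x$k_blue_per_s))
  invisible(x)
}

#' Recording noise and filter specification
#'
#' Describes the additive current noise and the acquisition chain applied to
#' synthetic traces: an optional first-order series-RC stage (patch amplifier
#' series resistance against membrane capacitance) followed by an optional
#' low-pass Bessel filter.
#'
#' @param noise_sd_pA Standard deviation of additive white Gaussian current
#'   noise (pA); 0 disables noise.
#' @param filter_cutoff_kHz -3 dB cutoff of the Bessel low-pass (kHz);
#'   `NULL` disables the filter.
#' @param filter_order Pole count of the Bessel design (default 4).
#' @param series_resistance_MOhm Series resistance (MOhm); together with
#'   `membrane_capacitance_pF` defines the RC smoothing time constant.
#'   0 disables the RC stage.
#' @param membrane_capacitance_pF Membrane capacitance (pF).
#' @return An object of class `noise_filter_spec`.
#' @examples
#' # the acquisition chain used for hydrophobic-anion transients:
#' noise_filter_spec(filter_cutoff_kHz = 10, series_resistance_MOhm = 2,
#'                   membrane_capacitance_pF = 100)
#' @export
noise_filter_spec <- function(noise_sd_pA = 0, filter_cutoff_kHz = NULL,
                              filter_order = 4L,
                              series_resistance_MOhm = 0,
                              membrane_capacitance_pF = 0) {
  check_number(noise_sd_pA, "noise_sd_pA")
  if (noise_sd_pA < 0) stop_pc("`noise_sd_pA` must be >= 0")
  if (!is.null(filter_cutoff_kHz)) {
    check_number(filter_cutoff_kHz, "filter_cutoff_kHz", positive = TRUE)
    if (filter_order < 1) stop_pc("`filter_order` must be >= 1")
  }
  if (series_resistance_MOhm < 0 || membrane_capacitance_pF < 0)
    stop_pc("series resistance and capacitance must be >= 0")
  structure(list(noise_sd_pA = noise_sd_pA,
                 filter_cutoff_kHz = filter_cutoff_kHz,
                 filter_order = as.integer(filter_order),
                 series_resistance_MOhm = series_resistance_MOhm,
                 membrane_capacitance_pF = membrane_capacitance_pF),
            class = "noise_filter_spec")
}

# RC time constant in ms; 0 when the stage is disabled.
rc_tau_ms <- function(nf) {
  # MOhm * pF = 1e6 Ohm * 1e-12 F = 1e-6 s = 1e-3 ms
  nf$series_resistance_MOhm * nf$membrane_capacitance_pF * 1e-3
}
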