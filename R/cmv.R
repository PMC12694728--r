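# Capacitance-voltage analysis: boundary potentials from Cm-V parabolas and
# surface-potential bookkeeping.

#' Fit a parabola to a capacitance--voltage curve
#'
#' Least-squares fit of `Cm(V) = a V^2 + b V + c`. The vertex voltage
#' `-b/(2a)` is where the externally applied voltage cancels the
#' intramembrane field, i.e. it equals the transmembrane boundary-potential
#' difference. The vertex standard error comes from the delta method on the
#' `(a, b)` covariance.
#'
#' @param cmv A [cmv_curve()] (>= 3 distinct voltages).
#' @return An object of class `parabola_fit` with `a`, `b`, `c`,
#'   `vertex_mV`, `vertex_stderr_mV`, `is_minimum`, `r_squared`.
#' @export
fit_cmv_parabola <- function(cmv) {
  if (length(unique(cmv$V_mV)) < 3) stop_pc("need >= 3 distinct voltages")
  V <- cmv$V_mV; C <- cmv$C
  fit <- stats::lm(C ~ V + I(V^2))
  cf <- stats::coef(fit)
  sfit <- suppressWarnings(summary(fit))  # exact quadratics are legitimate inputs
  a <- unname(cf["I(V^2)"]); b <- unname(cf["V"]); c0 <- unname(cf["(Intercept)"])
  if (a == 0) {
    vertex <- NA_real_; vse <- NA_real_; is_min <- FALSE
  } else {
    vertex <- -b / (2 * a)
    vc <- (sfit$sigma^2 * sfit$cov.unscaled)[c("I(V^2)", "V"), c("I(V^2)", "V")]
    grad <- c(b / (2 * a^2), -1 / (2 * a))   # d vertex / d(a, b)
    vse <- sqrt(drop(t(grad) %*% vc %*% grad))
    is_min <- a > 0
  }
  structure(list(a = a, b = b, c = c0, vertex_mV = vertex,
                 vertex_stderr_mV = vse, is_minimum = is_min,
                 r_squared = sfit$r.squared),
            class = "parabola_fit")
}

#' @export
print.parabola_fit <- function(x, ...) {
  cat(sprintf("<parabola_fit> a = %.4g, b = %.4g, c = %.4g; vertex %s%.4g +/- %.2g mV\n",
              x$a, x$b, x$c,
              if (!x$is_minimum) "(not a minimum!) " else "",
              x$vertex_mV, x$vertex_stderr_mV))
  invisible(x)
}

#' Boundary-potential difference between two membrane conditions
#'
#' Change in the transmembrane boundary-potential difference between two
#' conditions, computed as `vertex(state2) - vertex(state1)` from their
#' Cm-V parabola fits. The sign convention is V = side 1 minus side 2, and
#' differences are reported as (perturbed - reference).
#'
#' @param fit_state1 Reference-condition [fit_cmv_parabola()] result.
#' @param fit_state2 Perturbed-condition fit.
#' @return The change in boundary potential (mV).
#' @export
boundary_potential_difference <- function(fit_state1, fit_state2) {
  for (f in list(fit_state1, fit_state2)) {
    if (!inherits(f, "parabola_fit")) stop_pc("arguments must be parabola_fit objects")
    if (!isTRUE(f$is_minimum) || !is.finite(f$vertex_mV))
      stop_pc("parabola vertex is not a defined minimum; boundary potential undefined")
  }
  fit_state2$vertex_mV - fit_state1$vertex_mV
}

#' Decompose a surface-potential difference into baseline and photolipid parts
#'
#' Given the surface-potential shift attributable to carrier binding at
#' photolipid sites (`shift_photolipid_mV`, measured without any other
#' asymmetry) and the total shift measured across a bilayer carrying the
#' full condition gradient (`shift_total_gradient_mV`), the baseline
#' contribution of the plain bilayer is their difference. The decomposition
#' assumes the dipole-potential difference is unchanged between conditions;
#' that assumption is recorded in the result.
#'
#' @param shift_photolipid_mV Photolipid-attributable shift (mV).
#' @param shift_total_gradient_mV Total shift across the full gradient (mV).
#' @return A list with `baseline_mV`, `photolipid_mV`, and `assumptions`.
#' @examples
#' decompose_surface_contributions(6, 10)$baseline_mV # 4 mV
#' @export
decompose_surface_contributions <- function(shift_photolipid_mV,
                                            shift_total_gradient_mV) {
  check_number(shift_photolipid_mV, "shift_photolipid_mV")
  check_number(shift_total_gradient_mV, "shift_total_gradient_mV")
  list(baseline_mV = shift_total_gradient_mV - shift_photolipid_mV,
       photolipid_mV = shift_photolipid_mV,
       assumptions = "dipole-potential difference (delta phi_d) unchanged between conditions")
}

#' Relative interfacial binding-site abundance from surface potentials
#'
#' Treating the surface potential as proportional to the interfacial
#' concentration of the adsorbed charged carrier (linearized double-layer
#' regime), the ratio of the photolipid-attributable shift to the baseline
#' shift gives the carrier bound per azobenzene-bearing reference lipid
#' relative to the plain bilayer. The ratio scales linearly with the number
#' of azobenzene moieties per photolipid molecule; the total relative
#' abundance of binding sites adds the baseline bilayer contribution of 1.
#'
#' @param phi_photolipid_mV Photolipid-attributable surface-potential shift
#'   (mV).
#' @param phi_baseline_mV Baseline (plain bilayer) shift (mV), nonzero.
#' @param azobenzenes_per_lipid Azobenzene moieties per photolipid molecule
#'   (>= 0); 1 for the single-azobenzene reference photolipid.
#' @return A list with `per_unit_ratio` (one-azobenzene reference),
#'   `scaled_ratio` and `total_relative_sites`.
#' @examples
#' binding_site_ratio(6, 4, 1)$per_unit_ratio       # 1.5
#' binding_site_ratio(6, 4, 2)$total_relative_sites # 4
#' @export
binding_site_ratio <- function(phi_photolipid_mV, phi_baseline_mV,
                               azobenzenes_per_lipid = 1) {
  if (phi_baseline_mV == 0) stop_pc("baseline surface-potential shift must be nonzero")
  if (azobenzenes_per_lipid < 0) stop_pc("`azobenzenes_per_lipid` must be >= 0")
  per_unit <- phi_photolipid_mV / phi_baseline_mV
  scaled <- per_unit * azobenzenes_per_lipid
  list(per_unit_ratio = per_unit, scaled_ratio = scaled,
       total_relative_sites = scaled + 1)
}

#' Boundary-potential decomposition record
#'
#' Container for the identity `delta phi_b = delta phi_s + delta phi_d`
#' (boundary = surface + dipole). Any one component may be omitted and is
#' derived from the other two; if all three are given they must satisfy the
#' identity.
#'
#' @param delta_phi_b_mV,delta_phi_s_mV,delta_phi_d_mV Components (mV); at
#'   least two must be supplied.
#' @param assumptions Character vector of recorded assumptions.
#' @return An object of class `boundary_potentials`.
#' @export
boundary_potentials <- function(delta_phi_b_mV = NULL, delta_phi_s_mV = NULL,
                                delta_phi_d_mV = NULL, assumptions = character(0)) {
  have <- !vapply(list(delta_phi_b_mV, delta_phi_s_mV, delta_phi_d_mV), is.null, logical(1))
  if (sum(have) < 2) stop_pc("supply at least two of the three components")
  if (is.null(delta_phi_b_mV)) delta_phi_b_mV <- delta_phi_s_mV + delta_phi_d_mV
  if (is.null(delta_phi_s_mV)) delta_phi_s_mV <- delta_phi_b_mV - delta_phi_d_mV
  if (is.null(delta_phi_d_mV)) delta_phi_d_mV <- delta_phi_b_mV - delta_phi_s_mV
  if (abs(delta_phi_b_mV - delta_phi_s_mV - delta_phi_d_mV) > 1e-9)
    stop_pc("components violate delta phi_b = delta phi_s + delta phi_d")
  structure(list(delta_phi_b_mV = delta_phi_b_mV,
                 delta_phi_s_mV = delta_phi_s_mV,
                 delta_phi_d_mV = delta_phi_d_mV,
                 assumptions = assumptions),
            class = "boundary_potentials")
}
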