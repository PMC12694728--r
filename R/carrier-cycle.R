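# Four-step mobile-carrier cycle: association at one interface,
# translocation of the complex, release at the other interface, return of
# the free carrier. Linear four-state kinetics with Eyring half-barrier
# voltage splitting on the charged translocation leg.

#' Parameters of the four-step carrier cycle
#'
#' States are free carrier at side 1/2 and carrier--ion complex at side 1/2.
#' Association (`k_on * [ion]`) and dissociation (`k_off`) connect free
#' carrier and complex at each interface; translocation rates connect the
#' two sides. The voltage dependence sits on whichever translocating species
#' carries the charge: the complex for a neutral carrier binding an ion
#' (valinomycin--K+), the free carrier for a charged carrier whose complex
#' is neutral (anionic protonophores such as CCCP-).
#'
#' @param k_on_per_M_s Ion association rate constant (1/(M s)).
#' @param k_off_per_s Dissociation rate constant (1/s).
#' @param k_complex_per_s Complex translocation rate at 0 mV (1/s).
#' @param k_free_per_s Free-carrier translocation rate at 0 mV (1/s).
#' @param carrier_density_mol_cm2 Carrier surface density per leaflet
#'   (mol/cm^2).
#' @param c_ion_side1_M,c_ion_side2_M Aqueous ion concentrations (mol/L).
#' @param z Valence of the charged translocating species (nonzero).
#' @param charged_leg `"complex"` or `"free"`: which translocation step
#'   carries the charge (the other is voltage-independent).
#' @return An object of class `carrier_cycle_params`.
#' @export
carrier_cycle_params <- function(k_on_per_M_s, k_off_per_s,
                                 k_complex_per_s, k_free_per_s,
                                 carrier_density_mol_cm2 = 1e-12,
                                 c_ion_side1_M = 0.015, c_ion_side2_M = 0.015,
                                 z = 1L, charged_leg = c("complex", "free")) {
  charged_leg <- match.arg(charged_leg)
  rates <- c(k_on_per_M_s, k_off_per_s, k_complex_per_s, k_free_per_s)
  if (any(rates < 0)) stop_pc("rate constants must be >= 0")
  if (all(rates == 0)) stop_pc("at least one rate constant must be > 0")
  if (z == 0) stop_pc("valence `z` must be nonzero")
  if (k_off_per_s > 0 && !is.finite(k_on_per_M_s / k_off_per_s))
    stop_pc("K_A = k_on/k_off must be finite")
  structure(list(k_on = k_on_per_M_s, k_off = k_off_per_s,
                 k_complex = k_complex_per_s, k_free = k_free_per_s,
                 carrier_density = carrier_density_mol_cm2,
                 c1 = c_ion_side1_M, c2 = c_ion_side2_M,
                 z = as.integer(z), charged_leg = charged_leg),
            class = "carrier_cycle_params")
}

# Rate matrix of the four-state cycle. States in order:
# 1 free carrier side 1, 2 free carrier side 2, 3 complex side 1,
# 4 complex side 2. Q[i, j] is the i -> j rate; positive V (side 1 minus
# side 2) accelerates movement of positive charge from side 1 to side 2 by
# the symmetric Eyring factor exp(+u/2), u = zFV/RT.
cycle_rates <- function(p, V_mV, T_K = 298.15) {
  u <- p$z * .const$F_C_mol * (V_mV / 1000) / (.const$R_J_molK * T_K)
  bias_fwd <- exp(u / 2); bias_bwd <- exp(-u / 2)
  kc12 <- p$k_complex; kc21 <- p$k_complex
  kf12 <- p$k_free;    kf21 <- p$k_free
  if (p$charged_leg == "complex") {
    kc12 <- kc12 * bias_fwd; kc21 <- kc21 * bias_bwd
  } else {
    kf12 <- kf12 * bias_fwd; kf21 <- kf21 * bias_bwd
  }
  list(assoc1 = p$k_on * p$c1, assoc2 = p$k_on * p$c2, dissoc = p$k_off,
       kc12 = kc12, kc21 = kc21, kf12 = kf12, kf21 = kf21)
}

cycle_rate_matrix <- function(p, V_mV, T_K = 298.15) {
  r <- cycle_rates(p, V_mV, T_K)
  Q <- matrix(0, 4, 4)
  Q[1, 3] <- r$assoc1; Q[3, 1] <- r$dissoc
  Q[2, 4] <- r$assoc2; Q[4, 2] <- r$dissoc
  Q[3, 4] <- r$kc12;   Q[4, 3] <- r$kc21
  Q[1, 2] <- r$kf12;   Q[2, 1] <- r$kf21
  diag(Q) <- -rowSums(Q)
  Q
}

#' Steady-state occupancies of the carrier cycle
#'
#' Solves the stationary distribution of the linear four-state cycle at a
#' given voltage.
#'
#' @param p A [carrier_cycle_params()] object.
#' @param V_mV Transmembrane voltage (mV), side 1 minus side 2.
#' @param T_K Temperature (K).
#' @return Named numeric of occupancies (`free1`, `free2`, `complex1`,
#'   `complex2`) summing to 1.
#' @export
cycle_steady_state <- function(p, V_mV, T_K = 298.15) {
  Q <- cycle_rate_matrix(p, V_mV, T_K)
  # stationary pi: t(Q) pi = 0, sum(pi) = 1 -> replace one equation
  A <- rbind(t(Q)[1:3, ], rep(1, 4))
  pi <- solve(A, c(0, 0, 0, 1))
  stats::setNames(pi, c("free1", "free2", "complex1", "complex2"))
}

#' Steady-state carrier current density
#'
#' Closed-form steady-state current of the four-step carrier cycle: the net
#' translocation flux of the charged species times zF times the total
#' interfacial carrier density. At V = 0 with symmetric solutions the cycle
#' satisfies detailed balance and the current vanishes.
#'
#' @inheritParams cycle_steady_state
#' @return Current density (A/cm^2); positive for net positive charge
#'   moving from side 1 to side 2.
#' @export
steady_state_current <- function(p, V_mV, T_K = 298.15) {
  vapply(V_mV, function(v) {
    pi <- cycle_steady_state(p, v, T_K)
    r <- cycle_rates(p, v, T_K)
    flux <- if (p$charged_leg == "complex")
      r$kc12 * pi["complex1"] - r$kc21 * pi["complex2"]
    else
      r$kf12 * pi["free1"] - r$kf21 * pi["free2"]
    total_carrier <- 2 * p$carrier_density   # mol/cm^2, both leaflets
    unname(p$z * .const$F_C_mol * total_carrier * flux)
  }, numeric(1))
}

#' I-V curve from the carrier-cycle model
#'
#' Evaluates [steady_state_current()] on a voltage grid and packages the
#' result as an [iv_curve()] in pA so that the trace-analysis fitters can
#' consume it directly.
#'
#' @inheritParams cycle_steady_state
#' @param v_mV Voltage grid (mV).
#' @param area_cm2 Membrane area (cm^2).
#' @return An `iv_curve` with currents in pA.
#' @export
cycle_iv <- function(p, v_mV = seq(-130, 130, by = 20), T_K = 298.15,
                     area_cm2 = 1e-4) {
  I_pA <- steady_state_current(p, v_mV, T_K) * area_cm2 * 1e12
  iv_curve(v_mV, I_pA)
}

#' Fold effect of a change in the ion-association constant
#'
#' Ratio `K_A_new / K_A_ref` of carrier--ion association equilibrium
#' constants; in the translocation-limited regime the small-potential
#' conductance scales linearly with K_A, so this is also the predicted
#' conductance fold change.
#'
#' @param K_A_ref Reference association constant (> 0).
#' @param K_A_new New association constant.
#' @return Dimensionless fold change.
#' @examples
#' ka_fold_effect(1.5, 9) # 6
#' @export
ka_fold_effect <- function(K_A_ref, K_A_new) {
  check_number(K_A_ref, "K_A_ref", positive = TRUE)
  K_A_new / K_A_ref
}

#' Supralinearity factor of a symmetric single barrier
#'
#' For translocation over a single symmetric Eyring barrier the current is
#' proportional to `sinh(zFV/2RT)`, whose small-V expansion matches
#' `g0 (1 + alpha V^2) V` with
#' \deqn{\alpha = \frac{1}{6}\left(\frac{zF}{2RT}\right)^2}
#' (63.1 per V^2 for a monovalent ion at 298.15 K).
#'
#' @param T_K Temperature (K).
#' @param z Valence.
#' @return Supralinearity factor alpha (1/V^2).
#' @export
alpha_from_single_barrier <- function(T_K = 298.15, z = 1L) {
  check_number(T_K, "T_K", positive = TRUE)
  (z * .const$F_C_mol / (2 * .const$R_J_molK * T_K))^2 / 6
}
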