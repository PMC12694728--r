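# Electrostatic/thermodynamic barrier model: three-slab membrane energetics,
# Born and dipole terms, dielectric rescaling, speciation, and reversal
# potentials.

#' Thermal energy RT
#'
#' @param T_K Absolute temperature (K), > 0.
#' @return RT in kcal/mol (0.5925 at 298.15 K).
#' @export
thermal_energy <- function(T_K = 298.15) {
  check_number(T_K, "T_K", positive = TRUE)
  .const$R_kcal * T_K
}

#' Small-potential conductance from permeability
#'
#' Nernst--Planck small-potential limit for the conductance at V = 0 of a
#' membrane of area A permeated by a charged species at interfacial
#' concentration \[S\]:
#' \deqn{g_0 = z^2 F^2 A P [S] / (R T)}
#' Here \[S\] is the concentration of the transportable charged species in
#' the interfacial (headgroup) slabs of the three-slab membrane model and P
#' the permeability of the hydrophobic core.
#'
#' @param P_cm_s Permeability (cm/s).
#' @param S_mol_L Interfacial concentration of the charged species (mol/L).
#' @param A_cm2 Membrane area (cm^2).
#' @param T_K Temperature (K).
#' @param z Valence (nonzero integer).
#' @return Conductance in Siemens.
#' @export
conductance_small_potential <- function(P_cm_s, S_mol_L, A_cm2 = 1,
                                        T_K = 298.15, z = 1L) {
  check_number(P_cm_s, "P_cm_s", positive = TRUE)
  check_number(S_mol_L, "S_mol_L", positive = TRUE)
  check_number(A_cm2, "A_cm2", positive = TRUE)
  check_number(T_K, "T_K", positive = TRUE)
  if (z == 0) stop_pc("valence `z` must be nonzero")
  S_mol_cm3 <- S_mol_L / 1000
  z^2 * .const$F_C_mol^2 * A_cm2 * P_cm_s * S_mol_cm3 / (.const$R_J_molK * T_K)
}

#' Permeability of the hydrophobic core from a free-energy barrier
#'
#' `P = (D/d) exp(-dG / RT)`: the partition coefficient onto the top of the
#' trapezoidal barrier is a Boltzmann factor in the free energy `dG` that
#' opposes transmembrane movement.
#'
#' @param D_cm2_s Membrane diffusion coefficient (cm^2/s).
#' @param d_nm Membrane (hydrophobic core) thickness (nm).
#' @param dG_kcal_mol Free-energy barrier (kcal/mol).
#' @param T_K Temperature (K).
#' @return Permeability (cm/s).
#' @export
permeability_from_barrier <- function(D_cm2_s, d_nm, dG_kcal_mol, T_K = 298.15) {
  check_number(D_cm2_s, "D_cm2_s", positive = TRUE)
  check_number(d_nm, "d_nm", positive = TRUE)
  check_number(T_K, "T_K", positive = TRUE)
  d_cm <- d_nm * 1e-7
  (D_cm2_s / d_cm) * exp(-dG_kcal_mol / thermal_energy(T_K))
}

#' Rescale a barrier for a change in hydrocarbon-core dielectric constant
#'
#' The electrostatic contributions to the permeation barrier scale as
#' `1/eps_hc`; treating the whole barrier as electrostatic, a dielectric
#' change from `eps_old` to `eps_new` rescales it by `eps_old/eps_new`
#' (e.g. 16 kcal/mol at eps 2.1 becomes 14.6 kcal/mol at eps 2.3).
#'
#' @param dG_kcal_mol Barrier (kcal/mol).
#' @param eps_old,eps_new Old and new dielectric constants (>= 1).
#' @return Rescaled barrier (kcal/mol).
#' @export
rescale_barrier_dielectric <- function(dG_kcal_mol, eps_old, eps_new) {
  if (eps_old < 1 || eps_new < 1) stop_pc("dielectric constants must be >= 1")
  dG_kcal_mol * eps_old / eps_new
}

#' Conductance fold change implied by a barrier change
#'
#' Boltzmann ratio `exp((dG_high - dG_low)/RT)`: the factor by which the
#' small-potential conductance rises when the permeation barrier drops from
#' `dG_high` to `dG_low`, all other factors equal.
#'
#' @param dG_high_kcal_mol,dG_low_kcal_mol Barriers (kcal/mol).
#' @param T_K Temperature (K).
#' @return Dimensionless fold change.
#' @export
fold_change_from_barriers <- function(dG_high_kcal_mol, dG_low_kcal_mol,
                                      T_K = 298.15) {
  exp((dG_high_kcal_mol - dG_low_kcal_mol) / thermal_energy(T_K))
}

#' Born self-energy of ion transfer into a low-dielectric slab
#'
#' \deqn{\Delta G_b = \frac{z^2 e^2 N_A}{8 \pi \epsilon_0 r}
#'   \left(\frac{1}{\epsilon_m} - \frac{1}{\epsilon_w}\right)}
#'
#' @param z Valence.
#' @param radius_nm Ion (or complex) radius (nm), > 0.
#' @param eps_m Membrane-core dielectric constant.
#' @param eps_w Water dielectric constant (default 78).
#' @return Born energy (kcal/mol).
#' @export
born_energy <- function(z, radius_nm, eps_m, eps_w = 78) {
  check_number(radius_nm, "radius_nm", positive = TRUE)
  if (eps_m < 1 || eps_w < 1) stop_pc("dielectric constants must be >= 1")
  r_m <- radius_nm * 1e-9
  J_mol <- z^2 * .const$e_C^2 * .const$N_A /
    (8 * pi * .const$eps0 * r_m) * (1 / eps_m - 1 / eps_w)
  J_mol / .const$J_per_kcal
}

#' Born-energy scaling with molecular mass
#'
#' Under constant-density spherical scaling the radius grows as the cube
#' root of mass, so the Born energy of a complex relative to the bare ion is
#' `mass_ratio^(-1/3)`. Note that for a 4.3-fold mass increase this gives a
#' reduction factor of 1.63, somewhat less than a factor of two; radius
#' models other than the constant-density sphere give larger reductions.
#'
#' @param mass_ratio Molecular-mass ratio new/old, > 0.
#' @return Born-energy ratio new/old (dimensionless).
#' @export
born_scaling_from_mass <- function(mass_ratio) {
  check_number(mass_ratio, "mass_ratio", positive = TRUE)
  mass_ratio^(-1 / 3)
}

#' Dipole-potential energy term
#'
#' `dG_d = z F phi_d`: the interaction of the permeating charge with the
#' positive-inside membrane dipole potential (typically around +250 mV),
#' which penalizes cations and favors anions.
#'
#' @param z Valence.
#' @param phi_d_mV Dipole potential (mV).
#' @return Dipole energy (kcal/mol); +5.77 kcal/mol for z = +1 at +250 mV.
#' @export
dipole_energy <- function(z, phi_d_mV) {
  z * .const$F_C_mol * (phi_d_mV / 1000) / .const$J_per_kcal
}

#' Charged fraction of a weak acid or base
#'
#' Henderson--Hasselbalch speciation: the fraction of molecules carrying
#' charge at a given pH. For a weak acid (e.g. the protonophore CCCP,
#' pKa 6.1) this is the deprotonated-anion fraction
#' `1/(1 + 10^(pKa - pH))`; for a weak base, the protonated-cation fraction
#' `1/(1 + 10^(pH - pKa))`.
#'
#' @param pH Solution pH.
#' @param pKa Acid dissociation constant.
#' @param kind `"acid"` or `"base"`.
#' @return Charged fraction in \[0, 1\].
#' @examples
#' charged_fraction(5.0, 6.1, "acid") # ~0.07
#' charged_fraction(7.4, 6.1, "acid") # ~0.95
#' @export
charged_fraction <- function(pH, pKa, kind = c("acid", "base")) {
  kind <- match.arg(kind)
  if (kind == "acid") 1 / (1 + 10^(pKa - pH)) else 1 / (1 + 10^(pH - pKa))
}

#' Nernst equilibrium potential
#'
#' `V_r = (RT/zF) ln(c_side2 / c_side1)` under the convention
#' V = side 1 minus side 2: a 10-fold dilution of a monovalent cation on
#' side 2 gives -59.2 mV at 298.15 K.
#'
#' @param c_side1_M,c_side2_M Ion concentrations on the two sides (mol/L or
#'   any common unit), > 0.
#' @param z Valence (nonzero).
#' @param T_K Temperature (K).
#' @return Reversal potential (mV).
#' @examples
#' nernst_potential(0.150, 0.015) # -59.2 mV
#' @export
nernst_potential <- function(c_side1_M, c_side2_M, z = 1L, T_K = 298.15) {
  check_number(c_side1_M, "c_side1_M", positive = TRUE)
  check_number(c_side2_M, "c_side2_M", positive = TRUE)
  if (z == 0) stop_pc("valence `z` must be nonzero")
  1000 * .const$R_J_molK * T_K / (z * .const$F_C_mol) * log(c_side2_M / c_side1_M)
}

#' Goldman--Hodgkin--Katz reversal potential
#'
#' Multi-ion zero-current potential for monovalent ions, under the same
#' sign convention as [nernst_potential()] (V = side 1 minus side 2):
#' \deqn{V_r = \frac{RT}{F} \ln \frac{\sum_{cations} P c_{2} + \sum_{anions} P c_{1}}
#'   {\sum_{cations} P c_{1} + \sum_{anions} P c_{2}}}
#' With a single permeant ion this reduces exactly to the Nernst potential.
#'
#' @param ions A data frame with columns `z` (+1 or -1), `P` (relative
#'   permeability, > 0), `c_side1`, `c_side2` (concentrations, > 0).
#' @param T_K Temperature (K).
#' @return Reversal potential (mV).
#' @export
ghk_potential <- function(ions, T_K = 298.15) {
  if (NROW(ions) < 1) stop_pc("`ions` must contain at least one ion")
  need <- c("z", "P", "c_side1", "c_side2")
  if (!all(need %in% names(ions)))
    stop_pc("`ions` needs columns %s", paste(need, collapse = ", "))
  if (!all(ions$z %in% c(-1L, 1L)))
    stop_pc("GHK is implemented for monovalent ions only (z = +1 or -1)")
  cat_sel <- ions$z == 1L
  num <- sum(ions$P[cat_sel] * ions$c_side2[cat_sel]) +
    sum(ions$P[!cat_sel] * ions$c_side1[!cat_sel])
  den <- sum(ions$P[cat_sel] * ions$c_side1[cat_sel]) +
    sum(ions$P[!cat_sel] * ions$c_side2[!cat_sel])
  1000 * .const$R_J_molK * T_K / .const$F_C_mol * log(num / den)
}

#' Barrier decomposition into Born, dipole and residual terms
#'
#' @param dG_born_kcal_mol,dG_dipole_kcal_mol,dG_other_kcal_mol Components
#'   (kcal/mol); `dG_other` collects non-electrostatic and minor terms.
#' @return An object of class `barrier_decomposition` whose `dG_total` is
#'   the sum of the components.
#' @export
barrier_decomposition <- function(dG_born_kcal_mol, dG_dipole_kcal_mol,
                                  dG_other_kcal_mol = 0) {
  structure(list(dG_born = dG_born_kcal_mol, dG_dipole = dG_dipole_kcal_mol,
                 dG_other = dG_other_kcal_mol,
                 dG_total = dG_born_kcal_mol + dG_dipole_kcal_mol + dG_other_kcal_mol),
            class = "barrier_decomposition")
}

#' @export
print.barrier_decomposition <- function(x, ...) {
  cat(sprintf("<barrier_decomposition> Born %.3g + dipole %.3g + other %.3g = %.3g kcal/mol\n",
              x$dG_born, x$dG_dipole, x$dG_other, x$dG_total))
  invisible(x)
}

#' Membrane/electrostatic parameter set
#'
#' Bundles the constants of the three-slab barrier model for use by the
#' energetics calculator and configuration files.
#'
#' @param temperature_K Temperature (K).
#' @param eps_hc Hydrocarbon-core dielectric constant.
#' @param eps_w Water dielectric constant.
#' @param thickness_d_nm Core thickness (nm).
#' @param diffusion_D_cm2_s Membrane diffusion coefficient (cm^2/s).
#' @param dipole_potential_mV Dipole potential (mV).
#' @param barrier_dG_kcal_mol Permeation barrier (kcal/mol).
#' @param interfacial_conc_S_M Interfacial concentration of the charged
#'   species (mol/L).
#' @param membrane_area_cm2 Membrane area (cm^2).
#' @return An object of class `energetics_params`.
#' @export
energetics_params <- function(temperature_K = 298.15, eps_hc = 2.1, eps_w = 78,
                              thickness_d_nm = 4, diffusion_D_cm2_s = 1e-6,
                              dipole_potential_mV = 250,
                              barrier_dG_kcal_mol = 16,
                              interfacial_conc_S_M = 1e-6,
                              membrane_area_cm2 = 1) {
  check_number(temperature_K, "temperature_K", positive = TRUE)
  if (eps_hc < 1 || eps_w < 1) stop_pc("dielectric constants must be >= 1")
  check_number(thickness_d_nm, "thickness_d_nm", positive = TRUE)
  check_number(membrane_area_cm2, "membrane_area_cm2", positive = TRUE)
  structure(list(temperature_K = temperature_K, eps_hc = eps_hc, eps_w = eps_w,
                 thickness_d_nm = thickness_d_nm,
                 diffusion_D_cm2_s = diffusion_D_cm2_s,
                 dipole_potential_mV = dipole_potential_mV,
                 barrier_dG_kcal_mol = barrier_dG_kcal_mol,
                 interfacial_conc_S_M = interfacial_conc_S_M,
                 membrane_area_cm2 = membrane_area_cm2),
            class = "energetics_params")
}

#' Carrier identity
#'
#' @param name Carrier name (e.g. "valinomycin", "CCCP", "NB-lipid").
#' @param valence_z Charge of the transported/translocating species.
#' @param kind One of `"neutral-ionophore"`, `"weak-acid"`, `"weak-base"`.
#' @param pKa Acid dissociation constant (weak acids/bases).
#' @param molar_mass_g_mol Molar mass (g/mol).
#' @return An object of class `carrier_spec`.
#' @export
carrier_spec <- function(name, valence_z,
                         kind = c("neutral-ionophore", "weak-acid", "weak-base"),
                         pKa = NULL, molar_mass_g_mol = NULL) {
  kind <- match.arg(kind)
  if (kind != "neutral-ionophore" && is.null(pKa))
    stop_pc("weak acids/bases need a pKa")
  structure(list(name = name, valence_z = as.integer(valence_z), kind = kind,
                 pKa = pKa, molar_mass_g_mol = molar_mass_g_mol),
            class = "carrier_spec")
}

#' Small-potential conductance directly from barrier parameters
#'
#' Convenience composition of [permeability_from_barrier()] and
#' [conductance_small_potential()] over an [energetics_params()] set.
#'
#' @param par An [energetics_params()] object.
#' @param z Valence.
#' @return Conductance (Siemens).
#' @export
g0_from_barrier <- function(par, z = 1L) {
  P <- permeability_from_barrier(par$diffusion_D_cm2_s, par$thickness_d_nm,
                                 par$barrier_dG_kcal_mol, par$temperature_K)
  conductance_small_potential(P, par$interfacial_conc_S_M,
                              par$membrane_area_cm2, par$temperature_K, z)
}
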