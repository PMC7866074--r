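#' Packaged pure-compound property table
#'
#' Returns the pure-compound property table shipped with the package: one row
#' per compound with identity (name, formula, CAS number), molar mass `M`
#' (g mol-1), critical temperature `Tc` (K), normal boiling temperature `Tb`
#' (K), critical pressure `Pc` (bar), critical molar volume `Vc` (cm3 mol-1),
#' acentric factor `w`, Lennard-Jones diameter `sigma_lj` (Angstrom) and
#' Lennard-Jones energy constant `eps_lj_over_kB` (K). One provenance-code
#' column per estimated property (`src_*`) records the source of each value;
#' values are data as tabulated, not recomputed.
#'
#' Known quirks of the tabulated data are preserved verbatim: two synonym rows
#' (1-butanol / n-butanol) share a CAS number with identical properties, and
#' hydrogen carries a zero Lennard-Jones energy constant. Validation therefore
#' requires `eps_lj_over_kB >= 0` and allows duplicate CAS only when the
#' duplicated rows agree on every numeric property.
#'
#' @return A data.frame with one row per compound.
#' @export
#' @examples
#' tab <- compound_table()
#' nrow(tab)
compound_table <- function() {
  tab <- .compounds_cache$table
  if (is.null(tab)) {
    path <- system.file("extdata", "compounds.csv", package = "tracerdiff",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    validate_compound_table(tab)
    .compounds_cache$table <- tab
  }
  tab
}

.compounds_cache <- new.env(parent = emptyenv())

#' Validate a compound-property table
#'
#' Checks the structural invariants of a compound table: positive molar mass,
#' critical pressure, critical volume and Lennard-Jones diameter;
#' `Tc > Tb > 0`; non-negative Lennard-Jones energy; and no two rows sharing a
#' CAS number with differing numeric properties.
#'
#' @param tab data.frame in the layout of [compound_table()].
#' @return The table, invisibly; errors describe the first violated invariant.
#' @export
validate_compound_table <- function(tab) {
  need <- c("name", "cas", "M", "Tc", "Tb", "Pc", "Vc", "w",
            "sigma_lj", "eps_lj_over_kB")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    .stop_domain("compound table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- function(cond, what) {
    if (any(cond)) {
      .stop_domain(sprintf("compound table invariant violated (%s) for: %s",
                           what, paste(tab$name[cond], collapse = ", ")))
    }
  }
  bad(tab$M <= 0, "M > 0")
  bad(tab$Tb <= 0 | tab$Tc <= tab$Tb, "Tc > Tb > 0")
  bad(tab$Pc <= 0, "Pc > 0")
  bad(tab$Vc <= 0, "Vc > 0")
  bad(tab$sigma_lj <= 0, "sigma_lj > 0")
  bad(tab$eps_lj_over_kB < 0, "eps_lj_over_kB >= 0")
  dup <- unique(tab$cas[duplicated(tab$cas)])
  for (cas in dup) {
    rows <- tab[tab$cas == cas, c("M", "Tc", "Tb", "Pc", "Vc", "w",
                                  "sigma_lj", "eps_lj_over_kB")]
    if (nrow(unique(rows)) > 1L) {
      .stop_domain("compound table has conflicting rows for CAS ", cas)
    }
  }
  invisible(tab)
}

#' Look up a compound by name or CAS number
#'
#' Exact-match lookup in the packaged compound table, case-insensitive on the
#' compound name. Unknown keys raise an error listing near matches.
#'
#' @param key Compound name (case-insensitive) or CAS registry number.
#' @param table Compound table; defaults to the packaged one.
#' @return A one-row data.frame of compound properties.
#' @export
#' @examples
#' lookup_compound("ferrocene")$M
#' lookup_compound("108-88-3")$name
lookup_compound <- function(key, table = compound_table()) {
  stopifnot(is.character(key), length(key) == 1L)
  hit <- which(table$cas == key)
  if (!length(hit)) {
    hit <- which(tolower(table$name) == tolower(key))
  }
  if (!length(hit)) {
    near <- utils::head(table$name[order(utils::adist(tolower(key),
                                                      tolower(table$name)))], 3L)
    .stop_domain(sprintf("compound '%s' not found; nearest names: %s",
                         key, paste(near, collapse = ", ")))
  }
  table[hit[1L], , drop = FALSE]
}

#' Molar volume at the normal boiling point from the critical volume
#'
#' Tyn-Calus power-law relation `Vbp = 0.285 * Vc^1.048`, used to feed the
#' hydrodynamic correlations when only the critical volume is tabulated.
#'
#' @param vc Critical molar volume, cm3 mol-1 (non-negative).
#' @return Molar volume at the normal boiling point, cm3 mol-1.
#' @export
#' @examples
#' vbp_from_vc(259) # benzene
vbp_from_vc <- function(vc) {
  if (any(!is.finite(vc)) || any(vc < 0)) {
    .stop_domain("'vc' must be non-negative and finite")
  }
  0.285 * vc^1.048
}

#' Critical temperature by the Klincewicz molar-mass/boiling-point correlation
#'
#' `Tc = 50.2 - 0.16 M + 1.41 Tb`. This is the two-input (no group
#' contribution) form of the Klincewicz method, suitable for organometallics
#' and other molecules outside group-contribution coverage.
#'
#' @param M Molar mass, g mol-1 (non-negative).
#' @param Tb Normal boiling temperature, K (positive).
#' @return Critical temperature, K.
#' @export
#' @examples
#' klincewicz_tc(234.95, 456.25) # tetraethyltin
klincewicz_tc <- function(M, Tb) {
  if (any(!is.finite(M)) || any(M < 0)) .stop_domain("'M' must be non-negative")
  .check_positive(Tb = Tb)
  50.2 - 0.16 * M + 1.41 * Tb
}

#' Acentric factor by the Lee-Kesler relation
#'
#' Standard Lee-Kesler vapour-pressure-based estimate with
#' `theta = Tb / Tc` and the critical pressure expressed in atm (the input is
#' taken in bar and converted internally; this convention reproduces
#' tabulated values).
#'
#' @param Tb Normal boiling temperature, K.
#' @param Tc Critical temperature, K; must exceed `Tb`.
#' @param Pc Critical pressure, bar.
#' @return Acentric factor (dimensionless).
#' @export
#' @examples
#' lee_kesler_omega(522.15, 786.27, 32.07) # ferrocene
lee_kesler_omega <- function(Tb, Tc, Pc) {
  .check_positive(Tb = Tb, Tc = Tc, Pc = Pc)
  theta <- Tb / Tc
  if (any(theta >= 1)) {
    .stop_domain("'Tb' must be below 'Tc' (theta = Tb/Tc in (0, 1))")
  }
  ln_pc <- log(Pc / .const$atm_bar)
  k <- .lee_kesler
  num <- -ln_pc + k$num[1] + k$num[2] / theta + k$num[3] * log(theta) +
    k$num[4] * theta^6
  den <- k$den[1] + k$den[2] / theta + k$den[3] * log(theta) +
    k$den[4] * theta^6
  num / den
}

#' Lennard-Jones parameters of the solute from critical constants
#'
#' Solute energy constant `eps/kB = Tc2 / 1.313` (K) and diameter
#' `sigma = (0.13 eps / Pc2)^(1/3)` (Angstrom, with `eps = kB Tc2 / 1.313` in
#' J and `Pc2` converted to Pa; the cube root restores the volume-to-length
#' dimensionality of the estimator).
#'
#' @param Tc2 Solute critical temperature, K.
#' @param Pc2 Solute critical pressure, bar.
#' @return List with `eps_over_kB` (K) and `sigma` (Angstrom).
#' @export
#' @examples
#' zhu_solute_lj(562.2, 48.9) # benzene
zhu_solute_lj <- function(Tc2, Pc2) {
  .check_positive(Tc2 = Tc2, Pc2 = Pc2)
  eps_over_kB <- Tc2 / .zhu$eps_tc_divisor
  eps_J <- .const$kB_J * eps_over_kB
  sigma_m <- (.zhu$solute_sigma_coef * eps_J / (Pc2 * .const$bar_Pa))^(1 / 3)
  list(eps_over_kB = eps_over_kB, sigma = sigma_m * 1e10)
}

#' Effective Lennard-Jones parameters of the solvent at a reduced state
#'
#' State-dependent solvent parameters of the hybrid Lennard-Jones D12 model:
#' `eps1/kB = (Tc1 / 1.313) * (1 + 0.47527332 rho_r1 +
#' (0.06300484 + 0.12374707 rho_r1) T_r1)` and
#' `sigma1 = (0.31 / rho_nc1)^(1/3) * (1 - 0.0368868 rho_r1 +
#' (0.00006945 + 0.01089228 rho_r1) T_r1)`, where `rho_nc1 = N_A / Vc1` is the
#' number critical density (cm-3). The reduced density is a mass-density
#' ratio, `rho_r1 = rho1 / (M1 / Vc1)`, and `T_r1 = T / Tc1`.
#'
#' @param Tc1 Solvent critical temperature, K.
#' @param Vc1 Solvent critical molar volume, cm3 mol-1.
#' @param rho_r1 Reduced solvent density (dimensionless).
#' @param T_r1 Reduced temperature (dimensionless).
#' @return List with `eps_over_kB` (K), `sigma` (Angstrom), and the reduced
#'   state `rho_r1`, `T_r1` it was evaluated at.
#' @export
zhu_solvent_lj <- function(Tc1, Vc1, rho_r1, T_r1) {
  .check_positive(Tc1 = Tc1, Vc1 = Vc1)
  .check_positive(rho_r1 = rho_r1, T_r1 = T_r1, .allow_zero = TRUE)
  b <- .zhu$eps1_bracket
  eps_over_kB <- (Tc1 / .zhu$eps_tc_divisor) *
    (1 + b["a"] * rho_r1 + (b["b"] + b["c"] * rho_r1) * T_r1)
  s <- .zhu$sig1_bracket
  rho_nc1 <- .const$N_A / Vc1                       # cm^-3
  sigma_cm <- (.zhu$solvent_sigma_coef / rho_nc1)^(1 / 3) *
    (1 - s["a"] * rho_r1 + (s["b"] + s["c"] * rho_r1) * T_r1)
  list(eps_over_kB = unname(eps_over_kB), sigma = unname(sigma_cm * 1e8),
       rho_r1 = rho_r1, T_r1 = T_r1)
}
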