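#' Wilke-Chang association factor for a solvent
#'
#' Empirical multiplier on the solvent molar mass in the Wilke-Chang equation:
#' 1.9 for methanol, 1.5 for ethanol, 1.0 for unassociated solvents. The
#' solvent is recognised by CAS number or (case-insensitive) name.
#'
#' @param solvent Character vector of solvent names or CAS numbers.
#' @return Numeric vector of association factors.
#' @export
#' @examples
#' association_factor(c("methanol", "64-17-5", "n-hexane"))
association_factor <- function(solvent) {
  key <- tolower(as.character(solvent))
  phi <- rep(1.0, length(key))
  phi[key %in% c("methanol", "67-56-1")] <- 1.9
  phi[key %in% c("ethanol", "64-17-5")] <- 1.5
  phi
}

#' Wilke-Chang hydrodynamic estimate of D12
#'
#' `D12 = 7.4e-8 (phi M1)^0.5 T / (mu1 Vbp2^0.6)` in cm2 s-1: the empirical
#' Stokes-Einstein modification most widely used for infinite-dilution
#' diffusivities in liquids.
#'
#' @param T Temperature, K.
#' @param mu1 Solvent viscosity, cP.
#' @param M1 Solvent molar mass, g mol-1.
#' @param Vbp2 Solute molar volume at the normal boiling point, cm3 mol-1
#'   (see [vbp_from_vc()]).
#' @param phi Solvent association factor (see [association_factor()]).
#' @return D12, cm2 s-1.
#' @export
#' @examples
#' wilke_chang(300, 1, 46.07, vbp_from_vc(259), phi = 1.5)
wilke_chang <- function(T, mu1, M1, Vbp2, phi = 1.0) {
  .check_positive(T = T, mu1 = mu1, M1 = M1, Vbp2 = Vbp2, phi = phi)
  7.4e-8 * sqrt(phi * M1) * T / (mu1 * Vbp2^0.6)
}

#' Tyn-Calus hydrodynamic estimate of D12
#'
#' `D12 = 8.93e-8 (Vbp1^0.267 / Vbp2^0.433) T / mu1` in cm2 s-1, with the
#' solvent boiling-point volume in the numerator (the standard published
#' form).
#'
#' @param T Temperature, K.
#' @param mu1 Solvent viscosity, cP.
#' @param Vbp1,Vbp2 Solvent and solute molar volumes at the normal boiling
#'   point, cm3 mol-1.
#' @return D12, cm2 s-1.
#' @export
tyn_calus <- function(T, mu1, Vbp1, Vbp2) {
  .check_positive(T = T, mu1 = mu1, Vbp1 = Vbp1, Vbp2 = Vbp2)
  8.93e-8 * (Vbp1^0.267 / Vbp2^0.433) * T / mu1
}

#' Fit the two-parameter correlation D12 = a T / mu1 + b for one system
#'
#' Ordinary least squares of observed D12 on the single regressor
#' `x = T / mu1`. A Stokes-Einstein-type correlation: the two parameters are
#' specific to one solvent/solute system and must be fitted to data for that
#' system before prediction.
#'
#' @param T Temperature, K.
#' @param mu1 Solvent viscosity, cP.
#' @param D12 Observed diffusivities, cm2 s-1.
#' @param min_points Minimum number of distinct `T/mu1` values required
#'   (default 3: two parameters plus one degree of freedom).
#' @return Object of class `magalhaes_fit`: list with slope `a`
#'   (cm2 s-1 cP K-1), intercept `b` (cm2 s-1) and `n_points`.
#' @export
#' @examples
#' x <- c(1000, 2000, 3000)
#' magalhaes_fit(T = x, mu1 = 1, D12 = 2e-9 * x + 1e-6)
magalhaes_fit <- function(T, mu1, D12, min_points = 3L) {
  .check_positive(T = T, mu1 = mu1, D12 = D12)
  x <- T / mu1
  n <- length(x)
  if (length(D12) != n) .stop_domain("'T/mu1' and 'D12' lengths differ")
  if (length(unique(x)) < min_points) {
    .stop_domain(sprintf(
      "cannot fit the two-parameter correlation: %d distinct T/mu1 values (need >= %d)",
      length(unique(x)), min_points))
  }
  if (stats::var(x) == 0) .stop_domain("zero variance in T/mu1")
  fit <- stats::lm(D12 ~ x)
  structure(list(a = unname(stats::coef(fit)[2L]),
                 b = unname(stats::coef(fit)[1L]),
                 n_points = n),
            class = "magalhaes_fit")
}

#' Predict D12 from a fitted two-parameter correlation
#'
#' Evaluates `a T / mu1 + b`. Extreme extrapolation can produce a negative
#' value; it is returned as-is with a warning.
#'
#' @param fit A [magalhaes_fit()] object.
#' @param T Temperature, K.
#' @param mu1 Solvent viscosity, cP.
#' @return Predicted D12, cm2 s-1.
#' @export
magalhaes_predict <- function(fit, T, mu1) {
  stopifnot(inherits(fit, "magalhaes_fit"))
  .check_positive(T = T, mu1 = mu1)
  d12 <- fit$a * T / mu1 + fit$b
  if (any(d12 < 0)) {
    warning("negative D12 from extrapolation of the two-parameter correlation",
            call. = FALSE)
  }
  d12
}

#' @export
print.magalhaes_fit <- function(x, ...) {
  cat(sprintf("D12 = a*T/mu1 + b fit: a = %.6g cm2 s-1 cP K-1, b = %.6g cm2 s-1 (n = %d)\n",
              x$a, x$b, x$n_points))
  invisible(x)
}

#' Reduced state of the hybrid Lennard-Jones D12 model
#'
#' Builds the binary Lennard-Jones state used by [zhu_d12()]. Pure-component
#' parameters come from the state-dependent estimators [zhu_solvent_lj()]
#' (at `rho_r1 = rho1 / (M1 / Vc1)`, `T_r1 = T / Tc1`) and [zhu_solute_lj()];
#' unlike-pair parameters follow the combining rules
#' `k12d = 0.7926 (sigma2 - sigma1) / (sigma2 + sigma1)`,
#' `sigma12 = (1 - k12d)(sigma1 + sigma2)/2` and
#' `eps12 = sqrt(eps1 eps2)`.
#'
#' @param T Temperature, K.
#' @param rho1 Solvent density, g cm-3.
#' @param solvent,solute Lists or one-row data.frames with at least
#'   `Tc`, `Vc`, `M` (solvent) and `Tc`, `Pc` (solute), e.g. rows of
#'   [compound_table()].
#' @return Object of class `zhu_state`: `sigma12` (Angstrom),
#'   `eps12_over_kB` (K), `k12d`, `T12_star`, `rho12_star`, `rho_n1` (cm-3)
#'   and `m1` (g).
#' @export
#' @examples
#' hexane <- lookup_compound("n-hexane")
#' benzene <- lookup_compound("benzene")
#' zhu_state(313.15, 0.65, hexane, benzene)
zhu_state <- function(T, rho1, solvent, solute) {
  .check_positive(T = T, rho1 = rho1)
  solvent <- as.list(solvent)
  solute <- as.list(solute)
  rho_c1 <- solvent$M / solvent$Vc          # g cm-3
  rho_r1 <- rho1 / rho_c1
  T_r1 <- T / solvent$Tc
  lj1 <- zhu_solvent_lj(solvent$Tc, solvent$Vc, rho_r1, T_r1)
  lj2 <- zhu_solute_lj(solute$Tc, solute$Pc)
  k12d <- .zhu$k12d_coef * (lj2$sigma - lj1$sigma) / (lj2$sigma + lj1$sigma)
  sigma12 <- (1 - k12d) * (lj1$sigma + lj2$sigma) / 2
  eps12 <- sqrt(lj1$eps_over_kB * lj2$eps_over_kB)
  rho_n1 <- rho1 * .const$N_A / solvent$M   # cm-3
  structure(list(
    sigma12 = sigma12,
    eps12_over_kB = eps12,
    k12d = k12d,
    T12_star = T / eps12,
    rho12_star = rho_n1 * (sigma12 * 1e-8)^3,
    rho_n1 = rho_n1,
    m1 = solvent$M / .const$N_A
  ), class = "zhu_state")
}

#' @export
print.zhu_state <- function(x, ...) {
  cat(sprintf(paste0("binary LJ state: sigma12 = %.4f A, eps12/kB = %.2f K, ",
                     "k12d = %.5f, T12* = %.4f, rho12* = %.4f\n"),
              x$sigma12, x$eps12_over_kB, x$k12d, x$T12_star, x$rho12_star))
  invisible(x)
}

#' Hybrid Lennard-Jones estimate of D12
#'
#' Evaluates the free-volume/energy hybrid model on a [zhu_state()]:
#' `D12 = D_kin * F1 * F2 * F3`, where
#' `D_kin = (3/8) sqrt(kB T / (pi m1)) / (rho_n1 sigma12^2)` is the
#' dilute-gas (Chapman-Enskog) kinetic prefactor,
#' `F1 = 1 - rho12*^1.029079 / T12*^0.165377` is the free-volume correction,
#' `F2` an empirical dense-fluid correction and
#' `F3 = exp(-rho12*^2 / (2 T12*))` an energy damping term. At
#' `rho12* = 0` the model reduces exactly to `D_kin`. The model was devised
#' for nonpolar fluids.
#'
#' @param state A [zhu_state()] object.
#' @return D12, cm2 s-1. If the free-volume factor `F1` is non-positive the
#'   state is outside the model's validity: the value is still returned,
#'   with a warning.
#' @export
zhu_d12 <- function(state) {
  stopifnot(inherits(state, "zhu_state"))
  Tkelvin <- state$T12_star * state$eps12_over_kB
  sigma_cm <- state$sigma12 * 1e-8
  d_kin <- (3 / 8) * sqrt(.const$kB_erg * Tkelvin / (pi * state$m1)) /
    (state$rho_n1 * sigma_cm^2)
  rs <- state$rho12_star
  Ts <- state$T12_star
  f1c <- .zhu$F1
  f2c <- .zhu$F2
  F1 <- 1 - rs^f1c["rho_exp"] / Ts^f1c["T_exp"]
  F2 <- 1 + rs^f2c["rho_exp"] *
    (f2c["num"] * (rs - 1) /
       (f2c["den"] * (rs - 1) + Ts^(f2c["T_exp_a"] - f2c["T_exp_b"] * rs)) +
       f2c["offset"])
  F3 <- exp(-rs^2 / (2 * Ts))
  if (any(F1 <= 0)) {
    warning("free-volume factor F1 <= 0: state outside model validity",
            call. = FALSE)
  }
  unname(d_kin * F1 * F2 * F3)
}

#' One-call hybrid Lennard-Jones model
#'
#' Convenience wrapper building the [zhu_state()] and evaluating [zhu_d12()].
#'
#' @inheritParams zhu_state
#' @return D12, cm2 s-1.
#' @export
zhu_model <- function(T, rho1, solvent, solute) {
  zhu_d12(zhu_state(T, rho1, solvent, solute))
}
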