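# Physical constants (CODATA 2018). The working formulas are CGS-Gaussian
# where that keeps D12 in cm2 s-1 without trailing conversion factors.
.const <- list(
  N_A    = 6.02214076e23,  # mol^-1
  kB_J   = 1.380649e-23,   # J K^-1
  kB_erg = 1.380649e-16,   # erg K^-1
  bar_Pa = 1e5,
  atm_bar = 1.01325
)

# Every numeric constant of the hybrid Lennard-Jones D12 model lives in this
# one table, together with the grouping choices that had to be fixed when the
# printed equations lost their fraction bars and exponents: the solvent energy
# bracket multiplies Tc/1.313; the cube roots on both diameter estimators are
# restored on dimensional grounds (volume -> length); the temperature term in
# the correction factor F2 is a power of T12*; and the exponential damping is
# exp(-rho12*^2 / (2 T12*)). Correcting any reading against the original
# source changes one entry here.
.zhu <- list(
  eps_tc_divisor = 1.313,
  solute_sigma_coef = 0.13,
  solvent_sigma_coef = 0.31,
  eps1_bracket = c(a = 0.47527332, b = 0.06300484, c = 0.12374707),
  sig1_bracket = c(a = 0.0368868, b = 0.00006945, c = 0.01089228),
  k12d_coef = 0.7926,
  F1 = c(rho_exp = 1.029079, T_exp = 0.165377),
  F2 = c(rho_exp = 0.126978, num = 0.596103, den = 0.539292,
         T_exp_a = 0.400152, T_exp_b = 0.41054, offset = 0.68856)
)

# Lee-Kesler acentric-factor relation coefficients, theta = Tb/Tc,
# pressure in atm.
.lee_kesler <- list(
  num = c(-5.92714, 6.09648, 1.28862, -0.169347),
  den = c(15.2518, -15.6875, -13.4721, 0.43577)
)

.stop_domain <- function(...) {
  stop(..., call. = FALSE)
}

.check_positive <- function(..., .allow_zero = FALSE) {
  vals <- list(...)
  nm <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (any(!is.finite(v)) || (if (.allow_zero) any(v < 0) else any(v <= 0))) {
      .stop_domain(sprintf("'%s' must be %s and finite",
                           nm[i], if (.allow_zero) "non-negative" else "strictly positive"))
    }
  }
  invisible(TRUE)
}
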