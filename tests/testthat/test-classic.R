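test_that("Wilke-Chang equation matches hand evaluation and is linear in T", {
  expect_equal(wilke_chang(300, 1, 46.07, 96.42, phi = 1.5), 1.190e-5,
               tolerance = 0.005)
  expect_equal(wilke_chang(600, 1, 46.07, 96.42, phi = 1.5),
               2 * wilke_chang(300, 1, 46.07, 96.42, phi = 1.5))
  expect_error(wilke_chang(300, 0, 46.07, 96.42), "positive")
})

test_that("association factor defaults depend on the solvent identity", {
  expect_equal(association_factor(c("methanol", "67-56-1")), c(1.9, 1.9))
  expect_equal(association_factor(c("ethanol", "64-17-5")), c(1.5, 1.5))
  expect_equal(association_factor(c("n-hexane", "water", "toluene")),
               c(1, 1, 1))
})

test_that("Tyn-Calus equation matches hand evaluation and is monotone in Vbp2", {
  expect_equal(tyn_calus(300, 1, 100, 100), 8.93e-8 * 100^(-0.166) * 300,
               tolerance = 0.005)
  v2 <- seq(50, 500, by = 25)
  d <- tyn_calus(300, 1, 100, v2)
  expect_true(all(diff(d) < 0))
  expect_error(tyn_calus(300, 1, -5, 100), "positive")
})

test_that("hydrodynamic equations are homogeneous of degree 1 in T and -1 in mu1", {
  set.seed(11)
  for (i in 1:200) {
    T <- runif(1, 250, 550); mu <- runif(1, 0.05, 15)
    M1 <- runif(1, 20, 300); v1 <- runif(1, 50, 800); v2 <- runif(1, 50, 800)
    k <- runif(1, 0.5, 4)
    expect_equal(wilke_chang(k * T, mu, M1, v2), k * wilke_chang(T, mu, M1, v2))
    expect_equal(wilke_chang(T, k * mu, M1, v2), wilke_chang(T, mu, M1, v2) / k)
    expect_equal(tyn_calus(k * T, mu, v1, v2), k * tyn_calus(T, mu, v1, v2))
    expect_equal(tyn_calus(T, k * mu, v1, v2), tyn_calus(T, mu, v1, v2) / k)
  }
})

test_that("two-parameter correlation fit recovers exact and least-squares lines", {
  x <- c(1000, 2000, 3000, 4500)
  f <- magalhaes_fit(T = x, mu1 = 1, D12 = 2e-9 * x + 1e-6)
  expect_equal(f$a, 2e-9, tolerance = 1e-10)
  expect_equal(f$b, 1e-6, tolerance = 1e-10)
  expect_equal(f$n_points, 4L)
  # closed-form least squares on three points (computed by hand:
  # a = Sxy/Sxx = 1/2, b = mean(D) - a*mean(x) = 5/3 - 1 = 2/3)
  g <- magalhaes_fit(T = c(1, 2, 3), mu1 = 1, D12 = c(1, 2, 2))
  expect_equal(g$a, 0.5)
  expect_equal(g$b, 2 / 3)
  expect_error(magalhaes_fit(T = c(1, 2), mu1 = 1, D12 = c(1, 2)),
               "distinct T/mu1")
  expect_error(magalhaes_fit(T = c(2, 2, 2), mu1 = 1, D12 = c(1, 2, 3)),
               "distinct T/mu1")
})

test_that("two-parameter correlation prediction is the plain affine evaluation", {
  f <- structure(list(a = 0, b = 3e-6, n_points = 5L), class = "magalhaes_fit")
  expect_equal(magalhaes_predict(f, c(300, 400), c(1, 2)), c(3e-6, 3e-6))
  g <- magalhaes_fit(T = c(1, 2, 3), mu1 = 1, D12 = 2e-9 * c(1, 2, 3) + 1e-9)
  expect_equal(magalhaes_predict(g, 4, 1), 9e-9, tolerance = 1e-6)
  h <- magalhaes_fit(T = c(1000, 2000, 3000), mu1 = 1,
                     D12 = 2e-9 * c(1000, 2000, 3000) + 1e-6)
  expect_equal(magalhaes_predict(h, 4, 1), 2e-9 * 4 + 1e-6, tolerance = 1e-6)
  # mu1 -> Inf limit tends to the intercept
  expect_equal(magalhaes_predict(h, 300, 1e12), 1e-6, tolerance = 1e-6)
  neg <- structure(list(a = 1e-9, b = -1e-3, n_points = 5L),
                   class = "magalhaes_fit")
  expect_warning(magalhaes_predict(neg, 300, 1), "negative")
})

test_that("combining rules behave symmetrically and match direct arithmetic", {
  sv <- list(M = 86.18, Tc = 507.5, Vc = 370)
  so <- list(Tc = 562.2, Pc = 48.9)
  st <- zhu_state(300, 0.7, sv, so)
  # k12d from the printed ratio: sigma1 = 3, sigma2 = 5 (direct arithmetic)
  k <- 0.7926 * (5 - 3) / (5 + 3)
  expect_equal(k, 0.19815)
  expect_equal((1 - k) * (3 + 5) / 2, 3.2074)
  # the binary energy is the geometric mean of the pure-component ones
  lj1 <- zhu_solvent_lj(507.5, 370, 0.7 / (86.18 / 370), 300 / 507.5)
  lj2 <- zhu_solute_lj(562.2, 48.9)
  expect_equal(st$eps12_over_kB, sqrt(lj1$eps_over_kB * lj2$eps_over_kB))
  # equal diameters: k12d = 0 and sigma12 preserved (antisymmetry of the rule)
  expect_equal(0.7926 * (lj1$sigma - lj1$sigma) / (2 * lj1$sigma), 0)
  expect_equal(st$rho_n1, 0.7 * 6.02214076e23 / 86.18)
  expect_equal(st$T12_star * st$eps12_over_kB, 300)
})

test_that("hybrid LJ model reduces to the kinetic prefactor at zero density", {
  st <- zhu_state(300, 0.7, list(M = 86.18, Tc = 507.5, Vc = 370),
                  list(Tc = 562.2, Pc = 48.9))
  st0 <- st
  st0$rho12_star <- 0
  d_kin <- (3 / 8) * sqrt(1.380649e-16 * 300 / (pi * st$m1)) /
    (st$rho_n1 * (st$sigma12 * 1e-8)^2)
  expect_equal(zhu_d12(st0), d_kin, tolerance = 1e-12)
  # 1/sqrt(m1) scaling of the prefactor at fixed reduced state
  st_heavy <- st0
  st_heavy$m1 <- 4 * st0$m1
  expect_equal(zhu_d12(st_heavy), zhu_d12(st0) / 2, tolerance = 1e-12)
})

test_that("hybrid LJ model matches its frozen full-evaluation pin", {
  st <- zhu_state(300, 0.7, list(M = 86.18, Tc = 507.5, Vc = 370),
                  list(Tc = 562.2, Pc = 48.9))
  expect_equal(st$sigma12, 5.2448654, tolerance = 1e-7)   # frozen oracle value
  expect_equal(st$eps12_over_kB, 666.66369, tolerance = 1e-7)
  expect_equal(st$k12d, 0.01262421, tolerance = 1e-6)
  expect_equal(zhu_d12(st), 4.4813376e-5, tolerance = 1e-7) # frozen oracle value
})

test_that("hybrid LJ model is strictly decreasing in density over the dense-fluid domain", {
  # The empirical dense-fluid correction is only constrained where the model
  # was fitted (liquid-like reduced densities); below rho* ~ 0.4 the bracket
  # term is an unconstrained extrapolation and the reduced correction is not
  # monotone, so monotonicity is asserted on rho* in [0.4, 1].
  base <- zhu_state(300, 0.7, list(M = 86.18, Tc = 507.5, Vc = 370),
                    list(Tc = 562.2, Pc = 48.9))
  for (Ts in c(0.6, 1, 2, 4)) {
    d <- vapply(seq(0.4, 1, by = 0.025), function(rs) {
      st <- base
      st$T12_star <- Ts
      st$rho12_star <- rs
      suppressWarnings(zhu_d12(st)) # F1 <= 0 near rho* = 1 at low T* is expected
    }, 0)
    expect_true(all(diff(d) < 0), label = sprintf("T12* = %g", Ts))
  }
})

test_that("out-of-validity states (F1 <= 0) warn but still return a value", {
  st <- zhu_state(300, 0.7, list(M = 86.18, Tc = 507.5, Vc = 370),
                  list(Tc = 562.2, Pc = 48.9))
  st$rho12_star <- 2.5 # far above the free-volume validity edge
  expect_warning(v <- zhu_d12(st), "validity")
  expect_true(is.finite(v))
})
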