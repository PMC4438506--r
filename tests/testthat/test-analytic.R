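test_that("steady Dirichlet profile reduces to the classic closed form for W = 0", {
  prob <- radial_problem(R1 = 10, R2 = 50, D = 100)
  r <- seq(10, 50, by = 2.5)
  expect_equal(steady_profile(r, prob),
               (1 / 10 - 1 / r) / (1 / 10 - 1 / 50))
  expect_equal(steady_profile(10, prob), 0)
  expect_equal(steady_profile(50, prob), 1)
  expect_error(steady_profile(60, prob), "outside")
})

test_that("Robin profile interpolates between reflective and absorbing limits", {
  base <- radial_problem(R1 = 10, R2 = 50, D = 100,
                         betaW = radial_coulomb(7.136))
  hard <- radial_problem(R1 = 10, R2 = 50, D = 100,
                         betaW = radial_coulomb(7.136),
                         inner_bc = "robin", alpha = 1e12)
  soft <- radial_problem(R1 = 10, R2 = 50, D = 100,
                         betaW = radial_coulomb(7.136),
                         inner_bc = "robin", alpha = 1e-9)
  r <- seq(10, 50, length.out = 41)
  expect_equal(steady_profile(r, hard), steady_profile(r, base),
               tolerance = 1e-6)
  ## alpha -> 0: flat Boltzmann-weighted bulk profile (p = e^{bW(R2)-bW(r)})
  expect_equal(steady_profile(r, soft),
               exp(7.136 / 50 - 7.136 / r), tolerance = 1e-6)
  expect_equal(steady_rate(hard), steady_rate(base), tolerance = 1e-6)
})

test_that("Coulomb closed-form shell integral agrees with adaptive quadrature", {
  Q <- 7.136
  f_quad <- function(r) exp(Q / r) / r^2
  closed <- radial_problem(R1 = 50, R2 = 125, D = 1, betaW = radial_coulomb(Q))
  numeric_bw <- radial_problem(R1 = 50, R2 = 125, D = 1,
                               betaW = function(r) Q / r)  # no closed form attr
  r <- c(60, 80, 100, 125)
  expect_equal(steady_profile(r, closed), steady_profile(r, numeric_bw),
               tolerance = 1e-10)
  expect_equal(steady_rate(closed), steady_rate(numeric_bw), tolerance = 1e-10)
})

test_that("steady rates honor the textbook limits", {
  ## finite outer boundary, W = 0
  prob <- radial_problem(R1 = 10, R2 = 50, D = 100)
  expect_equal(steady_rate(prob), 4 * pi * 100 / (1 / 10 - 1 / 50))
  ## R2 -> infinity: Smoluchowski rate 4 pi D R1
  far <- radial_problem(R1 = 10, R2 = 1e9, D = 100)
  expect_equal(steady_rate(far), 4 * pi * 100 * 10, tolerance = 1e-7)
  ## weak reactivity: k ~ 4 pi R1^2 alpha, linear in alpha
  k1 <- steady_rate(radial_problem(R1 = 10, R2 = 50, D = 100,
                                   inner_bc = "robin", alpha = 1e-6))
  k2 <- steady_rate(radial_problem(R1 = 10, R2 = 50, D = 100,
                                   inner_bc = "robin", alpha = 2e-6))
  expect_equal(k2 / k1, 2, tolerance = 1e-6)
  expect_equal(k1, 4 * pi * 100 * 1e-6, tolerance = 1e-3)
})

test_that("steady rate equals the flux of the steady profile at any radius", {
  ## flux constancy: k = 4 pi r^2 D [p' + betaW' p] for all r in (R1, R2)
  prob <- radial_problem(R1 = 20, R2 = 80, D = 500,
                         betaW = radial_coulomb(-5),
                         inner_bc = "robin", alpha = 800)
  k <- steady_rate(prob)
  eps <- 1e-4
  for (r in c(25, 40, 66)) {
    dp <- (steady_profile(r + eps, prob) - steady_profile(r - eps, prob)) / (2 * eps)
    dbW <- 5 / r^2                      # d/dr of betaW = -5/r
    p <- steady_profile(r, prob)
    flux <- 4 * pi * r^2 * 500 * (dp + dbW * p)
    expect_equal(flux, k, tolerance = 1e-6)
  }
})

test_that("transient sphere series matches limits and the finite-difference oracle", {
  prob <- radial_problem(R1 = 0, R2 = 125, D = 78000)
  r <- seq(0, 125, by = 5)
  ## t = 0: zero inside, bulk at the surface
  p0 <- transient_sphere_profile(r, 0, prob)
  expect_true(all(p0[r < 125] == 0))
  ## long times: uniform bulk
  t_long <- 10 * 125^2 / 78000
  expect_equal(transient_sphere_profile(r, t_long, prob), rep(1, length(r)),
               tolerance = 1e-10)
  ## early time vs independent 1-D finite differences
  t <- 0.05 * 125^2 / 78000
  fd <- fd_sphere_transient(prob, t, nr = 1200)
  ri <- seq(2.5, 122.5, by = 5)
  pfd <- approx(fd$r, fd$p, xout = ri)$y
  expect_equal(transient_sphere_profile(ri, t, prob), pfd, tolerance = 1e-4)
  expect_error(transient_sphere_profile(130, t, prob), "outside")
})

test_that("relative L2 error metric is exact on hand-computed cases", {
  expect_equal(l2_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(l2_error(1.01 * c(4, 5, 6), c(4, 5, 6)), 0.01)
  ## 3-particle case by direct arithmetic
  num <- c(1, 2, 2); ref <- c(1, 1, 2)
  expect_equal(l2_error(num, ref), sqrt(1 / 6))
  ## mask selects the comparison set
  expect_equal(l2_error(c(9, 1, 1), c(1, 1, 1), mask = 2:3), 0)
  expect_error(l2_error(c(1, 2), c(0, 0)), "zero norm")
  expect_error(l2_error(c(1, 2), c(1, 2), mask = integer()), "empty mask")
})
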