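test_that("Coulombic PMF has the right scale, sign and decay", {
  pts <- rbind(c(5, 0, 0), c(0, 10, 0), c(0, 0, 1e6))
  pmf <- coulomb_pmf(pts, Q = 5)
  expect_equal(pmf$W, c(1, 0.5, 5e-6))        # r = Q gives betaW = 1
  expect_equal(coulomb_pmf(pts, Q = 0)$W, c(0, 0, 0))
  expect_lt(pmf$W[3], 1e-5 * 5)
  expect_error(coulomb_pmf(rbind(c(0, 0, 0)), Q = 1), "singular")
  ## attraction flips the sign
  expect_equal(coulomb_pmf(pts, Q = -5)$W, -pmf$W)
  ## default prefactor is the Bjerrum length for water at room temperature
  expect_equal(bjerrum_length(), 7.136, tolerance = 1e-3)
})

test_that("screened Coulomb reduces to bare Coulomb and decays with screening", {
  pts <- rbind(c(2, 0, 0), c(0, 7, 0))
  expect_equal(screened_coulomb_pmf(pts, Q = 3, kappa_dh = 0)$W,
               coulomb_pmf(pts, Q = 3)$W)
  ## kappa * r = ln 2 halves the bare value
  r <- 4
  W <- screened_coulomb_pmf(rbind(c(r, 0, 0)), Q = r, kappa_dh = log(2) / r)$W
  expect_equal(W, 0.5)
  ## monotone decrease in screening at fixed r, Q > 0
  Ws <- vapply(c(0, 0.1, 0.3, 1), function(k)
    screened_coulomb_pmf(rbind(c(5, 0, 0)), Q = 2, kappa_dh = k)$W, numeric(1))
  expect_true(all(diff(Ws) < 0))
})

test_that("OpenDX grids round-trip through write/read", {
  set.seed(3)
  g <- scalar_grid(origin = c(-1, 0, 2.5), spacing = c(0.5, 1, 0.25),
                   values = array(rnorm(5 * 4 * 6), dim = c(5, 4, 6)))
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx_grid(g, path)
  g2 <- read_dx_grid(path)
  expect_identical(g2$shape, g$shape)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$spacing, g$spacing)   # non-uniform spacings preserved
  expect_equal(g2$values, g$values)     # bit-identical round trip
  ## comment lines tolerated
  lines <- readLines(path)
  writeLines(c("# extra comment", lines[1:3], "# mid comment", lines[-(1:3)]),
             path)
  expect_equal(read_dx_grid(path)$values, g$values)
})

test_that("malformed OpenDX input is rejected with a parse error", {
  g <- scalar_grid(c(0, 0, 0), 1, array(1:27, dim = c(3, 3, 3)))
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx_grid(g, path)
  lines <- readLines(path)
  ## remove one data value -> count mismatch
  dstart <- grep("data follows", lines) + 1L
  lines[dstart] <- sub("^\\s*\\S+\\s*", "", lines[dstart])
  writeLines(lines, path)
  expect_error(read_dx_grid(path), "expected 27 values")
  writeLines(c("just", "garbage"), path)
  expect_error(read_dx_grid(path), "gridpositions")
})

test_that("trilinear interpolation is nodal-exact, cell-center-averaging and
          linear-exact", {
  vals <- array(0, dim = c(3, 3, 3))
  vals[] <- seq_len(27)
  g <- scalar_grid(c(0, 0, 0), 1, vals)
  ## exactly at a node
  expect_equal(trilinear_sample(g, rbind(c(1, 2, 0))), vals[2, 3, 1])
  ## cell center = mean of the 8 corners
  expect_equal(trilinear_sample(g, rbind(c(0.5, 0.5, 0.5))),
               mean(vals[1:2, 1:2, 1:2]))
  ## exact on a linear field f = 2x - y + 0.5 z
  f <- function(p) 2 * p[, 1] - p[, 2] + 0.5 * p[, 3]
  nodes <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4))[, c("x", "y", "z")]
  gl <- scalar_grid(c(0, 0, 0), 1,
                    array(f(as.matrix(expand.grid(0:4, 0:4, 0:4))), dim = c(5, 5, 5)))
  set.seed(9)
  pts <- matrix(runif(60, 0, 4), ncol = 3)
  expect_equal(trilinear_sample(gl, pts), f(pts), tolerance = 1e-12)
  ## out-of-box policy
  expect_error(trilinear_sample(g, rbind(c(-1, 0, 0))), "outside")
  expect_message(v <- trilinear_sample(g, rbind(c(-1, 0.5, 0.5)),
                                       out_of_box = "clamp"), "clamped")
  expect_equal(v, trilinear_sample(g, rbind(c(0, 0.5, 0.5))))
})

test_that("trilinear error on a quadratic field shrinks quadratically with spacing", {
  f <- function(p) p[, 1]^2 + 0.5 * p[, 2]^2 - p[, 3]^2
  errs <- vapply(c(1, 0.5, 0.25), function(sp) {
    ax <- seq(0, 4, by = sp)
    nodes <- as.matrix(expand.grid(ax, ax, ax))
    g <- scalar_grid(c(0, 0, 0), sp,
                     array(f(nodes), dim = rep(length(ax), 3)))
    set.seed(5)
    pts <- matrix(runif(90, 0.1, 3.9), ncol = 3)
    max(abs(trilinear_sample(g, pts) - f(pts)))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3)   # ~4x per halving
  expect_gt(errs[2] / errs[3], 3)
})

test_that("grid-sampled Coulomb field agrees with the analytic PMF on a fine grid", {
  ax <- seq(2, 12, by = 0.2)
  nodes <- as.matrix(expand.grid(ax, ax, ax))
  rn <- sqrt(rowSums(nodes^2))
  Q <- 7.136
  g <- scalar_grid(rep(2, 3), 0.2, array(Q / rn, dim = rep(length(ax), 3)))
  set.seed(13)
  pts <- matrix(runif(150, 4, 10), ncol = 3)
  pf <- grid_pmf(pts, g, charge = 1)
  expect_equal(pf$W, coulomb_pmf(pts, Q = Q)$W, tolerance = 2e-3)
})
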