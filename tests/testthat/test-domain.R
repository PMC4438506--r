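test_that("lattice generation matches brute-force enumeration and regions partition", {
  dx <- 1; R2 <- 4
  sys <- build_particles(domain_spec(dx = dx, R2 = R2))
  ks <- sys$kernel
  ## brute-force: half-integer lattice points with |x| <= R2 + 2h
  n <- 10
  g <- as.matrix(expand.grid(-n:n, -n:n, -n:n)) + 0.5
  r <- sqrt(rowSums(g^2)) * dx
  expect_equal(nrow(sys$positions), sum(r <= R2 + 2 * ks$h))
  ## every particle has exactly one label; labels exhaustive
  expect_false(anyNA(sys$region))
  expect_setequal(as.character(unique(sys$region)), c("solvent", "outer"))
  rr <- sqrt(rowSums(sys$positions^2))
  expect_true(all((sys$region == "outer") == (rr > R2)))
  ## uniform number density 1/dx^3
  expect_equal(sys$d, rep(1, nrow(sys$positions)))
})

test_that("shell domains carve reactive and discard deep-interior points", {
  dx <- 2; R1 <- 10; R2 <- 25
  sys <- build_particles(domain_spec(dx = dx, R2 = R2, R1 = R1))
  rr <- sqrt(rowSums(sys$positions^2))
  h2 <- 2 * sys$kernel$h
  expect_true(all(rr > R1 - h2))
  expect_true(all(rr <= R2 + h2))
  expect_true(all((sys$region == "reactive") == (rr <= R1)))
  ## region partition is independent of particle order (classification is
  ## pointwise): relabeling a permuted copy gives the permuted labels
  set.seed(11)
  perm <- sample(nrow(sys$positions))
  sys2 <- sys
  sys2$positions <- sys$positions[perm, ]
  r2 <- sqrt(rowSums(sys2$positions^2))
  expect_equal(as.character(sys$region)[perm],
               ifelse(r2 > R2, "outer", ifelse(r2 <= R1, "reactive", "solvent")))
  ## degenerate domain errors
  expect_error(build_particles(domain_spec(dx = 40, R2 = 10)), "degenerate")
})

test_that("find_neighbors agrees with the O(N^2) oracle and is symmetric", {
  set.seed(7)
  pos <- matrix(runif(500 * 3, 0, 10), ncol = 3)
  cutoff <- 2.3
  nb <- find_neighbors(pos, cutoff)
  ref <- brute_neighbors(pos, cutoff)
  ord <- order(nb$i, nb$j)
  expect_equal(nb$i[ord], ref$i)
  expect_equal(nb$j[ord], ref$j)
  ## symmetry: (i,j) present iff (j,i) present
  key <- paste(nb$i, nb$j)
  rkey <- paste(nb$j, nb$i)
  expect_setequal(key, rkey)
  ## no self pairs, distances correct
  expect_true(all(nb$i != nb$j))
  d <- sqrt(rowSums((pos[nb$i, ] - pos[nb$j, ])^2))
  expect_equal(nb$r, d)
})

test_that("pairs beyond the cutoff are excluded", {
  h <- 1.3
  pos <- rbind(c(0, 0, 0), c(2.7 * h, 0, 0))
  nb <- find_neighbors(pos, 2 * h)
  expect_length(nb$i, 0)
  nb2 <- find_neighbors(rbind(c(0, 0, 0), c(1.9 * h, 0, 0)), 2 * h)
  expect_length(nb2$i, 2)
  expect_error(ensure_neighbors(build_particles(domain_spec(1, 4)), cutoff = 1),
               "below the kernel support")
})

test_that("reactive patches relabel obstacle particles inside the sphere union", {
  ## spherical obstacle R = 20 with one probe sphere of radius 6 on its surface
  sys <- build_particles(domain_spec(dx = 1, R2 = 35, R1 = 20, reactive = "none"))
  expect_true(any(sys$region == "molecule"))
  center <- c(0, 0, 20)
  sys2 <- build_reactive_patch(sys, center, 6)
  relabeled <- which(sys2$region == "reactive")
  expect_gt(length(relabeled), 0)
  ## every relabeled particle is a former obstacle point inside the sphere
  dd <- sqrt(rowSums(sweep(sys2$positions[relabeled, , drop = FALSE], 2, center)^2))
  expect_true(all(dd <= 6))
  expect_true(all(sys$region[relabeled] == "molecule"))
  ## no non-patch obstacle particle was touched
  expect_equal(sum(sys2$region == "molecule") + length(relabeled),
               sum(sys$region == "molecule"))
  ## patch sphere disjoint from the obstacle -> empty-patch error
  expect_error(build_reactive_patch(sys, c(0, 0, 40), 5), "empty reactive patch")
  ## no obstacle at all -> error
  ball <- build_particles(domain_spec(dx = 1, R2 = 10))
  expect_error(build_reactive_patch(ball, c(0, 0, 0), 3), "no obstacle")
})

test_that("gorge patch recipe reproduces the reference sphere ladder", {
  p1 <- gorge_patch_spheres(1)
  expect_equal(p1$radii, c(12, 9, 6, 6, 6, 6))
  expect_equal(p1$centers[, 3], c(16.6, 13.6, 10.6, 7.6, 4.6, 1.6))
  p4 <- gorge_patch_spheres(4, origin = c(1, 2, 3), axis = c(1, 0, 0))
  expect_equal(nrow(p4$centers), 3)
  expect_equal(p4$centers[, 1] - 1, c(7.6, 4.6, 1.6))
  expect_equal(p4$radii, c(6, 6, 6))
})
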