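test_that("kernel has compact support, the hand-computed values, and continuity", {
  ks <- kernel_spec(h = 10)
  expect_equal(ks$support_radius, 20)
  # hand-evaluated spline values
  expect_equal(kernel_value(0, ks), 10 / (7 * pi * 100), tolerance = 1e-12)
  expect_equal(kernel_value(10, ks), 0.25 * 10 / (7 * pi * 100),
               tolerance = 1e-12)
  expect_identical(kernel_value(20, ks), 0)
  expect_identical(kernel_value(25, ks), 0)
  expect_true(all(kernel_value(seq(0, 30, by = 0.1), ks) >= 0))
  # continuity at the branch points q = 1 and q = 2
  eps <- 1e-10
  expect_equal(kernel_value(10 - eps, ks), kernel_value(10 + eps, ks),
               tolerance = 1e-8)
  expect_equal(kernel_value(20 - eps, ks), kernel_value(20 + eps, ks),
               tolerance = 1e-8)
  expect_error(kernel_value(-1, ks), "non-negative")
  expect_error(kernel_spec(h = 0), "positive")
})

test_that("kernel integrates to one over the plane for any h", {
  for (h in c(0.75, 5, 10)) {
    ks <- kernel_spec(h = h)
    I <- integrate(function(r) kernel_value(r, ks) * 2 * pi * r, 0, 2 * h,
                   rel.tol = 1e-10)$value
    expect_equal(I, 1, tolerance = 1e-6)
  }
  # the raw printed constant does not integrate to one (off by (7 pi / 10)^2)
  kp <- kernel_spec(h = 10, normalization = "printed")
  Ip <- integrate(function(r) kernel_value(r, kp) * 2 * pi * r, 0, 20,
                  rel.tol = 1e-10)$value
  expect_equal(Ip, (7 * pi / 10)^2, tolerance = 1e-6)
})

test_that("kernel gradient matches a central-difference oracle and is antisymmetric", {
  ks <- kernel_spec(h = 10)
  expect_identical(kernel_gradient(c(0, 0), ks), c(0, 0))
  expect_identical(kernel_gradient(c(25, 3), ks), c(0, 0))
  for (rv in list(c(5, 0), c(3, 4), c(-8, 11), c(14, -9))) {
    g <- kernel_gradient(rv, ks)
    expect_equal(g, oracle_kernel_gradient(rv, ks), tolerance = 1e-5)
    expect_equal(g, -kernel_gradient(-rv, ks), tolerance = 1e-14)
  }
  # matrix input
  m <- rbind(c(5, 0), c(0, 0), c(30, 0))
  gm <- kernel_gradient(m, ks)
  expect_equal(dim(gm), c(3, 2))
  expect_equal(gm[2, ], c(0, 0))
})

test_that("density summation matches the brute-force oracle", {
  ks <- kernel_spec(h = 10)
  # isolated particle: self term only
  expect_equal(sph_density(0, 0, 2, ks), 2 * kernel_value(0, ks))
  # two particles beyond the support radius: no cross term
  rho2 <- sph_density(c(0, 25), c(0, 0), 1, ks)
  expect_equal(rho2, rep(kernel_value(0, ks), 2))
  # three collinear particles at 0, h, 2h
  x <- c(0, 10, 20)
  expect_equal(sph_density(x, c(0, 0, 0), 1, ks),
               oracle_density(x, c(0, 0, 0), 1, ks), tolerance = 1e-12)
  # 50 random particles, mixed masses
  set.seed(42)
  x <- runif(50, 0, 40); y <- runif(50, 0, 40); m <- runif(50, 0.5, 2)
  expect_equal(sph_density(x, y, m, ks), oracle_density(x, y, m, ks),
               tolerance = 1e-12)
  expect_true(all(sph_density(x, y, m, ks) > 0))
  expect_error(sph_density(numeric(0), numeric(0)), "at least one")
})

test_that("continuity density rate matches finite differences of summation density", {
  ks <- kernel_spec(h = 10)
  set.seed(11)
  n <- 20
  x <- runif(n, 0, 30); y <- runif(n, 0, 30)
  vx <- runif(n, -1, 1); vy <- runif(n, -1, 1)
  drho <- sph_density_rate(x, y, vx, vy, 1, ks)
  eps <- 1e-6
  rho_p <- sph_density(x + eps * vx, y + eps * vy, 1, ks)
  rho_m <- sph_density(x - eps * vx, y - eps * vy, 1, ks)
  expect_equal(drho, (rho_p - rho_m) / (2 * eps), tolerance = 1e-6)
})

test_that("equation of state is compression-only, linear, and monotone", {
  eos <- eos_params(k = 10, rho0 = 2.8)
  expect_identical(eos_pressure(2.8, eos), 0)
  expect_identical(eos_pressure(1.4, eos), 0)
  expect_equal(eos_pressure(2 * 2.8, eos), 10 * 2.8)
  rho <- seq(0.01, 3 * 2.8, length.out = 200)
  expect_true(all(diff(eos_pressure(rho, eos)) >= 0))
  expect_error(eos_params(k = -1), "non-negative")
  expect_error(eos_params(rho0 = 0), "positive")
  expect_error(eos_pressure(0, eos), "positive")
})

test_that("repulsion matches the pairwise oracle and conserves momentum", {
  ks <- kernel_spec(h = 10)
  eos <- eos_params(k = 5, rho0 = 1e-4)
  # isolated particle: no force
  rho1 <- sph_density(0, 0, 1, ks)
  expect_equal(sph_repulsion(0, 0, 1, rho1, eos_pressure(rho1, eos), ks),
               matrix(0, 1, 2))
  # two identical particles at distance h on the x axis: equal and opposite,
  # pushed apart
  x <- c(0, 10); y <- c(0, 0)
  rho <- sph_density(x, y, 1, ks)
  P <- eos_pressure(rho, eos)
  a <- sph_repulsion(x, y, 1, rho, P, ks)
  expect_lt(a[1, 1], 0)
  expect_equal(a[1, ], -a[2, ], tolerance = 1e-14)
  expect_equal(a[1, 2], 0)
  # clusters up to 50 particles vs the oracle; Newton's third law
  set.seed(7)
  for (n in c(5, 50)) {
    x <- runif(n, 0, 15); y <- runif(n, 0, 15)
    m <- runif(n, 0.5, 2)
    rho <- sph_density(x, y, m, ks)
    P <- eos_pressure(rho, eos_params(k = 5, rho0 = 1e-4))
    a <- sph_repulsion(x, y, m, rho, P, ks)
    expect_equal(a, oracle_repulsion(x, y, m, rho, P, ks), tolerance = 1e-10)
    net <- colSums(a * m)
    expect_lt(max(abs(net)), 1e-10 * max(abs(a * m)))
  }
})

test_that("gaussian pair force reference is repulsive and kernel-weighted", {
  ks <- kernel_spec(h = 10)
  f <- gaussian_pair_force(c(5, 0), c(0, 0), 1, 1, 2, 2, 1, 1, ks)
  expect_gt(f[1], 0)   # pushes j away from i
  expect_equal(f[2], 0)
  # vanishes beyond the support radius
  expect_equal(gaussian_pair_force(c(25, 0), c(0, 0), 1, 1, 2, 2, 1, 1, ks),
               c(0, 0))
})
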