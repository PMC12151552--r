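test_that("positive-half Gauss-Legendre rules match independent references", {
  r1 <- gauss_legendre_positive(1)
  expect_equal(r1$roots, 1 / sqrt(3), tolerance = 1e-14)
  expect_equal(r1$weights, 1, tolerance = 1e-14)

  # independent oracle: Newton iteration on P4 for the 4-point rule
  p4 <- function(x) (35 * x^4 - 30 * x^2 + 3) / 8
  dp4 <- function(x) (140 * x^3 - 60 * x) / 8
  newton <- function(x) { for (i in 1:60) x <- x - p4(x) / dp4(x); x }
  roots <- sort(newton(c(0.35, 0.85)))
  w <- 2 / ((1 - roots^2) * dp4(roots)^2)
  r2 <- gauss_legendre_positive(2)
  expect_equal(r2$roots, roots, tolerance = 1e-12)
  expect_equal(r2$weights, w, tolerance = 1e-12)
  expect_equal(sum(r2$weights), 1, tolerance = 1e-14)

  # polynomial exactness: integral of x^2 over [-1,1] via symmetric doubling
  r8 <- gauss_legendre_positive(8)
  expect_equal(2 * sum(r8$weights * r8$roots^2), 2 / 3, tolerance = 1e-14)
  expect_true(all(diff(r8$roots) > 0) && all(r8$roots > 0 & r8$roots < 1))
})

test_that("harmonic certification detects true and false design strengths", {
  f <- withr::local_tempfile()
  write.table(octahedron_points(), f, row.names = FALSE, col.names = FALSE)
  oct <- load_spherical_design(f)
  expect_equal(oct$m_hemisphere, 3)
  expect_equal(oct$strength, 3)
  expect_lt(as.numeric(validate_design(oct, 3)), 1e-12)
  expect_gt(as.numeric(validate_design(oct, 4)), 1e-3)

  write.table(icosahedron_points(), f, row.names = FALSE, col.names = FALSE)
  ico <- load_spherical_design(f)
  expect_equal(ico$m_hemisphere, 6)
  expect_equal(ico$strength, 5)

  # a single stored point stands for the antipodal pair, which handles
  # degree 1 exactly but fails degree 2
  one <- glst:::new_spherical_rule(rbind(c(0, 0, 1)), 1, 1L, "design")
  expect_lt(as.numeric(validate_design(one, 1)), 1e-15)
  expect_gt(as.numeric(validate_design(one, 2)), 0.1)

  # non-unit point is a format error; unpaired full-sphere point a symmetry error
  write.table(rbind(c(0.5, 0, 0)), f, row.names = FALSE, col.names = FALSE)
  expect_error(load_spherical_design(f), "format error")
  write.table(octahedron_points()[-1, ], f, row.names = FALSE,
              col.names = FALSE)
  expect_error(load_spherical_design(f), "symmetry error")
})

test_that("product angular rules are exact through their stated degree", {
  for (t in c(3, 8, 15)) {
    rule <- spherical_product_rule(t)
    expect_lt(as.numeric(validate_design(rule, t)), 1e-12)
    expect_equal(sum(rule$weights), 1, tolerance = 1e-13)
    expect_true(all(abs(sqrt(rowSums(rule$points^2)) - 1) < 1e-12))
  }
  # strength is tight at the next even degree
  expect_gt(as.numeric(validate_design(spherical_product_rule(7), 8)), 1e-6)
})

test_that("the design generator reproduces small equal-weight designs", {
  des <- generate_spherical_design(3, n_points_hint = 3, seed = 0)
  expect_equal(des$m_hemisphere, 3)
  expect_lt(as.numeric(validate_design(des, 3)), 1e-9)
  # a 3-point symmetric 3-design is a rotated octahedron: mutually orthogonal
  gram <- abs(des$points %*% t(des$points))
  expect_equal(gram, diag(3), tolerance = 1e-6)
  # determinism
  des2 <- generate_spherical_design(3, n_points_hint = 3, seed = 0)
  expect_identical(des$points, des2$points)
})

test_that("fused cubature nodes and weights follow the declared formulas", {
  rule <- gauss_legendre_positive(3)
  des <- spherical_product_rule(6)
  alpha <- 0.5; zeta <- 3
  cub <- build_cubature(alpha, zeta, rule, des)
  expect_equal(cub$n_nodes, 3 * des$m_hemisphere)
  expect_true(all(cub$weights > 0))
  # node magnitudes are 2 alpha zeta s_n
  expect_equal(sort(unique(round(sqrt(rowSums(cub$k^2)), 10))),
               sort(round(2 * alpha * zeta * rule$roots, 10)))
  # degree-0 identity: sum of weights is the fused radial sum, independent
  # of the angular rule
  expect_equal(sum(cub$weights),
               (4 * alpha * zeta / pi) *
                 sum(rule$weights * exp(-zeta^2 * rule$roots^2)),
               tolerance = 1e-13)
  des2 <- spherical_product_rule(12)
  cub2 <- build_cubature(alpha, zeta, rule, des2)
  expect_equal(sum(cub2$weights), sum(cub$weights), tolerance = 1e-13)

  # r -> 0 limit at high order: sum W -> 2 alpha / sqrt(pi)
  cub_hi <- build_cubature(alpha, 6, gauss_legendre_positive(60),
                           spherical_product_rule(3))
  expect_equal(sum(cub_hi$weights), 2 * alpha / sqrt(pi), tolerance = 1e-10)
})

test_that("calibration certifies the erf kernel over its distance range", {
  cal <- calibrate_cubature(6.4, 33.3, 0.38, 1e-5)
  expect_lte(cal$certified_error, 1e-5)
  expect_lte(cal$certified_force_error, 2e-5)
  # independent probe resample stays within 2 epsilon
  expect_lte(verify_cubature(cal, seed = 101), 2e-5)

  # kernel matches erf(alpha r)/r on random draws inside the range
  set.seed(21)
  for (i in 1:25) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    r <- runif(1, 6.4, 33.3)
    expect_lt(abs(naive_kernel(cal$cubature, r * u) -
                    pracma::erf(0.38 * r) / r), 1.5 * cal$certified_error)
  }

  # rotation invariance within tolerance
  Rm <- glst:::rotation_matrix(c(1, -2, 0.5), 0.9)
  cub_rot <- cal$cubature
  cub_rot$k <- cub_rot$k %*% t(Rm)
  for (i in 1:10) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    p <- runif(1, 6.4, 33.3) * u
    expect_lt(abs(naive_kernel(cub_rot, p) - naive_kernel(cal$cubature, p)),
              2 * cal$certified_error)
  }

  # loose threshold certifies with minimal effort
  cal_loose <- calibrate_cubature(6.4, 33.3, 0.38, 0.5)
  expect_lte(cal_loose$certified_error, 0.5)
  expect_lt(cal_loose$n_nodes, cal$n_nodes)

  # zeta truncation rule
  expect_lte(exp(-cal$zeta^2), 1e-6 * (1 + 1e-12))
  expect_error(calibrate_cubature(10, 5, 0.3, 1e-4), "d_min < d_max")
})

test_that("fast polar probe evaluation agrees with direct node summation", {
  cal <- calibrate_cubature(3, 12, 0.8, 1e-3)
  dirs <- rbind(c(1, 0, 0), c(0.6, 0.8, 0), c(1, 2, -2) / 3)
  nr <- 7; r0 <- 3; dr <- 1.2
  fast <- glst:::cpp_kernel_probe_radial(cal$cubature$k, cal$cubature$weights,
                                         dirs, r0, dr, nr, TRUE)
  pts <- dirs[rep(1:3, each = nr), ] * rep(r0 + dr * (0:(nr - 1)), 3)
  direct <- glst:::cpp_kernel_probe(cal$cubature$k, cal$cubature$weights,
                                    pts, TRUE)
  expect_equal(fast$value, direct$value, tolerance = 1e-11)
  expect_equal(fast$grad, direct$grad, tolerance = 1e-10)
})
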