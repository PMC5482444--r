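test_that("mode count and update interval derive from (T, L, ell)", {
  fp <- field_params(1000, 20)
  expect_equal(fp$p_star, 5L)
  expect_equal(fp$dt_c, 10)
  expect_warning(field_params(100, 30), "not an integer")
  expect_equal(suppressWarnings(field_params(100, 30))$p_star, 3L)
})

test_that("the field starts from zero weights and equilibrates to stationarity", {
  fp <- field_params(100, 20)
  cold <- init_field(fp, seed = 1, t_eq = 0)
  expect_equal(cold$X, numeric(5))
  expect_equal(concentration(cold, fp, seq(0, 99)), numeric(100))

  # stationary per-weight variance ~ 1/p_star (with the small AR(1)
  # discretization correction), pooled over all weights of a long run
  run <- chemoevolve:::cpp_field_series(100, 1, 5, 42, 200, 1e5)
  v <- var(as.vector(run$weights))
  v_exact <- (2 * 1 / (100 * 5)) / (1 - (1 - 1 / 100)^2)
  expect_equal(v_exact, 1 / 5 / (1 - 1 / 200), tolerance = 1e-12)
  expect_lt(abs(v - v_exact) / v_exact, 0.05)
})

test_that("weight dynamics are AR(1) with correlation time T", {
  run <- chemoevolve:::cpp_field_series(100, 1, 2, 7, 200, 2e4)
  w <- run$weights
  rho <- 1 - 1 / 100
  for (j in 1:2) {
    a <- acf(w[, j], lag.max = 10, plot = FALSE)$acf
    expect_equal(a[2], rho, tolerance = 0.05)
    expect_equal(a[11], rho^10, tolerance = 0.15)
  }
  # distinct modes are driven by independent noise
  expect_lt(abs(cor(w[, 1], w[, 2])), 0.15)
  expect_lt(abs(cor(w[, 1], w[, 3])), 0.15)
})

test_that("explicit-noise update reproduces the AR(1) recursion exactly", {
  fp <- field_params(200, 50)  # p_star = 2
  st <- init_field(fp, seed = 3, t_eq = 0)
  eta <- matrix(c(1.3, -0.4, 0.2, 2.2), nrow = 1)
  st2 <- update_field(st, fp, noise = eta)
  sdv <- sqrt(2 * fp$dt_c / (fp$T_corr * fp$p_star))
  expect_equal(st2$X, c(1.3, -0.4) * sdv)
  expect_equal(st2$Y, c(0.2, 2.2) * sdv)
  st3 <- update_field(st2, fp, noise = matrix(0, 1, 4))
  expect_equal(st3$X, st2$X * (1 - fp$dt_c / fp$T_corr))
  expect_equal(st3$t, 2 * fp$dt_c)
})

test_that("concentration is the clipped Fourier sum", {
  fp <- field_params(100, 100) # single mode
  st <- init_field(fp, 1, t_eq = 0)
  st$X <- 1
  expect_equal(concentration(st, fp, 0), 1)
  expect_equal(concentration(st, fp, 50), 0)  # cos(pi) = -1, clipped
  expect_equal(concentration(st, fp, 50, clip = FALSE), -1)
  expect_equal(concentration(st, fp, 125), concentration(st, fp, 25))
})

test_that("field realizations are bit-identical given the same seed", {
  a <- chemoevolve:::cpp_field_series(1000, 10, 5, 123, 200, 50)
  b <- chemoevolve:::cpp_field_series(1000, 10, 5, 123, 200, 50)
  expect_identical(a$weights, b$weights)
  c <- chemoevolve:::cpp_field_series(1000, 10, 5, 124, 200, 50)
  expect_false(identical(a$weights, c$weights))
})

test_that("spatial covariance and clipped mean match the stationary theory", {
  # thinned snapshots of a long stationary run (about one correlation time
  # apart), evaluated on a position grid
  fp <- field_params(100, 20)
  run <- chemoevolve:::cpp_field_series(100, 1, 5, 2024, 200, 5e4)
  idx <- seq(100, 5e4, by = 100)
  xs <- 0:99
  raw <- sapply(idx, function(i)
    chemoevolve:::cpp_conc1d(run$weights[i, 1:5], run$weights[i, 6:10],
                             100, xs, FALSE))
  # empirical covariance at separations d vs (1/p*) sum cos(2 pi p d / ell)
  for (d in c(0, 5, 10, 20, 50)) {
    emp <- mean(raw * raw[((xs + d) %% 100) + 1, ])
    expect_equal(emp, field_spatial_covariance(d, 5, 100), tolerance = 0.08)
  }
  # clipped mean ~ E max(0, N(0,1)) = 1/sqrt(2 pi), independent of T and L
  expect_equal(mean(pmax(raw, 0)), 1 / sqrt(2 * pi), tolerance = 0.03)
})

test_that("3D field is real, isotropic in construction, and plane-wave for one mode", {
  fp <- field_params(1000, 20)
  f3 <- make_field_3d(fp, seed = 5)
  expect_length(f3$X3, 125)
  expect_true(all(is.finite(c(f3$X3, f3$Y3))))
  # total variance ~ 1 by the p*^(-3/2) weight scaling
  set.seed(31)
  pts <- matrix(runif(3000, 0, 100), ncol = 3)
  cc <- field3d_concentration(f3, pts[, 1], pts[, 2], pts[, 3])
  expect_equal(var(cc), 1, tolerance = 0.35)

  # single (1,1,1) mode: constant on planes x + y + z = const
  f1 <- f3
  f1$X3 <- numeric(125); f1$Y3 <- numeric(125)
  f1$X3[1] <- 1  # mode (p,q,r) = (1,1,1)
  v1 <- field3d_concentration(f1, 10, 20, 30)
  v2 <- field3d_concentration(f1, 15, 25, 20) # same x+y+z
  v3 <- field3d_concentration(f1, 11, 20, 30)
  expect_equal(v1, v2)
  expect_false(isTRUE(all.equal(v1, v3)))
  expect_equal(v1, cos(2 * pi * 60 / 100))
})

test_that("step environment switches at the stated times", {
  env <- step_environment(1, 50, 350)
  expect_equal(env_concentration(env, 10, 49), 0)
  expect_equal(env_concentration(env, 10, 50), 1)
  expect_equal(env_concentration(env, 10, 349.9), 1)
  expect_equal(env_concentration(env, 10, 350), 0)
  expect_equal(env_concentration(step_environment(0, 50, 350), 0, 100), 0)
})

test_that("two-Gaussian world oscillates in antiphase with period 5000", {
  env <- two_gaussian_environment()
  # full amplitude on the left peak at theta = 0
  expect_equal(env_concentration(env, 25, 0), 1)
  expect_lt(env_concentration(env, 75, 0), 1e-10)
  # quarter period: both amplitudes 0.5
  expect_equal(env_concentration(env, 25, 1250), 0.5)
  expect_equal(env_concentration(env, 75, 1250), 0.5, tolerance = 1e-10)
  # half period: roles swapped
  expect_equal(env_concentration(env, 75, 2500), 1)
  # periodicity
  xs <- seq(0, 99, by = 7)
  expect_equal(env_concentration(env, xs, 637),
               env_concentration(env, xs, 637 + 5000))
  # periodic wrapping of the bumps
  expect_equal(env_concentration(env, 0, 0), env_concentration(env, 100, 0))
})
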