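test_that("analytic kernel masses are exact", {
  m <- sim_kernel_masses(kernel_single())
  expect_equal(m$trigger_mass, 0.2)
  expect_equal(m$background_rate, 5.71)
  m2 <- sim_kernel_masses(kernel_multi())
  expect_equal(m2$trigger_mass, 0.5)
  zero <- sim_kernel(5, 1, 0, 0, components = tibble::tibble(
    theta = 0, omega = 1, sigma_x = 1, sigma_y = 1))
  expect_equal(sim_kernel_masses(zero)$trigger_mass, 0)
})

test_that("simulation is reproducible and time-sorted", {
  reg <- spatial_region(0, 20, 0, 20)
  a <- simulate_catalog(kernel_single(), target_n = 500, region = reg,
                        trim = 100, seed = 7)
  b <- simulate_catalog(kernel_single(), target_n = 500, region = reg,
                        trim = 100, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 500)
  expect_true(all(diff(a$t) > 0))
  expect_true(all(a$x >= 0 & a$x <= 20 & a$y >= 0 & a$y <= 20))
  expect_equal(a$t[1], 0)
  expect_error(simulate_catalog(kernel_single(), target_n = 100, region = reg,
                                trim = 100, seed = 1), NA)
})

test_that("a zero-mass kernel reduces to a Poisson stream in time", {
  reg <- spatial_region(-50, 50, -50, 50) # capture essentially all the mass
  kern <- sim_kernel(mu_bar = 8, sigma_mu = 3, c = 0, d = 0,
                     components = tibble::tibble(theta = 0, omega = 1,
                                                 sigma_x = 1, sigma_y = 1))
  cat0 <- simulate_catalog(kern, target_n = 2000, region = reg, trim = 200,
                           seed = 21)
  # inter-event gaps of a homogeneous Poisson stream are iid exponential
  gaps <- diff(cat0$t)
  ks <- stats::ks.test(gaps, "pexp", rate = 1 / mean(gaps))
  expect_gt(ks$p.value, 0.01)
  # and the empirical rate is close to mu_bar
  expect_lt(abs(nrow(cat0) / max(cat0$t) - 8) / 8, 0.1)
})

test_that("the offspring law matches the branching construction", {
  reg <- spatial_region(0, 20, 0, 20)
  cat1 <- simulate_catalog(kernel_single(), target_n = 6000, region = reg,
                           trim = 500, seed = 31, genealogy = TRUE)
  gen <- attr(cat1, "genealogy")
  expect_false(is.null(gen))
  t_max <- max(gen$t)
  # direct-offspring counts, for parents far enough from the horizon that
  # censoring of Exp(0.1) lags is negligible
  counts <- tabulate(gen$parent[gen$parent > 0], nbins = max(gen$id))
  interior <- gen$id[gen$t < t_max - 80]
  n_par <- length(interior)
  expect_gt(n_par, 5000)
  mean_off <- mean(counts[interior])
  expect_lt(abs(mean_off - 0.2), 3 * sqrt(0.2 / n_par))

  # offspring time lags are Exp(omega)
  child <- gen[gen$parent > 0, ]
  lag <- child$t - gen$t[match(child$parent, gen$id)]
  expect_gt(length(lag), 1000)
  ks <- stats::ks.test(lag, "pexp", rate = 0.1)
  expect_gt(ks$p.value, 0.01)
})

test_that("long-run event rate follows the branching identity", {
  reg <- spatial_region(0, 20, 0, 20)
  rates <- vapply(1:5, function(s) {
    cat1 <- simulate_catalog(kernel_single(), target_n = 3000, region = reg,
                             trim = 500, seed = 40 + s)
    nrow(cat1) / max(cat1$t)
  }, numeric(1))
  in_frac <- (pnorm(20, 10, 4.5) - pnorm(0, 10, 4.5))^2
  expected <- 5.71 * in_frac / (1 - 0.2)
  expect_lt(abs(mean(rates) - expected) / expected, 0.05)
})

test_that("correlated kernels produce correlated offspring offsets", {
  kern <- sim_kernel(mu_bar = 5.71, sigma_mu = 4.5, c = 10, d = 10, rho = 0.5,
                     components = tibble::tibble(theta = 0.3, omega = 0.2,
                                                 sigma_x = 0.1, sigma_y = 0.1))
  reg <- spatial_region(0, 20, 0, 20)
  cat1 <- simulate_catalog(kern, target_n = 5000, region = reg, trim = 300,
                           seed = 51, genealogy = TRUE)
  gen <- attr(cat1, "genealogy")
  child <- gen[gen$parent > 0, ]
  pidx <- match(child$parent, gen$id)
  r <- stats::cor(child$x - gen$x[pidx], child$y - gen$y[pidx])
  n <- nrow(child)
  expect_lt(abs(r - 0.5), 3 * (1 - 0.5^2) / sqrt(n))
  # the immigrant locations are correlated too
  imm <- gen[gen$parent == 0, ]
  r_imm <- stats::cor(imm$x, imm$y)
  expect_lt(abs(r_imm - 0.5), 3 * (1 - 0.5^2) / sqrt(nrow(imm)))
})

test_that("homogeneous simulation has Poisson counts and uniform locations", {
  reg <- spatial_region(0, 5, 0, 2)
  win <- time_window(0, 5)
  expect_equal(nrow(simulate_homogeneous(0, reg, win, seed = 1)), 0)

  counts <- vapply(1:20, function(s) {
    nrow(simulate_homogeneous(2, reg, win, seed = 60 + s))
  }, numeric(1))
  # pooled count ~ Poisson(20 * 100)
  expect_lt(abs(sum(counts) - 2000), 3 * sqrt(2000))

  pooled <- dplyr::bind_rows(lapply(1:50, function(s) {
    simulate_homogeneous(1, reg, win, seed = 100 + s)
  }))
  grid_id <- paste(findInterval(pooled$x, seq(0, 5, length.out = 5),
                                rightmost.closed = TRUE),
                   findInterval(pooled$y, seq(0, 2, length.out = 5),
                                rightmost.closed = TRUE))
  chi <- stats::chisq.test(table(grid_id))
  expect_gt(chi$p.value, 0.01)
})

test_that("residual superposition thins a dominating homogeneous process", {
  reg <- spatial_region(0, 4, 0, 4)
  win <- time_window(0, 10)
  # flat model intensity: a wide Gaussian is effectively constant on S
  flat <- function(level) {
    model_spec(bg_params(a = level, c = 2, d = 2, alpha = 1e-12, beta = 1e-12),
               trig_params(1e-14, 1, 1, 1))
  }
  empty <- event_catalog(numeric(0), numeric(0), numeric(0))
  # lambda_hat >= k everywhere: nothing superposed
  expect_equal(nrow(simulate_residual_superposition(flat(5), empty, 2, reg,
                                                    win, seed = 1)), 0)
  # lambda_hat ~ 0: reduces to the homogeneous process at rate k
  n0 <- vapply(1:10, function(s) {
    nrow(simulate_residual_superposition(flat(1e-9), empty, 2, reg, win,
                                         seed = 200 + s))
  }, numeric(1))
  expect_lt(abs(sum(n0) - 10 * 2 * 16 * 10), 3 * sqrt(10 * 2 * 16 * 10))
  # lambda_hat = k / 2: mean count (k/2) |S| |D|
  nh <- vapply(1:10, function(s) {
    nrow(simulate_residual_superposition(flat(1), empty, 2, reg, win,
                                         seed = 300 + s))
  }, numeric(1))
  expect_lt(abs(sum(nh) - 10 * 160), 3 * sqrt(10 * 160))
})

test_that("supercritical kernels are rejected", {
  bad <- sim_kernel(5, 1, 0, 0, components = tibble::tibble(
    theta = 1.1, omega = 1, sigma_x = 1, sigma_y = 1))
  expect_error(simulate_catalog(bad, 100, spatial_region(0, 1, 0, 1),
                                trim = 0, seed = 1), "supercritical")
})

test_that("fitted models convert to simulation kernels with matching masses", {
  model <- truth_model_single()
  kern <- as_sim_kernel(model)
  m <- sim_kernel_masses(kern)
  expect_equal(m$background_rate, 5.71, tolerance = 1e-12)
  expect_equal(m$trigger_mass, 0.2, tolerance = 1e-12)
  expect_equal(kern$trigger$omega, 0.1)
  expect_equal(kern$trigger$sigma_x, 0.01)
})
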