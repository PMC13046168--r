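flat_model <- function(level) {
  model_spec(bg_params(a = level, c = 2, d = 2, alpha = 1e-12, beta = 1e-12),
             trig_params(1e-14, 1, 1, 1))
}

test_that("thinning keeps, drops and halves as the retention law dictates", {
  cat1 <- toy_catalog(2000, region = spatial_region(0, 4, 0, 4), t_max = 100,
                      seed = 211)
  lam <- rep(3, 2000)
  expect_identical(thin_events(cat1, lam, 3, seed = 1), cat1)
  expect_equal(nrow(thin_events(cat1, lam, 0, seed = 1)), 0)
  kept <- nrow(thin_events(cat1, rep(6, 2000), 3, seed = 2))
  expect_lt(abs(kept - 1000), 3 * sqrt(2000 * 0.25))
})

test_that("the super-thinning rate is the domain-averaged intensity", {
  reg <- spatial_region(0, 4, 0, 4)
  win <- time_window(0, 10)
  # pure background capturing the full Gaussian mass
  bg <- bg_params_natural(mu_bar = 7, sigma_x = 0.3, sigma_y = 0.3, c = 2, d = 2)
  model <- model_spec(bg, trig_params(1e-14, 1, 1, 1))
  empty <- event_catalog(numeric(0), numeric(0), numeric(0))
  expect_equal(superthin_rate(model, empty, reg, win), 7 * 10 / (16 * 10),
               tolerance = 1e-6)

  # toy five-event model against direct quadrature of the intensity
  skip_if_not_installed("pracma")
  cat5 <- toy_catalog(5, seed = 212)
  model2 <- model_spec(random_bg(0, seed = 213), random_tr(0, seed = 214))
  k <- superthin_rate(model2, cat5, reg, win)
  k_quad <- oracle_compensator(model2, cat5, reg, win) / (16 * 10)
  expect_equal(k, k_quad, tolerance = 1e-5)

  # linearity in the amplitudes
  model3 <- model_spec(dplyr::mutate(model2$background, a = 2 * a),
                       dplyr::mutate(model2$trigger, b = 2 * b))
  expect_equal(superthin_rate(model3, cat5, reg, win), 2 * k, tolerance = 1e-12)
})

test_that("super-thinning homogenizes under the true model", {
  reg <- spatial_region(0, 4, 0, 4)
  win <- time_window(0, 50)
  # constant intensity equal to k: everything retained, nothing superposed
  cat_c <- toy_catalog(300, region = reg, t_max = 50, seed = 221)
  st <- super_thin(flat_model(1), cat_c, reg, win, k = 1, seed = 3)
  expect_equal(st$combined[, c("t", "x", "y")], cat_c[, c("t", "x", "y")])
  expect_equal(nrow(st$superposed), 0)

  # k far below the intensity: nothing superposed, thinning at rate k/lambda
  st2 <- super_thin(flat_model(10), cat_c, reg, win, k = 1, seed = 4)
  expect_equal(nrow(st2$superposed), 0)
  expect_lt(abs(nrow(st2$retained) - 30), 3 * sqrt(300 * 0.1 * 0.9) + 1)

  # model = generating truth: combined count concentrates around k |S| |D|
  kern <- sim_kernel(mu_bar = 12, sigma_mu = 1.2, c = 2, d = 2, rho = 0,
                     components = tibble::tibble(theta = 0.3, omega = 0.3,
                                                 sigma_x = 0.1, sigma_y = 0.1))
  truth <- model_spec(bg_params_natural(12, 1.2, c = 2, d = 2),
                      trig_params_natural(0.3, 0.3, 0.1, 0.1))
  counts <- vapply(1:5, function(s) {
    cat_s <- simulate_catalog(kern, target_n = 400, region = reg, trim = 80,
                              seed = 230 + s)
    win_s <- catalog_window(cat_s)
    k_s <- superthin_rate(truth, cat_s, reg, win_s)
    st_s <- super_thin(truth, cat_s, reg, win_s, k = k_s, seed = s)
    nrow(st_s$combined) - k_s * region_area(reg) * window_length(win_s)
  }, numeric(1))
  expect_lt(abs(mean(counts)), 3 * sqrt(400 / 5))
})

test_that("Ripley K matches closed forms and the brute-force oracle", {
  reg1 <- spatial_region(0, 1, 0, 1)
  # two points 0.1 apart at the center of the unit square
  two <- event_catalog(t = c(1, 2), x = c(0.45, 0.55), y = c(0.5, 0.5))
  K <- ripley_k(two, reg1, distances = c(0.05, 0.2))
  expect_equal(K$K, c(0, 0.5))

  # far-apart points: K identically zero
  far <- event_catalog(t = 1:2, x = c(0.1, 0.9), y = c(0.1, 0.9))
  expect_true(all(ripley_k(far, reg1, distances = seq(0, 0.25,
                                                      length.out = 10))$K == 0))
  expect_error(ripley_k(two[1, ], reg1), "at least 2")

  # 30 random points against the brute-force double loop at the same
  # circle discretization (isolates the pair loop and binning)
  cat30 <- toy_catalog(30, region = reg1, seed = 241)
  d <- seq(0, 0.25, length.out = 12)
  K30 <- ripley_k(cat30, reg1, distances = d, n_circle = 8192)
  expect_equal(K30$K, oracle_ripley_k(cat30, reg1, d, n_circ = 8192),
               tolerance = 1e-6)
  # the default 512-point edge weights agree closely with the fine oracle
  K512 <- ripley_k(cat30, reg1, distances = d, n_circle = 512)
  expect_equal(K512$K, K30$K, tolerance = 2e-3)
  # K is nondecreasing in d
  expect_true(all(diff(K30$K) >= 0))
})

test_that("interior point patterns need no edge correction", {
  # tight central cluster: all circles lie inside S, so weights are 1 and
  # K reduces to the unweighted pair count formula
  reg <- spatial_region(0, 10, 0, 10)
  cl <- withr::with_seed(251, event_catalog(t = 1:20, x = 5 + runif(20, -0.3, 0.3),
                                            y = 5 + runif(20, -0.3, 0.3)))
  d <- c(0.1, 0.5, 1)
  K <- ripley_k(cl, reg, distances = d)
  dij <- as.matrix(stats::dist(cbind(cl$x, cl$y)))
  plain <- vapply(d, function(dd) {
    100 * sum(dij[upper.tri(dij)] < dd) * 2 / 400
  }, numeric(1))
  expect_equal(K$K, plain)
})

test_that("centered L transforms K as stated", {
  d <- seq(0, 2, length.out = 20)
  expect_equal(centered_l(pi * d^2, d), rep(0, 20))
  expect_equal(centered_l(rep(0, 20), d), -d)
  expect_error(centered_l(c(-1, 0), c(0, 1)), "nonnegative")

  reg1 <- spatial_region(0, 1, 0, 1)
  cat20 <- toy_catalog(20, region = reg1, seed = 261)
  dd <- seq(0, 0.25, length.out = 8)
  end_to_end <- centered_l(ripley_k(cat20, reg1, dd)$K, dd)
  expect_equal(end_to_end, sqrt(ripley_k(cat20, reg1, dd)$K / pi) - dd)
})

test_that("Monte-Carlo envelopes bracket the Poisson truth", {
  reg <- spatial_region(0, 10, 0, 10)
  win <- time_window(0, 4)
  d <- distance_grid(reg, n = 20)
  env <- mc_envelope(1, reg, win, distances = d, M = 60, seed = 271)
  expect_true(all(env$env_lo <= env$env_hi))
  expect_true(all(env$env_lo[-1] < 0 & env$env_hi[-1] > 0))
  expect_lt(max(abs(env$mean_L[-1] / pmax(d[-1], 0.2))), 0.15)
  expect_error(mc_envelope(1, reg, win, M = 5), "at least 20")

  # positive control: a strongly clustered catalog escapes the envelope
  kern <- sim_kernel(mu_bar = 5, sigma_mu = 2.5, c = 5, d = 5, rho = 0,
                     components = tibble::tibble(theta = 0.5, omega = 1,
                                                 sigma_x = 0.05, sigma_y = 0.05))
  cc <- simulate_catalog(kern, target_n = 400, region = reg, trim = 50,
                         seed = 272)
  rate <- nrow(cc) / (region_area(reg) * max(cc$t))
  envc <- mc_envelope(rate, reg, time_window(0, max(cc$t)), distances = d,
                      M = 60, seed = 273)
  cl <- centered_l(ripley_k(cc, reg, d)$K, d)
  expect_true(any(cl[d < 2 & d > 0] > envc$env_hi[d < 2 & d > 0]))
})

test_that("the full residual diagnostic returns coherent bands", {
  reg <- spatial_region(0, 4, 0, 4)
  kern <- sim_kernel(mu_bar = 12, sigma_mu = 1.2, c = 2, d = 2, rho = 0,
                     components = tibble::tibble(theta = 0.3, omega = 0.3,
                                                 sigma_x = 0.1, sigma_y = 0.1))
  cat1 <- simulate_catalog(kern, target_n = 250, region = reg, trim = 50,
                           seed = 281)
  truth <- model_spec(bg_params_natural(12, 1.2, c = 2, d = 2),
                      trig_params_natural(0.3, 0.3, 0.1, 0.1))
  win <- catalog_window(cat1)
  res <- residual_diagnostics(truth, cat1, reg, win, M = 25, seed = 282)
  expect_s3_class(res, "kl_result")
  expect_true(all(c("d", "K", "L", "centered_L", "env_lo", "env_hi",
                    "st_lo", "st_hi", "mean_L") %in% names(res)))
  expect_true(all(res$env_lo <= res$env_hi))
  expect_true(all(res$st_lo <= res$st_hi))
  expect_gt(attr(res, "rate_k"), 0)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  # temporal uniformity of the super-thinned residuals is acceptable
  st <- super_thin(truth, cat1, reg, win, seed = 283)
  expect_gt(temporal_uniformity_test(st$combined, win)$p.value, 0.001)
})
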