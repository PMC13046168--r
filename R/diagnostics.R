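#' Thin a catalog by intensity
#'
#' Each event is retained independently with probability
#' `min(b / lambda_i, 1)`; under a correctly specified intensity the
#' retained points form a homogeneous Poisson process of rate `b`.
#'
#' @param data Event catalog.
#' @param intensity Positive intensity values at the events (same length).
#' @param b Nonnegative target rate.
#' @param seed Optional integer seed.
#' @return The retained sub-catalog (tibble).
#' @export
thin_events <- function(data, intensity, b, seed = NULL) {
  data <- as_event_catalog(data)
  stopifnot(b >= 0, length(intensity) == nrow(data), all(intensity > 0))
  run <- function() {
    keep <- runif(nrow(data)) < pmin(b / intensity, 1)
    data[keep, , drop = FALSE]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Super-thinning rate
#'
#' The domain-averaged model intensity
#' `k = (1 / (|S| |D|)) * integral of lambda_hat over S x D`, computed
#' exactly from the closed-form compensators.
#'
#' @param model A [model_spec()].
#' @param data Event catalog the model was fitted on.
#' @param region A [spatial_region()].
#' @param window A [time_window()].
#' @return A positive rate (events per km^2 per unit time).
#' @export
superthin_rate <- function(model, data, region, window) {
  (background_compensator(model$background, region, window) +
     trigger_compensator(model$trigger, data, region, window)) /
    (region_area(region) * window_length(window))
}

#' Super-thin a catalog
#'
#' Residuals by super-thinning: events where the model intensity exceeds
#' `k` are thinned with probability `k / lambda_hat`, and an inhomogeneous
#' Poisson process with intensity `max(k - lambda_hat, 0)` is superposed.
#' If the intensity is correctly specified the combined process is
#' homogeneous Poisson with rate `k`.
#'
#' @param model A [model_spec()] (or `hawkes_fit`; its model is used).
#' @param data Event catalog.
#' @param region A [spatial_region()].
#' @param window A [time_window()].
#' @param k Positive rate; defaults to [superthin_rate()].
#' @param seed Optional integer seed.
#' @return An object of class `superthin`: a list with tibbles `retained`,
#'   `superposed`, `combined` (time-sorted union) and the `rate_k` used.
#' @export
super_thin <- function(model, data, region, window, k = NULL, seed = NULL) {
  if (inherits(model, "hawkes_fit")) model <- model$model
  data <- as_event_catalog(data)
  if (is.null(k)) k <- superthin_rate(model, data, region, window)
  stopifnot(k > 0)
  lam <- conditional_intensity(model, data, data$x, data$y, data$t)
  retained <- thin_events(data, lam, k,
                          seed = if (is.null(seed)) NULL else seed)
  superposed <- simulate_residual_superposition(model, data, k, region, window,
                                                seed = if (is.null(seed)) NULL else seed + 1L)
  combined <- bind_rows(retained, superposed)
  combined <- combined[order(combined$t), , drop = FALSE]
  structure(list(retained = retained, superposed = superposed,
                 combined = combined, rate_k = k, seed = seed),
            class = "superthin")
}

#' @export
print.superthin <- function(x, ...) {
  cat(sprintf("<superthin: %d retained + %d superposed = %d residual points, k = %g>\n",
              nrow(x$retained), nrow(x$superposed), nrow(x$combined), x$rate_k))
  invisible(x)
}

#' Default distance grid for K/L functions
#'
#' 50 distances from 0 to a quarter of the shorter region side.
#'
#' @param region A [spatial_region()].
#' @param n Number of grid values.
#' @return A numeric vector.
#' @export
distance_grid <- function(region, n = 50) {
  seq(0, min(region$x_hi - region$x_lo, region$y_hi - region$y_lo) / 4,
      length.out = n)
}

#' Edge-corrected Ripley K function
#'
#' `K(d) = |S| n^-2 sum_{i != j} w_ij^-1 1(d_ij < d)`, where the edge
#' weight `w_ij` is the fraction of the circumference of the circle
#' centered at point i with radius `d_ij` that lies inside the region
#' (computed numerically from `n_circle` evenly spaced points per circle).
#'
#' @param data Event catalog (spatial projection is used); needs >= 2 rows.
#' @param region A [spatial_region()] containing the points.
#' @param distances Nondecreasing distance grid; defaults to
#'   [distance_grid()].
#' @param n_circle Points per circle for the edge weights.
#' @return A tibble with columns `d` and `K`.
#' @export
ripley_k <- function(data, region, distances = distance_grid(region),
                     n_circle = 512) {
  data <- as_event_catalog(data)
  if (nrow(data) < 2) abort("ripley_k needs at least 2 events")
  if (is.unsorted(distances)) abort("distances must be nondecreasing")
  K <- cpp_ripley_k(data$x, data$y, region$x_lo, region$x_hi,
                    region$y_lo, region$y_hi, as.numeric(distances),
                    as.integer(n_circle))
  tibble(d = as.numeric(distances), K = K)
}

#' Centered L function
#'
#' `L(d) - d = sqrt(K(d) / pi) - d`; zero for a homogeneous Poisson
#' process, positive under clustering.
#'
#' @param K Nonnegative K values.
#' @param distances Matching distance grid.
#' @return Numeric vector of centered L values.
#' @export
centered_l <- function(K, distances) {
  if (any(K < 0)) abort("K must be nonnegative")
  sqrt(K / pi) - distances
}

# centered L of a catalog, with the empty/degenerate guard used by the
# Monte-Carlo loops: fewer than 2 points means K = 0 identically
centered_l_of <- function(data, region, distances, n_circle = 512) {
  if (nrow(data) < 2) return(-as.numeric(distances))
  centered_l(ripley_k(data, region, distances, n_circle)$K, distances)
}

#' Monte-Carlo envelope for the centered L function
#'
#' Simulates `M` homogeneous Poisson catalogs at rate `k` over the domain,
#' computes the centered L function of each, and returns the pointwise
#' 2.5% and 97.5% quantiles and the mean.
#'
#' Besides the pointwise band, a simultaneous (global) 95% band is
#' returned: pointwise bands are exceeded somewhere on a 50-point grid by
#' most realizations even under the null, so curve-level pass/fail checks
#' should use the global band, built from the max-studentized-deviation
#' statistic of the replicate curves.
#'
#' @param k Space-time rate of the null homogeneous process.
#' @param region A [spatial_region()].
#' @param window A [time_window()].
#' @param distances Distance grid; defaults to [distance_grid()].
#' @param M Number of replicates (>= 20).
#' @param seed Optional integer seed.
#' @param n_circle Points per circle for the edge weights.
#' @return A tibble with columns `d`, `env_lo`, `env_hi` (pointwise 2.5%
#'   and 97.5% quantiles), `env_lo_global`, `env_hi_global` (simultaneous
#'   95% band) and `mean_L`.
#' @export
mc_envelope <- function(k, region, window, distances = distance_grid(region),
                        M = 100, seed = NULL, n_circle = 512) {
  if (M < 20) abort("M must be at least 20")
  curves <- matrix(0, nrow = M, ncol = length(distances))
  for (m in seq_len(M)) {
    cat_m <- simulate_homogeneous(k, region, window,
                                  seed = if (is.null(seed)) NULL else seed + m)
    curves[m, ] <- centered_l_of(cat_m, region, distances, n_circle)
  }
  mean_L <- colMeans(curves)
  s <- pmax(apply(curves, 2, sd), 1e-12)
  tmax <- apply(abs(sweep(sweep(curves, 2, mean_L), 2, s, "/")), 1, max)
  q95 <- quantile(tmax, 0.95, names = FALSE)
  tibble(d = as.numeric(distances),
         env_lo = apply(curves, 2, quantile, probs = 0.025, names = FALSE),
         env_hi = apply(curves, 2, quantile, probs = 0.975, names = FALSE),
         env_lo_global = mean_L - q95 * s,
         env_hi_global = mean_L + q95 * s,
         mean_L = mean_L)
}

#' Super-thinning residual diagnostics
#'
#' The full diagnostic: super-thin the catalog under the model, compute the
#' centered L function of the residual point pattern (its spatial
#' projection), repeat the super-thinning `M` times for a replicate band
#' and mean curve, and simulate `M` homogeneous Poisson catalogs at the
#' same rate for the null 95% envelope. A model that fits leaves the
#' centered L curve inside the Poisson envelope at all distances.
#'
#' @param model A [model_spec()] or `hawkes_fit`.
#' @param data Event catalog.
#' @param region A [spatial_region()].
#' @param window A [time_window()].
#' @param distances Distance grid; defaults to [distance_grid()].
#' @param M Monte-Carlo replicates for both bands.
#' @param seed Integer seed.
#' @param n_circle Points per circle for the edge weights.
#' @return A tibble of class `kl_result` with columns `d`, `K`, `L`,
#'   `centered_L` (primary super-thinning), `env_lo`, `env_hi`, `mean_L`
#'   (Poisson envelope and super-thinned mean), `st_lo`, `st_hi`
#'   (super-thinned replicate band); attributes `rate_k` and `M`.
#' @export
residual_diagnostics <- function(model, data, region, window,
                                 distances = distance_grid(region),
                                 M = 100, seed = 1, n_circle = 512) {
  if (inherits(model, "hawkes_fit")) model <- model$model
  data <- as_event_catalog(data)
  k <- superthin_rate(model, data, region, window)

  st <- super_thin(model, data, region, window, k = k, seed = seed)
  kl <- ripley_k(st$combined, region, distances, n_circle)
  cl <- centered_l(kl$K, distances)

  st_curves <- matrix(0, nrow = M, ncol = length(distances))
  st_curves[1, ] <- cl
  for (m in seq_len(M)[-1]) {
    rep_m <- super_thin(model, data, region, window, k = k,
                        seed = seed + 13L * m)
    st_curves[m, ] <- centered_l_of(rep_m$combined, region, distances, n_circle)
  }
  env <- mc_envelope(k, region, window, distances, M = M,
                     seed = seed + 13L * M + 1L, n_circle = n_circle)

  out <- tibble(d = as.numeric(distances), K = kl$K, L = sqrt(kl$K / pi),
                centered_L = cl,
                env_lo = env$env_lo, env_hi = env$env_hi,
                env_lo_global = env$env_lo_global,
                env_hi_global = env$env_hi_global,
                st_lo = apply(st_curves, 2, quantile, probs = 0.025, names = FALSE),
                st_hi = apply(st_curves, 2, quantile, probs = 0.975, names = FALSE),
                mean_L = colMeans(st_curves))
  attr(out, "rate_k") <- k
  attr(out, "M") <- M
  class(out) <- c("kl_result", class(out))
  out
}

#' Temporal homogeneity check of a residual catalog
#'
#' Kolmogorov-Smirnov test of the residual event times against the uniform
#' distribution on the window: a convenience companion to the spatial K/L
#' diagnostics.
#'
#' @param data Event catalog.
#' @param window A [time_window()].
#' @return The `htest` object from [stats::ks.test()].
#' @export
temporal_uniformity_test <- function(data, window) {
  data <- as_event_catalog(data)
  stats::ks.test((data$t - window$t_lo) / window_length(window), "punif")
}

# ---- plots ------------------------------------------------------------------

#' Plot a residual diagnostic
#'
#' Centered L curve of the super-thinned residuals with the homogeneous
#' Poisson 95% envelope (grey ribbon), the super-thinned replicate band
#' (dashed) and the replicate mean.
#'
#' @param object A `kl_result` from [residual_diagnostics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kl_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$d)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$env_lo, ymax = .data$env_hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$st_lo), linetype = "dashed",
                       color = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$st_hi), linetype = "dashed",
                       color = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_L), color = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$centered_L), color = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "distance d (km)", y = "L(d) - d",
                  title = "Super-thinning residual diagnostic") +
    ggplot2::theme_minimal()
}

#' Plot an event catalog
#'
#' Spatial scatter of the events, colored by time.
#'
#' @param data Event catalog.
#' @param region Optional [spatial_region()] drawn as a frame.
#' @return A ggplot object.
#' @export
plot_catalog <- function(data, region = NULL) {
  data <- as_event_catalog(data)
  gg <- ggplot2::ggplot(data, ggplot2::aes(x = .data$x, y = .data$y,
                                           color = .data$t)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", color = "time") +
    ggplot2::theme_minimal()
  if (!is.null(region)) {
    gg <- gg + ggplot2::annotate("rect", xmin = region$x_lo, xmax = region$x_hi,
                                 ymin = region$y_lo, ymax = region$y_hi,
                                 fill = NA, color = "grey40")
  }
  gg
}

#' Plot a BIC order-selection table
#'
#' @param object A `hawkes_selection` from [select_order()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hawkes_selection <- function(object, ...) {
  tab <- object$table |>
    mutate(label = paste0("(", .data$p, ",", .data$q, ")"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$label, y = .data$bic, group = 1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "(p, q)", y = "BIC") +
    ggplot2::theme_minimal()
}
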