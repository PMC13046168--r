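#' Simulate-and-refit recovery study
#'
#' The replication harness behind the parameter-recovery experiments:
#' simulate `n_reps` catalogs of `n_events` events from a generating kernel
#' (burn-in trimming included), fit each with the Gaussian-exponent mixture
#' model at order `(p, q)`, and return every fit's natural-scale parameter
#' table. Triggering components are sorted by temporal decay within each
#' fit, so component labels are comparable across replicates.
#'
#' @param kernel A [sim_kernel()] generating model.
#' @param n_events Catalog size after trimming and clipping.
#' @param n_reps Number of replicates.
#' @param p,q Fitted mixture orders.
#' @param region Observation region (simulation clip and fit domain).
#' @param trim Burn-in events discarded at each end of each simulation.
#' @param options [fit_options()] for every fit.
#' @param seed Base seed; replicate r uses `seed + r` for both simulation
#'   and fit.
#' @return A tibble: the [to_natural_scale()] rows of every fit with
#'   `replicate`, `loglik`, `bic` and `converged` columns added.
#' @export
recovery_study <- function(kernel, n_events = 5000, n_reps = 50, p = 0, q = 0,
                           region = spatial_region(0, 20, 0, 20), trim = 2000,
                           options = fit_options(restarts = 1), seed = 1) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cat_r <- simulate_catalog(kernel, target_n = n_events, region = region,
                              trim = trim, seed = seed + r)
    opts_r <- options
    opts_r$seed <- options$seed + r
    fit <- fit_hawkes(cat_r, region, catalog_window(cat_r), p = p, q = q,
                      options = opts_r)
    rows[[r]] <- to_natural_scale(fit) |>
      mutate(replicate = r, loglik = fit$loglik$loglik, bic = fit$bic,
             converged = fit$converged)
  }
  list_rbind(rows)
}

#' Summarise a recovery study
#'
#' Mean and variance of each natural-scale parameter across replicates,
#' per kernel component.
#'
#' @param results A tibble from [recovery_study()].
#' @return A tibble with one row per kernel component and `mean_` /
#'   `var_` columns for each parameter.
#' @export
summarise_recovery <- function(results) {
  results |>
    group_by(.data$kernel, .data$component) |>
    summarise(across(c("mu_bar", "c", "d", "theta", "omega",
                       "sigma_x", "sigma_y"),
                     list(mean = ~mean(.x), var = ~var(.x))),
              n_reps = dplyr::n(), .groups = "drop")
}
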