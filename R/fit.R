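#' Fitting options
#'
#' Tuning values for maximum-likelihood fitting. The triggering history sum
#' is truncated to the `n_star` most recent events; 200 is the default
#' working value (small windows inflate the background estimate, large ones
#' cost proportionally more per likelihood evaluation). Alternatively a
#' trailing time bound `z` may be given, in which case the window size is
#' the maximal event count in any trailing window of length `z`
#' (see [compute_n_star()]).
#'
#' @param n_star Number of most recent events in the truncated history sum.
#' @param z Optional trailing time bound; when non-`NULL` it overrides
#'   `n_star` via [compute_n_star()].
#' @param restarts Number of seeded optimizer starts; the best is kept.
#' @param rel_tol Relative convergence tolerance of the optimizer.
#' @param max_iter Iteration cap per start.
#' @param seed Integer seed controlling start jitter (reproducible fits).
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(n_star = 200, z = NULL, restarts = 3,
                        rel_tol = 1e-8, max_iter = 500, seed = 1) {
  stopifnot(n_star >= 0, restarts >= 1, rel_tol > 0, max_iter > 0)
  structure(list(n_star = n_star, z = z, restarts = as.integer(restarts),
                 rel_tol = rel_tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "fit_options")
}

#' Bayesian information criterion for a (p, q) model
#'
#' `-2 * loglik + (5 * (p + 1) + 4 * (q + 1)) * log(n)`: each background
#' component carries 5 free parameters (amplitude, two center coordinates,
#' two decay rates) and each triggering component 4.
#'
#' @param loglik Maximized log-likelihood.
#' @param p,q Mixture orders (number of components minus one).
#' @param n Number of events.
#' @return The BIC value (smaller is better).
#' @export
bic_hawkes <- function(loglik, p, q, n) {
  -2 * loglik + (5 * (p + 1) + 4 * (q + 1)) * log(n)
}

# ---- parameter packing ------------------------------------------------------
# All positive parameters are log-transformed; background centers are mapped
# to the fitting region through a scaled logistic so box constraints never
# bind explicitly.

pack_params <- function(model, region) {
  bg <- model$background; tr <- model$trigger
  wx <- region$x_hi - region$x_lo
  wy <- region$y_hi - region$y_lo
  to_u <- function(v, lo, w) stats::qlogis(pmin(pmax((v - lo) / w, 1e-9), 1 - 1e-9))
  c(rbind(log(bg$a), to_u(bg$c, region$x_lo, wx), to_u(bg$d, region$y_lo, wy),
          log(bg$alpha), log(bg$beta)),
    rbind(log(tr$b), log(tr$alpha), log(tr$beta), log(tr$gamma)))
}

unpack_params <- function(par, p, q, region, n_star) {
  nb <- 5 * (p + 1)
  bgm <- matrix(par[seq_len(nb)], nrow = 5)
  trm <- matrix(par[nb + seq_len(4 * (q + 1))], nrow = 4)
  wx <- region$x_hi - region$x_lo
  wy <- region$y_hi - region$y_lo
  model_spec(
    background = bg_params(a = exp(bgm[1, ]),
                           c = region$x_lo + wx * stats::plogis(bgm[2, ]),
                           d = region$y_lo + wy * stats::plogis(bgm[3, ]),
                           alpha = exp(bgm[4, ]), beta = exp(bgm[5, ])),
    trigger = trig_params(b = exp(trm[1, ]), alpha = exp(trm[2, ]),
                          beta = exp(trm[3, ]), gamma = exp(trm[4, ])),
    n_star = n_star
  )
}

# ---- initialization ---------------------------------------------------------
# Moment-based starting values. Background: event centroid and coordinate
# variances, with (1 - mass0) of the mean event rate. Triggering: spatial
# scales from the offsets to each event's nearest previous event (the
# offspring signature is spatial proximity), temporal decay from the lags of
# spatially close pairs, total mass 0.2 split evenly across components.
init_model <- function(data, region, window, p, q, n_star) {
  n <- nrow(data)
  lookback <- 100L
  dmin <- rep(Inf, n); dxn <- rep(NA_real_, n); dyn <- rep(NA_real_, n)
  lagn <- rep(NA_real_, n)
  for (i in 2:n) {
    idx <- max(1L, i - lookback):(i - 1L)
    dx <- data$x[i] - data$x[idx]; dy <- data$y[i] - data$y[idx]
    dd <- dx^2 + dy^2
    k <- which.min(dd)
    dmin[i] <- dd[k]; dxn[i] <- abs(dx[k]); dyn[i] <- abs(dy[k])
    lagn[i] <- data$t[i] - data$t[idx][k]
  }
  close <- which(is.finite(dmin) & dmin <= quantile(dmin[-1], 0.2, names = FALSE))
  sx0 <- max(median(dxn[close]), 1e-4)
  sy0 <- max(median(dyn[close]), 1e-4)
  lag0 <- median(lagn[close][lagn[close] > 0])
  if (!is.finite(lag0) || lag0 <= 0) lag0 <- mean(diff(data$t))
  gamma0 <- 1 / lag0

  mass0 <- 0.2
  mu0 <- (1 - mass0) * n / window_length(window)
  j <- seq_len(q + 1)
  gam <- gamma0 * 4^(j - 1 - q / 2)
  # spread the spatial scales too so components start distinguishable
  sxj <- sx0 * 2^(j - 1 - q / 2)
  syj <- sy0 * 2^(j - 1 - q / 2)
  trigger <- trig_params_natural(theta = rep(mass0 / (q + 1), q + 1),
                                 omega = gam, sigma_x = sxj, sigma_y = syj)
  smux <- max(sd(data$x), 1e-3)
  smuy <- max(sd(data$y), 1e-3)
  background <- bg_params_natural(mu_bar = rep(mu0 / (p + 1), p + 1),
                                  sigma_x = smux, sigma_y = smuy,
                                  c = rep(mean(data$x), p + 1),
                                  d = rep(mean(data$y), p + 1))
  model_spec(background, trigger, n_star = n_star)
}

# ---- main fit ---------------------------------------------------------------

#' Fit a space-time self-exciting model by maximum likelihood
#'
#' Maximizes the closed-form log-likelihood of [log_likelihood()] over all
#' kernel parameters with a quasi-Newton optimizer (BFGS on log-transformed
#' positive parameters, background centers constrained to the region;
#' gradients by finite differences). The truncated-history window `n_star`
#' is fixed before optimization. Several seeded starts are run and the best
#' is kept; the starts beyond the first jitter the moment-based initial
#' values.
#'
#' @param data Event catalog (data frame with `t`, `x`, `y`); catalogs of
#'   fewer than 50 events are allowed with a warning.
#' @param region A [spatial_region()] (finite).
#' @param window A [time_window()] containing the event times.
#' @param p,q Mixture orders: p + 1 background and q + 1 triggering
#'   components.
#' @param options A [fit_options()].
#' @return An object of class `hawkes_fit`: a list with the fitted
#'   `model` ([model_spec()]), the `loglik` breakdown tibble, `bic`, orders
#'   `p`, `q`, event count `n`, `n_star`, `converged`, `restarts_used` and
#'   `seed`. Supports [tidy()], [glance()] and [to_natural_scale()].
#' @examples
#' \donttest{
#' kern <- sim_kernel(mu_bar = 5, sigma_mu = 2, c = 5, d = 5, rho = 0,
#'                    components = data.frame(theta = 0.2, omega = 0.5,
#'                                            sigma_x = 0.1, sigma_y = 0.1))
#' cat <- simulate_catalog(kern, target_n = 400, trim = 50,
#'                         region = spatial_region(0, 10, 0, 10), seed = 1)
#' fit <- fit_hawkes(cat, spatial_region(0, 10, 0, 10), catalog_window(cat),
#'                   options = fit_options(restarts = 1))
#' glance(fit)
#' }
#' @export
fit_hawkes <- function(data, region, window, p = 0, q = 0,
                       options = fit_options()) {
  data <- as_event_catalog(data)
  n <- nrow(data)
  if (n < 50) warn(sprintf("catalog has only %d events; estimates will be unstable", n))
  n_star <- if (!is.null(options$z)) compute_n_star(data, options$z) else options$n_star

  # hot loop: transform in place and call the compiled core directly,
  # skipping the tibble plumbing of unpack_params()/log_likelihood()
  nb <- 5 * (p + 1)
  wx <- region$x_hi - region$x_lo
  wy <- region$y_hi - region$y_lo
  objective <- function(par) {
    # clamp the transformed scale so line-search excursions cannot overflow
    par <- pmin(pmax(par, -45), 45)
    bgm <- matrix(par[seq_len(nb)], nrow = 5)
    trm <- matrix(par[nb + seq_len(4 * (q + 1))], nrow = 4)
    parts <- cpp_loglik(data$x, data$y, data$t,
                        exp(bgm[1, ]),
                        region$x_lo + wx * stats::plogis(bgm[2, ]),
                        region$y_lo + wy * stats::plogis(bgm[3, ]),
                        exp(bgm[4, ]), exp(bgm[5, ]),
                        exp(trm[1, ]), exp(trm[2, ]), exp(trm[3, ]),
                        exp(trm[4, ]), n_star,
                        region$x_lo, region$x_hi, region$y_lo, region$y_hi,
                        window$t_lo, window$t_hi)
    ll <- parts$point_term - parts$background_compensator -
      parts$trigger_compensator
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  init0 <- init_model(data, region, window, p, q, n_star)
  par0 <- pack_params(init0, region)

  best <- NULL
  converged <- FALSE
  for (r in seq_len(options$restarts)) {
    par_r <- if (r == 1) par0 else {
      withr::with_seed(options$seed + 1000L * r,
                       par0 + rnorm(length(par0), sd = 0.5))
    }
    opt <- tryCatch(
      optim(par_r, objective, method = "BFGS",
            control = list(maxit = options$max_iter,
                           reltol = options$rel_tol)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      converged <- opt$convergence == 0
    }
  }
  if (is.null(best)) abort("all optimizer starts failed (degenerate likelihood)")

  model <- unpack_params(pmin(pmax(best$par, -45), 45), p, q, region, n_star)
  ll <- log_likelihood(model, data, region, window)
  mass <- trigger_total_mass(model$trigger)
  if (mass >= 1) {
    warn(sprintf("fitted triggering mass %.3f >= 1: supercritical optimum", mass))
  }
  structure(list(model = model, loglik = ll,
                 bic = bic_hawkes(ll$loglik, p, q, n),
                 p = p, q = q, n = n, n_star = n_star,
                 converged = converged,
                 restarts_used = options$restarts,
                 seed = options$seed,
                 region = region, window = window, options = options),
            class = "hawkes_fit")
}

#' @export
print.hawkes_fit <- function(x, ...) {
  cat(sprintf("<hawkes_fit (p, q) = (%d, %d), n = %d, n* = %s>\n",
              x$p, x$q, x$n, format(x$n_star)))
  cat(sprintf("  loglik = %.3f, BIC = %.3f, converged = %s\n",
              x$loglik$loglik, x$bic, x$converged))
  print(to_natural_scale(x))
  invisible(x)
}

#' Map a fit to the natural parameter scale
#'
#' Re-expresses fitted kernel parameters as interpretable quantities: per
#' triggering component the mass `theta = b * pi / (gamma * sqrt(alpha * beta))`,
#' temporal decay `omega = gamma` and spatial scales
#' `sigma_x = 1 / sqrt(2 alpha)`, `sigma_y = 1 / sqrt(2 beta)`; per
#' background component the total rate `mu_bar = a * pi / sqrt(alpha * beta)`,
#' the center `(c, d)` and the pair of implied spatial scales. Triggering
#' components are sorted by `omega` ascending to fix label switching.
#'
#' @param fit A `hawkes_fit` or a [model_spec()].
#' @return A tibble with one row per kernel component and columns `kernel`,
#'   `component`, `mu_bar`, `c`, `d`, `theta`, `omega`, `sigma_x`, `sigma_y`.
#' @export
to_natural_scale <- function(fit) {
  model <- if (inherits(fit, "hawkes_fit")) fit$model else fit
  bg <- model$background; tr <- model$trigger
  bg_tbl <- tibble(kernel = "background", component = seq_len(nrow(bg)),
                   mu_bar = bg$a * pi / sqrt(bg$alpha * bg$beta),
                   c = bg$c, d = bg$d, theta = NA_real_, omega = NA_real_,
                   sigma_x = 1 / sqrt(2 * bg$alpha),
                   sigma_y = 1 / sqrt(2 * bg$beta))
  ord <- order(tr$gamma)
  tr <- tr[ord, , drop = FALSE]
  tr_tbl <- tibble(kernel = "trigger", component = seq_len(nrow(tr)),
                   mu_bar = NA_real_, c = NA_real_, d = NA_real_,
                   theta = tr$b * pi / (tr$gamma * sqrt(tr$alpha * tr$beta)),
                   omega = tr$gamma,
                   sigma_x = 1 / sqrt(2 * tr$alpha),
                   sigma_y = 1 / sqrt(2 * tr$beta))
  bind_rows(bg_tbl, tr_tbl)
}

#' @export
tidy.hawkes_fit <- function(x, ...) {
  nat <- to_natural_scale(x)
  nat |>
    tidyr::pivot_longer(cols = c("mu_bar", "c", "d", "theta", "omega",
                                 "sigma_x", "sigma_y"),
                        names_to = "parameter", values_to = "estimate") |>
    filter(!is.na(.data$estimate)) |>
    mutate(term = paste0(.data$kernel, .data$component, ".", .data$parameter)) |>
    select("term", "estimate", "kernel", "component", "parameter")
}

#' @export
glance.hawkes_fit <- function(x, ...) {
  tibble(loglik = x$loglik$loglik, bic = x$bic, p = x$p, q = x$q,
         n = x$n, n_star = x$n_star,
         trigger_mass = trigger_total_mass(x$model$trigger),
         converged = x$converged, restarts = x$restarts_used, seed = x$seed)
}

#' Select mixture orders (p, q) by BIC
#'
#' Fits every order pair in `grid` and returns the pair with the smallest
#' BIC together with the full fit table.
#'
#' @param data Event catalog.
#' @param region A [spatial_region()].
#' @param window A [time_window()].
#' @param grid A data frame with columns `p` and `q`; defaults to the full
#'   3 x 3 grid p, q in 0..2.
#' @param options A [fit_options()].
#' @return An object of class `hawkes_selection`: a list with `best_p`,
#'   `best_q`, a `table` tibble (p, q, loglik, bic, converged) and the list
#'   of `fits`. `tidy()` returns the table.
#' @export
select_order <- function(data, region, window,
                         grid = expand.grid(p = 0:2, q = 0:2),
                         options = fit_options()) {
  if (nrow(grid) == 0) abort("order grid must be nonempty")
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; q <- grid$q[i]
    fit <- tryCatch(fit_hawkes(data, region, window, p = p, q = q,
                               options = options),
                    error = function(e) NULL)
    fits[[i]] <- fit
    rows[[i]] <- tibble(p = p, q = q,
                        loglik = if (is.null(fit)) NA_real_ else fit$loglik$loglik,
                        bic = if (is.null(fit)) NA_real_ else fit$bic,
                        converged = if (is.null(fit)) FALSE else fit$converged)
  }
  table <- list_rbind(rows)
  if (all(is.na(table$bic))) abort("all order fits failed")
  k <- which.min(table$bic)
  structure(list(best_p = table$p[k], best_q = table$q[k],
                 table = table, fits = fits),
            class = "hawkes_selection")
}

#' @export
print.hawkes_selection <- function(x, ...) {
  cat(sprintf("<hawkes_selection: best (p, q) = (%d, %d)>\n", x$best_p, x$best_q))
  print(x$table)
  invisible(x)
}

#' @export
tidy.hawkes_selection <- function(x, ...) x$table
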