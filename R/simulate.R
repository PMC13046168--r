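#' Generating kernel for the branching simulator
#'
#' The simulator's model: immigrants arrive as a Poisson stream with total
#' rate `mu_bar` per unit time and correlated bivariate-normal locations
#' centered at `(c, d)` with scale `sigma_mu` and correlation `rho`; each
#' event spawns, per triggering component, a Poisson(`theta`) number of
#' direct offspring with Exp(`omega`) forward time lags and correlated
#' bivariate-normal spatial offsets (`sigma_x`, `sigma_y`, `rho`). All
#' kernels are normalized correlated bivariate normal densities, so the
#' background integrates over the plane to exactly `mu_bar` per unit time
#' and the triggering kernel to exactly `sum(theta)`.
#'
#' @param mu_bar Background rate (events per unit time), > 0.
#' @param sigma_mu Background spatial standard deviation (km).
#' @param c,d Background center (km).
#' @param rho Spatial correlation in (-1, 1), shared by background and
#'   triggering kernels.
#' @param components A data frame with one row per triggering component and
#'   columns `theta`, `omega`, `sigma_x`, `sigma_y`. `sum(theta)` must be
#'   < 1 for stationarity (checked at simulation time).
#' @return An object of class `sim_kernel`.
#' @seealso [kernel_single()], [kernel_multi()] for the reference
#'   burglary-simulation settings.
#' @export
sim_kernel <- function(mu_bar, sigma_mu, c, d, rho = 0,
                       components = tibble(theta = 0.2, omega = 0.1,
                                           sigma_x = 0.01, sigma_y = 0.1)) {
  stopifnot(mu_bar > 0, all(sigma_mu > 0), abs(rho) < 1)
  components <- as_tibble(components)
  stopifnot(all(c("theta", "omega", "sigma_x", "sigma_y") %in% names(components)),
            all(components$theta >= 0), all(components$omega > 0),
            all(components$sigma_x > 0), all(components$sigma_y > 0))
  structure(list(background = tibble(mu_bar = mu_bar, sigma_x = sigma_mu,
                                     sigma_y = sigma_mu, c = c, d = d),
                 trigger = components[, c("theta", "omega", "sigma_x", "sigma_y")],
                 rho = rho),
            class = "sim_kernel")
}

#' @export
print.sim_kernel <- function(x, ...) {
  m <- sim_kernel_masses(x)
  cat(sprintf("<sim_kernel: background rate %g / unit time, trigger mass %g, rho = %g>\n",
              m$background_rate, m$trigger_mass, x$rho))
  invisible(x)
}

#' Reference simulation settings
#'
#' The single-component burglary-simulation kernel (background rate 5.71,
#' sigma_mu = 4.5, center (10, 10); one triggering component with
#' theta = 0.2, omega = 0.1, sigma_x = 0.01, sigma_y = 0.1) and its
#' two-component variant adding (theta = 0.3, omega = 0.2, sigma_x = 0.2,
#' sigma_y = 0.05), both on a 20 x 20 km domain.
#'
#' @param rho Spatial correlation, default 0.
#' @return A [sim_kernel()].
#' @export
kernel_single <- function(rho = 0) {
  sim_kernel(mu_bar = 5.71, sigma_mu = 4.5, c = 10, d = 10, rho = rho,
             components = tibble(theta = 0.2, omega = 0.1,
                                 sigma_x = 0.01, sigma_y = 0.1))
}

#' @rdname kernel_single
#' @export
kernel_multi <- function(rho = 0) {
  sim_kernel(mu_bar = 5.71, sigma_mu = 4.5, c = 10, d = 10, rho = rho,
             components = tibble(theta = c(0.2, 0.3), omega = c(0.1, 0.2),
                                 sigma_x = c(0.01, 0.2), sigma_y = c(0.1, 0.05)))
}

#' Analytic kernel masses
#'
#' The spatial integral of the background over the plane per unit time, and
#' the space-time integral of the triggering kernel (the branching ratio).
#' Both are exact because the kernels are normalized densities.
#'
#' @param kernel A [sim_kernel()].
#' @return A one-row tibble with `background_rate` and `trigger_mass`.
#' @export
sim_kernel_masses <- function(kernel) {
  tibble(background_rate = sum(kernel$background$mu_bar),
         trigger_mass = sum(kernel$trigger$theta))
}

#' Convert a fitted model to a simulation kernel
#'
#' Maps the Gaussian-exponent mixture of a [model_spec()] (or `hawkes_fit`)
#' to the branching simulator's normalized-density parameterization:
#' each background component becomes an immigrant stream with rate
#' `a * pi / sqrt(alpha * beta)` and each triggering component an offspring
#' law with mass `b * pi / (gamma * sqrt(alpha * beta))`. The fitted model
#' has no spatial correlation, so `rho = 0`.
#'
#' @param x A `hawkes_model` or `hawkes_fit`.
#' @return A [sim_kernel()]-like object.
#' @export
as_sim_kernel <- function(x) {
  model <- if (inherits(x, "hawkes_fit")) x$model else x
  if (inherits(model, "sim_kernel")) return(model)
  stopifnot(inherits(model, "hawkes_model"))
  bg <- model$background; tr <- model$trigger
  structure(list(background = tibble(mu_bar = bg$a * pi / sqrt(bg$alpha * bg$beta),
                                     sigma_x = 1 / sqrt(2 * bg$alpha),
                                     sigma_y = 1 / sqrt(2 * bg$beta),
                                     c = bg$c, d = bg$d),
                 trigger = tibble(theta = tr$b * pi / (tr$gamma * sqrt(tr$alpha * tr$beta)),
                                  omega = tr$gamma,
                                  sigma_x = 1 / sqrt(2 * tr$alpha),
                                  sigma_y = 1 / sqrt(2 * tr$beta)),
                 rho = 0),
            class = "sim_kernel")
}

# correlated bivariate normal draws scaled by (sx, sy)
rbinorm <- function(n, sx, sy, rho) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  list(dx = sx * z1, dy = sy * z2)
}

# one full branching realization on [0, t_max]; returns the genealogy table
simulate_branching <- function(kernel, t_max) {
  bg <- kernel$background; tr <- kernel$trigger; rho <- kernel$rho
  mu_tot <- sum(bg$mu_bar)
  n0 <- rpois(1, mu_tot * t_max)
  comp <- sample.int(nrow(bg), n0, replace = TRUE, prob = bg$mu_bar / mu_tot)
  off <- rbinorm(n0, bg$sigma_x[comp], bg$sigma_y[comp], rho)
  events <- tibble(t = runif(n0, 0, t_max),
                   x = bg$c[comp] + off$dx,
                   y = bg$d[comp] + off$dy,
                   parent = 0L, generation = 0L, component = 0L)
  events$id <- seq_len(nrow(events))
  next_id <- nrow(events) + 1L
  current <- events
  gen <- 0L
  while (nrow(current) > 0) {
    gen <- gen + 1L
    kids <- vector("list", nrow(tr))
    for (m in seq_len(nrow(tr))) {
      counts <- rpois(nrow(current), tr$theta[m])
      tot <- sum(counts)
      if (tot == 0) next
      par_idx <- rep.int(seq_len(nrow(current)), counts)
      lag <- rexp(tot, rate = tr$omega[m])
      off <- rbinorm(tot, tr$sigma_x[m], tr$sigma_y[m], rho)
      kids[[m]] <- tibble(t = current$t[par_idx] + lag,
                          x = current$x[par_idx] + off$dx,
                          y = current$y[par_idx] + off$dy,
                          parent = current$id[par_idx],
                          generation = gen, component = m)
    }
    kids <- bind_rows(kids)
    if (nrow(kids) == 0) break
    kids <- kids[kids$t < t_max, , drop = FALSE]
    if (nrow(kids) == 0) break
    kids$id <- next_id - 1L + seq_len(nrow(kids))
    next_id <- next_id + nrow(kids)
    events <- bind_rows(events, kids)
    current <- kids
  }
  events[order(events$t), , drop = FALSE]
}

#' Simulate an event catalog by branching
#'
#' Cluster (branching) construction: immigrants from the background stream,
#' then generations of offspring until extinction. Events are sorted by
#' time; the first and last `trim` events are discarded so the retained
#' segment reflects the stationary regime; remaining events are clipped to
#' `region` and time is re-zeroed at the first retained event. The immigrant
#' time span is extended automatically until the post-trim catalog reaches
#' `target_n` events (the catalog is then truncated to exactly `target_n`).
#'
#' @param kernel A [sim_kernel()] (or a fitted model, converted via
#'   [as_sim_kernel()]). Its triggering mass must be < 1.
#' @param target_n Desired number of events after trimming and clipping.
#' @param region A [spatial_region()] to clip to.
#' @param trim Number of events discarded at each end (default 2000).
#' @param seed Optional integer seed; fixed seeds give bit-reproducible
#'   catalogs.
#' @param genealogy If `TRUE`, attach the full pre-trim event table (with
#'   `id`, `parent`, `generation`, `component` columns) as attribute
#'   `"genealogy"`.
#' @return An event catalog tibble (`t`, `x`, `y`).
#' @export
simulate_catalog <- function(kernel, target_n, region, trim = 2000,
                             seed = NULL, genealogy = FALSE) {
  kernel <- as_sim_kernel(kernel)
  mass <- sum(kernel$trigger$theta)
  if (mass >= 1) abort("supercritical kernel: triggering mass must be < 1")
  bg <- kernel$background
  # expected fraction of events inside the region, from the background law
  in_frac <- sum(bg$mu_bar *
                   (pnorm(region$x_hi, bg$c, bg$sigma_x) - pnorm(region$x_lo, bg$c, bg$sigma_x)) *
                   (pnorm(region$y_hi, bg$d, bg$sigma_y) - pnorm(region$y_lo, bg$d, bg$sigma_y))) /
    sum(bg$mu_bar)
  in_frac <- max(in_frac, 0.25)
  rate <- sum(bg$mu_bar) / (1 - mass)
  t_max <- (2 * trim + target_n / in_frac) / rate * 1.15 + 10 / rate

  for (attempt in 1:6) {
    run <- function() simulate_branching(kernel, t_max)
    events <- if (is.null(seed)) run() else {
      withr::with_seed(seed + 7919L * (attempt - 1L), run())
    }
    if (nrow(events) > 2 * trim) {
      kept <- events[seq(trim + 1, nrow(events) - trim), , drop = FALSE]
      kept <- kept[kept$x >= region$x_lo & kept$x <= region$x_hi &
                     kept$y >= region$y_lo & kept$y <= region$y_hi, , drop = FALSE]
      if (nrow(kept) >= target_n) {
        kept <- kept[seq_len(target_n), , drop = FALSE]
        out <- tibble(t = kept$t - kept$t[1], x = kept$x, y = kept$y)
        if (genealogy) attr(out, "genealogy") <- events
        return(out)
      }
    }
    t_max <- t_max * 1.4
  }
  abort("simulation failed to reach target_n; increase target_n headroom")
}

#' Simulate a homogeneous Poisson catalog
#'
#' Count Poisson with mean `rate * |S| * |D|`; locations and times uniform
#' over the domain.
#'
#' @param rate Nonnegative intensity (events per km^2 per unit time).
#' @param region A [spatial_region()].
#' @param window A [time_window()].
#' @param seed Optional integer seed.
#' @return An event catalog tibble.
#' @export
simulate_homogeneous <- function(rate, region, window, seed = NULL) {
  stopifnot(rate >= 0)
  run <- function() {
    n <- rpois(1, rate * region_area(region) * window_length(window))
    event_catalog(t = runif(n, window$t_lo, window$t_hi),
                  x = runif(n, region$x_lo, region$x_hi),
                  y = runif(n, region$y_lo, region$y_hi))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate the superposition residual process
#'
#' An inhomogeneous Poisson process with intensity
#' `max(k - lambda_hat(x, y, t), 0)`, realized by thinning a dominating
#' homogeneous process of rate `k`: the superposed points of the
#' super-thinning residual method.
#'
#' @param model A [model_spec()] supplying the estimated intensity
#'   `lambda_hat` (full-history conditional intensity given `data`).
#' @param data Event catalog supplying the history.
#' @param k Positive dominating rate.
#' @param region A [spatial_region()].
#' @param window A [time_window()].
#' @param seed Optional integer seed.
#' @return An event catalog tibble (possibly empty).
#' @export
simulate_residual_superposition <- function(model, data, k, region, window,
                                            seed = NULL) {
  stopifnot(k > 0)
  run <- function() {
    cand <- simulate_homogeneous(k, region, window)
    if (nrow(cand) == 0) return(cand)
    lam <- conditional_intensity(model, data, cand$x, cand$y, cand$t)
    keep <- runif(nrow(cand)) < pmax(k - lam, 0) / k
    cand[keep, , drop = FALSE]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
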