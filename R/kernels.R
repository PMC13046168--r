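#' Background kernel parameters
#'
#' The background intensity is a time-invariant mixture of p+1 Gaussian-type
#' exponent components,
#' mu(x, y) = sum_j a_j exp(-alpha_j (x - c_j)^2 - beta_j (y - d_j)^2).
#' Each component has an amplitude `a` (events per km^2 per unit time), a
#' center `(c, d)` (km), and spatial decay rates `alpha`, `beta` (km^-2).
#'
#' @param a,c,d,alpha,beta Equal-length numeric vectors, one entry per
#'   component; `a`, `alpha`, `beta` strictly positive.
#' @return A tibble with one row per component and columns
#'   `a`, `c`, `d`, `alpha`, `beta`.
#' @seealso [bg_params_natural()] for the (mu_bar, sigma, center) scale.
#' @export
bg_params <- function(a, c, d, alpha, beta) {
  out <- tibble(a = as.numeric(a), c = as.numeric(c), d = as.numeric(d),
                alpha = as.numeric(alpha), beta = as.numeric(beta))
  if (nrow(out) < 1) abort("background needs at least one component")
  if (any(!is.finite(as.matrix(out)))) abort("background parameters must be finite")
  if (any(out$a <= 0) || any(out$alpha <= 0) || any(out$beta <= 0)) {
    abort("background a, alpha, beta must be strictly positive")
  }
  out
}

#' Triggering kernel parameters
#'
#' The triggering function is a mixture of q+1 separable Gaussian-exponent
#' components,
#' g(x, y, t) = sum_j b_j exp(-alpha_j x^2 - beta_j y^2 - gamma_j t),
#' acting forward in time only. `alpha`, `beta` are spatial decay rates
#' (km^-2) and `gamma` is the temporal decay rate (time^-1).
#'
#' The total mass of g over the plane and positive time (the branching
#' ratio) is `sum_j b_j * pi / (gamma_j * sqrt(alpha_j * beta_j))`; values
#' below 1 correspond to a subcritical (stationary) process. Subcriticality
#' is checked by [trigger_total_mass()] and warned about where relevant, not
#' enforced.
#'
#' @param b,alpha,beta,gamma Equal-length numeric vectors, one entry per
#'   component, all strictly positive.
#' @return A tibble with one row per component and columns
#'   `b`, `alpha`, `beta`, `gamma`.
#' @seealso [trig_params_natural()] for the (theta, omega, sigma) scale.
#' @export
trig_params <- function(b, alpha, beta, gamma) {
  out <- tibble(b = as.numeric(b), alpha = as.numeric(alpha),
                beta = as.numeric(beta), gamma = as.numeric(gamma))
  if (nrow(out) < 1) abort("triggering needs at least one component")
  if (any(!is.finite(as.matrix(out)))) abort("triggering parameters must be finite")
  if (any(as.matrix(out) <= 0)) abort("triggering parameters must be strictly positive")
  out
}

#' Kernel parameters on the natural scale
#'
#' Convenience constructors taking the interpretable parameterization used
#' throughout reporting: per triggering component a mass `theta` (expected
#' direct offspring), temporal decay `omega` (time^-1) and spatial standard
#' deviations `sigma_x`, `sigma_y` (km); per background component a total
#' rate `mu_bar` (events per unit time), isotropic-or-not standard deviations
#' and a center. The mapping is
#' `b = theta * omega / (2 * pi * sigma_x * sigma_y)`,
#' `alpha = 1 / (2 sigma_x^2)`, `beta = 1 / (2 sigma_y^2)`, `gamma = omega`,
#' and `a = mu_bar / (2 * pi * sigma_x * sigma_y)`.
#'
#' @param theta,omega,sigma_x,sigma_y Triggering mass, temporal decay and
#'   spatial scales, one entry per component.
#' @param mu_bar Background total rate per component.
#' @param c,d Background center coordinates.
#' @return A [trig_params()] or [bg_params()] tibble.
#' @export
trig_params_natural <- function(theta, omega, sigma_x, sigma_y) {
  trig_params(b = theta * omega / (2 * pi * sigma_x * sigma_y),
              alpha = 1 / (2 * sigma_x^2),
              beta = 1 / (2 * sigma_y^2),
              gamma = omega)
}

#' @rdname trig_params_natural
#' @export
bg_params_natural <- function(mu_bar, sigma_x, sigma_y = sigma_x, c = 0, d = 0) {
  bg_params(a = mu_bar / (2 * pi * sigma_x * sigma_y), c = c, d = d,
            alpha = 1 / (2 * sigma_x^2), beta = 1 / (2 * sigma_y^2))
}

#' Model specification
#'
#' Bundles background and triggering kernel parameters with the
#' truncation-window size `n_star`: the conditional intensity at an event
#' sums triggering contributions of at most the `n_star` most recent
#' preceding events (see [truncated_intensity()]).
#'
#' @param background A [bg_params()] tibble.
#' @param trigger A [trig_params()] tibble.
#' @param n_star Nonnegative integer; `Inf` means the full history.
#' @return An object of class `hawkes_model`.
#' @export
model_spec <- function(background, trigger, n_star = Inf) {
  if (!is.infinite(n_star) && (n_star < 0 || n_star != round(n_star))) {
    abort("n_star must be a nonnegative integer or Inf")
  }
  structure(list(background = bg_params(background$a, background$c, background$d,
                                        background$alpha, background$beta),
                 trigger = trig_params(trigger$b, trigger$alpha,
                                       trigger$beta, trigger$gamma),
                 n_star = n_star),
            class = "hawkes_model")
}

#' @export
print.hawkes_model <- function(x, ...) {
  cat(sprintf("<hawkes_model p = %d, q = %d, n_star = %s>\n",
              nrow(x$background) - 1L, nrow(x$trigger) - 1L,
              format(x$n_star)))
  cat("Background components:\n")
  print(x$background)
  cat("Triggering components (total mass ",
      format(trigger_total_mass(x$trigger), digits = 4), "):\n", sep = "")
  print(x$trigger)
  invisible(x)
}

#' Evaluate the background intensity
#'
#' @param bg A [bg_params()] tibble.
#' @param x,y Query coordinates (equal-length numeric vectors).
#' @return Numeric vector of background intensities (>= 0).
#' @export
eval_background <- function(bg, x, y) {
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    abort("query coordinates must be finite")
  }
  out <- numeric(length(x))
  for (j in seq_len(nrow(bg))) {
    out <- out + bg$a[j] * exp(-bg$alpha[j] * (x - bg$c[j])^2 -
                                 bg$beta[j] * (y - bg$d[j])^2)
  }
  out
}

#' Evaluate the triggering kernel
#'
#' Triggering acts forward in time only: negative lags are an error.
#'
#' @param tr A [trig_params()] tibble.
#' @param dx,dy Spatial offsets from the parent event (km).
#' @param dt Time lags since the parent event (>= 0).
#' @return Numeric vector of triggering intensities.
#' @export
eval_trigger <- function(tr, dx, dy, dt) {
  if (any(dt < 0)) abort("triggering lag dt must be nonnegative")
  out <- numeric(length(dx))
  for (j in seq_len(nrow(tr))) {
    out <- out + tr$b[j] * exp(-tr$alpha[j] * dx^2 - tr$beta[j] * dy^2 -
                                 tr$gamma[j] * dt)
  }
  out
}

#' Total triggering mass (branching ratio)
#'
#' The integral of the triggering kernel over the plane and positive time:
#' the expected number of direct offspring per event. Values >= 1 mean the
#' process is supercritical (nonstationary).
#'
#' @param tr A [trig_params()] tibble.
#' @return A nonnegative number.
#' @export
trigger_total_mass <- function(tr) {
  sum(tr$b * pi / (sqrt(tr$alpha * tr$beta) * tr$gamma))
}

#' Conditional intensity of the process
#'
#' Background plus the triggering contributions of all catalog events
#' strictly before the query time (events exactly at `t` contribute
#' nothing).
#'
#' @param model A [model_spec()]. The full history is used regardless of
#'   `model$n_star`; see [truncated_intensity()] for the truncated version.
#' @param data Event catalog supplying the history.
#' @param x,y,t Query location(s) and time(s), recycled to a common length.
#' @return Numeric vector of intensities.
#' @export
conditional_intensity <- function(model, data, x, y, t) {
  data <- as_event_catalog(data)
  m <- max(length(x), length(y), length(t))
  x <- rep_len(x, m); y <- rep_len(y, m); t <- rep_len(t, m)
  out <- eval_background(model$background, x, y)
  for (k in seq_len(m)) {
    idx <- which(data$t < t[k])
    if (length(idx) > 0) {
      out[k] <- out[k] + sum(eval_trigger(model$trigger,
                                          x[k] - data$x[idx],
                                          y[k] - data$y[idx],
                                          t[k] - data$t[idx]))
    }
  }
  out
}

#' Truncated conditional intensity at an event
#'
#' The intensity at event `k` of the catalog, with the triggering sum
#' restricted to the `min(n_star, k - 1)` immediately preceding events.
#' Preceding events at exactly the same time contribute nothing (strict
#' inequality in time); indices below 1 are skipped.
#'
#' @param model A [model_spec()]; its `n_star` sets the window.
#' @param data Event catalog.
#' @param k Event index (1-based), vectorized.
#' @return Numeric vector of intensities at the selected events.
#' @export
truncated_intensity <- function(model, data, k) {
  data <- as_event_catalog(data)
  n <- nrow(data)
  if (any(k < 1 | k > n)) abort("event index k out of range")
  n_star <- model$n_star
  vapply(k, function(ki) {
    out <- eval_background(model$background, data$x[ki], data$y[ki])
    lo <- if (is.infinite(n_star)) 1L else max(1L, ki - as.integer(n_star))
    idx <- seq_len(ki - 1L)
    idx <- idx[idx >= lo]
    idx <- idx[data$t[idx] < data$t[ki]]
    if (length(idx) > 0) {
      out <- out + sum(eval_trigger(model$trigger,
                                    data$x[ki] - data$x[idx],
                                    data$y[ki] - data$y[idx],
                                    data$t[ki] - data$t[idx]))
    }
    out
  }, numeric(1))
}

#' Maximum event count in a trailing time window
#'
#' For each event time t_k, counts the events with t_k - z <= t_i < t_k and
#' returns the maximum over k. This is the window size that makes the
#' fixed-count truncated intensity dominate the time-bound truncation.
#'
#' @param data Event catalog.
#' @param z Positive time-window length.
#' @return A nonnegative integer (0 for an empty catalog).
#' @export
compute_n_star <- function(data, z) {
  if (z <= 0) abort("z must be positive")
  data <- as_event_catalog(data)
  n <- nrow(data)
  if (n == 0) return(0L)
  t <- data$t
  # #{i : t_k - z <= t_i < t_k} = #{t_i < t_k} - #{t_i < t_k - z};
  # findInterval(v, t, left.open = TRUE) counts t_i < v by binary search
  below_tk <- findInterval(t, t, left.open = TRUE)
  below_lo <- findInterval(t - z, t, left.open = TRUE)
  max(below_tk - below_lo)
}
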