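#' Gaussian interval mass
#'
#' The exact integral of `exp(-rate * (u - center)^2)` over `[lo, hi]`,
#' written through the normal distribution function:
#' `sqrt(pi / rate) * (pnorm(hi; center, s) - pnorm(lo; center, s))` with
#' `s = 1 / sqrt(2 * rate)`. Infinite bounds are allowed.
#'
#' @param center Center of the squared-exponent kernel.
#' @param rate Positive decay rate.
#' @param lo,hi Integration bounds, `lo <= hi`.
#' @return The interval mass (vectorized over all arguments).
#' @export
gaussian_interval_mass <- function(center, rate, lo, hi) {
  if (any(rate <= 0)) abort("rate must be strictly positive")
  if (any(lo > hi)) abort("lo must not exceed hi")
  s <- 1 / sqrt(2 * rate)
  sqrt(pi / rate) * (pnorm(hi, mean = center, sd = s) -
                       pnorm(lo, mean = center, sd = s))
}

#' Background compensator
#'
#' The integral of the background intensity over the space-time observation
#' domain S x D: `sum_j a_j * A_j`, where `A_j` is the product of the two
#' spatial interval masses of component j times the window length.
#'
#' @param bg A [bg_params()] tibble.
#' @param region A [spatial_region()] (infinite bounds allowed).
#' @param window A [time_window()].
#' @return A nonnegative number.
#' @export
background_compensator <- function(bg, region, window) {
  sum(bg$a *
        gaussian_interval_mass(bg$c, bg$alpha, region$x_lo, region$x_hi) *
        gaussian_interval_mass(bg$d, bg$beta, region$y_lo, region$y_hi)) *
    window_length(window)
}

#' Triggering compensator
#'
#' The integral over S x D of the summed triggering intensity of all catalog
#' events: `sum_i sum_j b_j * B_j(i) * H_j(t_hi - t_i)`, with `B_j(i)` the
#' product of spatial interval masses centered at event i and
#' `H_j(t) = (1 - exp(-gamma_j t)) / gamma_j` the temporal kernel integral
#' from the event time to the window end. Events at or beyond `t_hi`
#' contribute nothing (half-open window).
#'
#' @param tr A [trig_params()] tibble.
#' @param data Event catalog (events should lie in S x D).
#' @param region A [spatial_region()].
#' @param window A [time_window()].
#' @return A nonnegative number (0 for an empty catalog).
#' @export
trigger_compensator <- function(tr, data, region, window) {
  data <- as_event_catalog(data)
  if (nrow(data) == 0) return(0)
  out <- 0
  for (j in seq_len(nrow(tr))) {
    rem <- pmax(window$t_hi - data$t, 0)
    H <- -expm1(-tr$gamma[j] * rem) / tr$gamma[j]
    out <- out + tr$b[j] *
      sum(gaussian_interval_mass(data$x, tr$alpha[j], region$x_lo, region$x_hi) *
            gaussian_interval_mass(data$y, tr$beta[j], region$y_lo, region$y_hi) *
            H)
  }
  out
}

#' Triggering history sums
#'
#' For each event i and triggering component j, the sum of
#' `exp(-alpha_j dx^2 - beta_j dy^2 - gamma_j dt)` over the
#' `min(n_star, i - 1)` immediately preceding events (strictly earlier in
#' time). The first event's row is all zeros.
#'
#' @param tr A [trig_params()] tibble.
#' @param data Event catalog.
#' @param n_star Nonnegative integer window size, or `Inf` for full history.
#' @return An `n x (q + 1)` numeric matrix.
#' @export
trigger_history_sums <- function(tr, data, n_star = Inf) {
  data <- as_event_catalog(data)
  if (!is.infinite(n_star) && (n_star < 0 || n_star != round(n_star))) {
    abort("n_star must be a nonnegative integer or Inf")
  }
  cpp_trigger_history_sums(data$x, data$y, data$t,
                           tr$alpha, tr$beta, tr$gamma, n_star)
}

#' Log-likelihood of a space-time self-exciting model
#'
#' The exact log-likelihood over S x D,
#' `loglik = point_term - background_compensator - trigger_compensator`,
#' where the point term evaluates the (truncated-history) conditional
#' intensity at each event and both compensators are closed forms in normal
#' distribution functions — no numerical integration is involved.
#'
#' An intensity that underflows to zero at some event is floored at the
#' smallest positive double and flagged in the `degenerate` column rather
#' than silently returning `-Inf`.
#'
#' @param model A [model_spec()]; its `n_star` truncates the history sums.
#' @param data Event catalog, sorted in time, inside S x D.
#' @param region A [spatial_region()].
#' @param window A [time_window()].
#' @return A one-row tibble with columns `loglik`, `point_term`,
#'   `background_compensator`, `trigger_compensator`, `degenerate`.
#' @export
log_likelihood <- function(model, data, region, window) {
  data <- as_event_catalog(data)
  bg <- model$background; tr <- model$trigger
  parts <- cpp_loglik(data$x, data$y, data$t,
                      bg$a, bg$c, bg$d, bg$alpha, bg$beta,
                      tr$b, tr$alpha, tr$beta, tr$gamma,
                      model$n_star,
                      region$x_lo, region$x_hi, region$y_lo, region$y_hi,
                      window$t_lo, window$t_hi)
  tibble(loglik = parts$point_term - parts$background_compensator -
           parts$trigger_compensator,
         point_term = parts$point_term,
         background_compensator = parts$background_compensator,
         trigger_compensator = parts$trigger_compensator,
         degenerate = parts$degenerate)
}
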