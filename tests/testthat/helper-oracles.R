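# Independent oracles and fixture builders used across the suite. All
# oracles are deliberately naive (scalar loops, adaptive quadrature) and
# share no code with the package internals they check.

toy_catalog <- function(n, region = spatial_region(0, 4, 0, 4), t_max = 10,
                        seed = 1) {
  withr::with_seed(seed, event_catalog(t = sort(runif(n, 0, t_max)),
                                       x = runif(n, region$x_lo, region$x_hi),
                                       y = runif(n, region$y_lo, region$y_hi)))
}

random_bg <- function(p, seed, center_box = c(1, 3)) {
  withr::with_seed(seed, bg_params(a = runif(p + 1, 0.5, 2),
                                   c = runif(p + 1, center_box[1], center_box[2]),
                                   d = runif(p + 1, center_box[1], center_box[2]),
                                   alpha = runif(p + 1, 0.2, 1.5),
                                   beta = runif(p + 1, 0.2, 1.5)))
}

random_tr <- function(q, seed) {
  withr::with_seed(seed, trig_params(b = runif(q + 1, 0.05, 0.3),
                                     alpha = runif(q + 1, 0.3, 2),
                                     beta = runif(q + 1, 0.3, 2),
                                     gamma = runif(q + 1, 0.3, 1.5)))
}

# scalar-loop kernel evaluations
oracle_background <- function(bg, x, y) {
  out <- numeric(length(x))
  for (k in seq_along(x)) {
    acc <- 0
    for (j in seq_len(nrow(bg))) {
      acc <- acc + bg$a[j] * exp(-bg$alpha[j] * (x[k] - bg$c[j])^2 -
                                   bg$beta[j] * (y[k] - bg$d[j])^2)
    }
    out[k] <- acc
  }
  out
}

oracle_trigger <- function(tr, dx, dy, dt) {
  out <- numeric(length(dx))
  for (k in seq_along(dx)) {
    acc <- 0
    for (j in seq_len(nrow(tr))) {
      acc <- acc + tr$b[j] * exp(-tr$alpha[j] * dx[k]^2 - tr$beta[j] * dy[k]^2 -
                                   tr$gamma[j] * dt[k])
    }
    out[k] <- acc
  }
  out
}

# naive double-loop conditional intensity (full history)
oracle_intensity <- function(model, cat, x, y, t) {
  out <- numeric(length(x))
  for (k in seq_along(x)) {
    acc <- oracle_background(model$background, x[k], y[k])
    for (i in seq_len(nrow(cat))) {
      if (cat$t[i] < t[k]) {
        acc <- acc + oracle_trigger(model$trigger, x[k] - cat$x[i],
                                    y[k] - cat$y[i], t[k] - cat$t[i])
      }
    }
    out[k] <- acc
  }
  out
}

# direct numerical integral of the conditional intensity over S x D,
# integrating time slab by slab so the integrand is smooth on each piece
oracle_compensator <- function(model, cat, region, window, reltol = 1e-9) {
  knots <- sort(unique(c(window$t_lo, window$t_hi,
                         cat$t[cat$t > window$t_lo & cat$t < window$t_hi])))
  total <- 0
  for (s in seq_len(length(knots) - 1)) {
    s0 <- knots[s]; s1 <- knots[s + 1]
    active <- which(cat$t <= s0)
    f <- function(x, y, t) {
      lam <- eval_background(model$background, x, y)
      for (i in active) {
        lam <- lam + eval_trigger(model$trigger, x - cat$x[i], y - cat$y[i],
                                  t - cat$t[i])
      }
      lam
    }
    total <- total + pracma::integral3(f, region$x_lo, region$x_hi,
                                       region$y_lo, region$y_hi, s0, s1,
                                       reltol = reltol)
  }
  total
}

# full-history log-likelihood by brute force: naive point term plus the
# quadrature compensator
oracle_loglik <- function(model, cat, region, window) {
  lam <- oracle_intensity(model, cat, cat$x, cat$y, cat$t)
  sum(log(lam)) - oracle_compensator(model, cat, region, window)
}

oracle_n_star <- function(t, z) {
  n <- length(t)
  best <- 0L
  for (k in seq_len(n)) {
    best <- max(best, sum(t >= t[k] - z & t < t[k]))
  }
  best
}

# brute-force edge-corrected K with a fine circle discretization
oracle_ripley_k <- function(cat, region, distances, n_circ = 8192) {
  n <- nrow(cat)
  frac_inside <- function(cx, cy, r) {
    ang <- 2 * pi * (0:(n_circ - 1)) / n_circ
    px <- cx + r * cos(ang); py <- cy + r * sin(ang)
    max(mean(px >= region$x_lo & px <= region$x_hi &
               py >= region$y_lo & py <= region$y_hi), 1 / n_circ)
  }
  K <- numeric(length(distances))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dij <- sqrt((cat$x[i] - cat$x[j])^2 + (cat$y[i] - cat$y[j])^2)
      hit <- distances > dij
      if (any(hit)) {
        K[hit] <- K[hit] + 1 / frac_inside(cat$x[i], cat$y[i], dij)
      }
    }
  }
  region_area(region) * K / n^2
}

# shared truth model for the reference simulation settings (full history)
truth_model_single <- function(n_star = Inf) {
  model_spec(bg_params_natural(5.71, 4.5, c = 10, d = 10),
             trig_params_natural(0.2, 0.1, 0.01, 0.1), n_star = n_star)
}

truth_model_multi <- function(n_star = Inf) {
  model_spec(bg_params_natural(5.71, 4.5, c = 10, d = 10),
             trig_params_natural(theta = c(0.2, 0.3), omega = c(0.1, 0.2),
                                 sigma_x = c(0.01, 0.2), sigma_y = c(0.1, 0.05)),
             n_star = n_star)
}
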