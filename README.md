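# hawkesmix

Space-time self-exciting (Hawkes) point processes with Gaussian-exponent
mixture kernels: fast exact maximum-likelihood estimation, BIC order
selection, a branching simulator, and super-thinning residual diagnostics.

## What problem this solves

Clustered event data — burglary reports, aftershock sequences, cascades of
transactions — are naturally modeled by a conditional intensity that jumps
after every event:

    lambda(x, y, t | H_t) = mu(x, y) + sum_{i : t_i < t} g(x - x_i, y - y_i, t - t_i)

with a spatially varying, time-invariant background `mu` (spontaneous
"immigrant" events) and a triggering kernel `g` (offspring). hawkesmix
models both as mixtures of Gaussian-type exponent components,

    mu(x, y) = sum_j a_j exp(-alpha_j (x - c_j)^2 - beta_j (y - d_j)^2)
    g(x, y, t) = sum_j b_j exp(-alpha_j x^2 - beta_j y^2 - gamma_j t)

which buys two things at once:

* **flexibility** — the component counts (p + 1, q + 1) are selected by
  BIC, so the mixture approximates a wide range of background surfaces and
  triggering shapes while every fit remains parametric maximum likelihood;
* **speed on large catalogs** — the likelihood's integral (compensator)
  term is an exact closed form in normal distribution functions, and the
  triggering history sum at each event is truncated to the `n_star` most
  recent events, reducing the point-term cost from O(n^2) to
  O(n n_star). No numerical integration appears anywhere in a fit.

Estimates are reported on the natural scale: triggering mass
`theta = b pi / (gamma sqrt(alpha beta))` (expected direct offspring per
event, < 1 for a subcritical process), temporal decay `omega = gamma`,
spatial scales `sigma = 1 / sqrt(2 alpha)`, and background rate
`mu_bar = a pi / sqrt(alpha beta)`.

The package is tidyverse-shaped: catalogs are tibbles with columns
`t, x, y`, every user-facing function takes a data frame first, fitted
objects support `tidy()` / `glance()` / `autoplot()`, and results compose
with the pipe.

## Worked example

Simulate a catalog from the reference single-component generating model
(background rate 5.71 events/day spread as a Gaussian with sd 4.5 km
centered at (10, 10) in a 20 x 20 km domain; each event triggers on
average theta = 0.2 offspring with Exp(0.1)/day lags and (0.01, 0.1) km
offsets), then refit it:

```r
library(hawkesmix)

region  <- spatial_region(0, 20, 0, 20)
catalog <- simulate_catalog(kernel_single(), target_n = 5000,
                            region = region, trim = 2000, seed = 42)
fit <- fit_hawkes(catalog, region, catalog_window(catalog), p = 0, q = 0,
                  options = fit_options(n_star = 200, restarts = 1, seed = 7))
to_natural_scale(fit)
#> # A tibble: 2 × 9
#>   kernel     component mu_bar     c     d  theta  omega sigma_x sigma_y
#>   <chr>          <int>  <dbl> <dbl> <dbl>  <dbl>  <dbl>   <dbl>   <dbl>
#> 1 background         1   5.83  9.96  9.91 NA     NA      4.71     4.53
#> 2 trigger            1  NA    NA    NA     0.194  0.123  0.0100   0.101
```

Reading the output: the background rate (5.83/day) and center are
recovered; the triggering spatial scales match the truth to three
decimals. The decay `omega = 0.123` (truth 0.1) and mass `theta = 0.194`
(truth 0.2) carry the deliberate, reproducible bias of the
200-event-truncated likelihood — the history window spans ~28 days, so
lags beyond that never enter the point term; see the methods vignette
(`vignettes/hawkesmix-methods.Rmd`) for the arithmetic. `glance(fit)`
adds the log-likelihood and BIC; `select_order()` scans a (p, q) grid.

Diagnostics: super-thin the catalog under the fitted model and compare the
residuals' centered L function with a homogeneous-Poisson envelope:

```r
diag <- residual_diagnostics(fit, catalog, region, catalog_window(catalog),
                             M = 100, seed = 1)
autoplot(diag)   # curve inside the grey band = no unexplained clustering
```

A thin CLI wraps the same functions
(`inst/cli/hawkesmix simulate|fit|select|diagnose`), and
`read_catalog()` / `write_catalog()` / `project_equirectangular()` handle
CSV catalogs and lon/lat inputs.

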