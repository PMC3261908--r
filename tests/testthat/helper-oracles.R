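# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's segment algebra and bracket-scan internals: they work
# on dense grids with sign-change detection plus bisection.

# All crossings of the log-log-interpolated IOC with y = s * x, by dense
# scan over an extended range (covering both flat tails) and bisection.
oracle_intersections <- function(obj, line, n_grid = 1e5) {
  # range wide enough to cover flat-tail crossings at y/s on either side
  lo <- min(min(obj$input), min(obj$output) / line$scale) / 10
  hi <- max(max(obj$input), max(obj$output) / line$scale) * 10
  xs <- exp(seq(log(lo), log(hi), length.out = n_grid))
  # include the nodes themselves so two crossings flanking a node never
  # share one scan cell (each log-log segment is linear: one crossing max)
  xs <- sort(unique(c(xs, obj$input)))
  n_grid <- length(xs)
  h <- log(loglog_interp(obj, xs)) - log(line$scale * xs)
  roots <- numeric(0)
  idx <- which(h[-1] * h[-n_grid] < 0 | h[-n_grid] == 0)
  for (i in idx) {
    r <- stats::uniroot(function(x) log(loglog_interp(obj, x)) -
                          log(line$scale * x),
                        c(xs[i], xs[i + 1]), tol = 1e-12 * xs[i + 1])$root
    roots <- c(roots, r)
  }
  sort(roots)
}

# All roots of lambda * f(x) - x = 0 by dense scan (default 1e5 points,
# far finer than the package's 512-point bracket scan) plus bisection.
oracle_roots <- function(g, lambda, eps, n_grid = 1e5) {
  xs <- exp(seq(log(lambda * eps / 20), log(20 * lambda),
                length.out = n_grid))
  h <- g(xs) - xs
  roots <- numeric(0)
  idx <- which(h[-1] * h[-n_grid] < 0 | h[-n_grid] == 0)
  for (i in idx) {
    r <- stats::uniroot(function(x) g(x) - x, c(xs[i], xs[i + 1]),
                        tol = 1e-12 * xs[i + 1])$root
    roots <- c(roots, r)
  }
  sort(roots)
}

# Random valid PLF parameter draws over broad log-uniform ranges
random_plf_params <- function() {
  plf_params(
    basal_fraction = 10^stats::runif(1, -3, -1),
    ahl_luxr_halfsat = 10^stats::runif(1, -1, 1),
    luxr_dna_halfsat = 10^stats::runif(1, 1, 3),
    hill_m = stats::runif(1, 1, 3),
    hill_n = stats::runif(1, 0.8, 2.5),
    ahl_density_const = 10^stats::runif(1, -2, 0),
    density = 10^stats::runif(1, -2, 0)
  )
}

# Random monotone IOC on a log grid (random node count, range and shape)
random_monotone_ioc <- function() {
  k <- sample(4:9, 1)
  x <- sort(10^stats::runif(k, 0, 3))
  while (any(diff(x) == 0)) x <- sort(10^stats::runif(k, 0, 3))
  y0 <- 10^stats::runif(1, -1, 1)
  steps <- 10^stats::runif(k - 1, 0, 1.2)
  ioc(x, y0 * cumprod(c(1, steps)), axis = "luxI")
}
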