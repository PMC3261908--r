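# Scalar root scan for g(x) - x = 0 with g = lambda * f(.): brackets on a
# log grid over [lambda*eps/10, 10*lambda] (steady states are confined to
# [lambda*eps, lambda]), refined by uniroot to 1e-8 relative.
scan_roots <- function(g, lambda, eps, n_scan = 512, rel_tol = 1e-8) {
  xs <- exp(seq(log(lambda * eps / 10), log(10 * lambda), length.out = n_scan))
  h <- g(xs) - xs
  roots <- numeric(0)
  sgn <- sign(h)
  for (i in seq_len(n_scan - 1)) {
    if (sgn[i] == 0) {
      roots <- c(roots, xs[i])
    } else if (sgn[i] * sgn[i + 1] < 0) {
      r <- stats::uniroot(function(x) g(x) - x, c(xs[i], xs[i + 1]),
                          tol = rel_tol * xs[i + 1])$root
      roots <- c(roots, r)
    }
  }
  if (sgn[n_scan] == 0) roots <- c(roots, xs[n_scan])
  if (!length(roots)) return(roots)
  roots <- sort(roots)
  roots[c(TRUE, diff(roots) / roots[-length(roots)] > 10 * rel_tol)]
}

#' Steady states of a 1-D feedback loop at a given density
#'
#' Finds all roots of `lambda * f(x; rho) - x = 0` for the feedback
#' variable `x` by a log-spaced bracket scan (512 points over
#' `[lambda*eps/10, 10*lambda]`) refined by bisection to `1e-8` relative.
#' Stability is assigned from the sign of the derivative of
#' `lambda * f(x) - x` at each root; the stable/unstable alternation of a
#' one-dimensional monotone-response system is cross-checked.
#'
#' @param topo A 1-D feedback [topology_spec].
#' @param p A [plf_params]; its `density` field is overridden by `rho`.
#' @param rho Cell density (OD600, >= 0).
#' @return A `fixed_points` data frame (`level`, `stability`), ascending.
#' @export
steady_states_at_density <- function(topo, p, rho) {
  stopifnot(inherits(topo, "topology_spec"),
            topo$kind %in% c("luxR_feedback", "luxI_feedback"))
  validate_plf_params(p)
  if (!is.finite(rho) || rho < 0) stop("rho must be >= 0", call. = FALSE)
  p$density <- rho
  lambda <- feedback_lambda(topo)
  g <- feedback_map(topo, p)
  roots <- scan_roots(g, lambda, p$basal_fraction)
  stab <- vapply(roots, function(r) {
    dx <- 1e-5 * r
    slope <- (g(r + dx) - g(r - dx)) / (2 * dx)
    if (abs(slope - 1) < 1e-6) "unknown"
    else if (slope < 1) "stable" else "unstable"
  }, "")
  fp <- structure(data.frame(level = roots, stability = stab),
                  class = c("fixed_points", "data.frame"))
  known <- fp$stability[fp$stability != "unknown"]
  if (length(known) > 1 && any(known[-1] == known[-length(known)]))
    warning("stability labels do not alternate; near-degenerate parameters",
            call. = FALSE)
  fp
}

n_roots_at <- function(topo, p, rho)
  nrow(steady_states_at_density(topo, p, rho))

#' Compute a density-dependent response curve
#'
#' Sweeps cell density over a grid, collects the steady states of the
#' feedback loop at each density, and locates the fold (saddle-node)
#' densities bounding the bistable interval by bisection on the
#' root-count change (to `1e-3` relative density). The DDR is the moving
#' target towards which the circuit converges as density increases.
#'
#' @param topo A 1-D feedback [topology_spec].
#' @param p A [plf_params].
#' @param density_grid Ascending positive densities (default 400
#'   log-spaced points over `[1e-4, 1]` OD600).
#' @param rho_T Terminal density (OD600) used for classification.
#' @return An object of class `ddr_curve`: `branches` (data frame
#'   `density`, `level`, `stability`), `rho_low`, `rho_high` (fold
#'   densities, `NA` when monostable throughout), `rho_T`, and `flagged`
#'   (TRUE when a root count other than 1 or 3 was met).
#' @export
compute_ddr <- function(topo, p,
                        density_grid = exp(seq(log(1e-4), log(1), length.out = 400)),
                        rho_T = 0.05) {
  if (is.unsorted(density_grid, strictly = TRUE) || any(density_grid <= 0))
    stop("density_grid must be ascending and > 0", call. = FALSE)
  states <- lapply(density_grid, function(rho)
    steady_states_at_density(topo, p, rho))
  counts <- vapply(states, nrow, 1L)
  flagged <- any(!counts %in% c(1L, 3L))
  if (flagged)
    warning("root count other than 1 or 3 encountered (degenerate parameters)",
            call. = FALSE)
  branches <- do.call(rbind, Map(function(rho, fp)
    data.frame(density = rho, level = fp$level, stability = fp$stability),
    density_grid, states))

  # fold densities: bisection on the root-count transitions
  refine <- function(lo, hi) {
    n_lo <- n_roots_at(topo, p, lo)
    for (k in 1:40) {
      mid <- sqrt(lo * hi)
      if (n_roots_at(topo, p, mid) == n_lo) lo <- mid else hi <- mid
      if ((hi - lo) / hi < 1e-3) break
    }
    sqrt(lo * hi)
  }
  rho_low <- rho_high <- NA_real_
  multi <- which(counts >= 3)
  if (length(multi)) {
    on_i <- min(multi)
    off_i <- max(multi)
    rho_low <- if (on_i > 1) refine(density_grid[on_i - 1], density_grid[on_i])
               else density_grid[1]
    rho_high <- if (off_i < length(counts))
                  refine(density_grid[off_i], density_grid[off_i + 1])
                else density_grid[length(counts)]
  }
  structure(list(branches = branches, rho_low = rho_low, rho_high = rho_high,
                 rho_T = rho_T, flagged = flagged,
                 density_grid = density_grid, counts = counts,
                 topo = topo, params = p),
            class = "ddr_curve")
}

#' @export
print.ddr_curve <- function(x, ...) {
  cat(sprintf("Density-dependent response (%s), %d densities\n",
              x$topo$kind, length(x$density_grid)))
  if (is.finite(x$rho_low))
    cat(sprintf("  bistable for rho in [%.4g, %.4g] OD600\n",
                x$rho_low, x$rho_high))
  else cat("  monostable at every density\n")
  cat(sprintf("  terminal density rho_T = %.4g; class %s\n",
              x$rho_T, classify_ddr(x)))
  invisible(x)
}

#' Classify a density-dependent response
#'
#' Four exhaustive, mutually exclusive classes given the bistable density
#' interval `[rho_low, rho_high]` and the terminal density `rho_T`:
#' \describe{
#'   \item{`"M"`}{monostable: no bistable interval over the densities
#'     considered; transcription rises smoothly.}
#'   \item{`"B+"`}{bistable with `rho_T > rho_high`: an abrupt threshold
#'     is crossed before the terminal density.}
#'   \item{`"B+-"`}{bistable and hysteretic at the terminal density
#'     (`rho_low <= rho_T <= rho_high`): ON- and OFF-history populations
#'     settle to different states.}
#'   \item{`"B-"`}{bistable with `rho_T < rho_low`: the potentially
#'     bistable region is never reached; cells stay un-induced.}
#' }
#'
#' @param ddr A `ddr_curve`.
#' @return One of `"M"`, `"B+"`, `"B+-"`, `"B-"`.
#' @export
classify_ddr <- function(ddr) {
  stopifnot(inherits(ddr, "ddr_curve"))
  if (!is.finite(ddr$rho_low)) return("M")
  if (ddr$rho_T > ddr$rho_high) return("B+")
  if (ddr$rho_T < ddr$rho_low) return("B-")
  "B+-"
}

#' Map DDR classes over (Hill coefficient, regulator level) space
#'
#' Classifies the density-dependent response of a feedback topology on a
#' grid of the LuxR-DNA Hill coefficient `n` (x-axis) and the clamped
#' regulator level (y-axis, log-spaced), holding all other parameters
#' fixed. Both feedback topologies can be mapped on identical slices;
#' boundaries between classes are resolved to cell resolution.
#'
#' @param topo A 1-D feedback [topology_spec] (its regulator field is
#'   overridden cell by cell).
#' @param p A [plf_params] (its `hill_n` is overridden cell by cell).
#' @param n_range Length-2 range of Hill coefficients (> 0).
#' @param regulator_range Length-2 positive range of regulator levels.
#' @param rho_T Terminal density for classification.
#' @param resolution Cells per axis (>= 10).
#' @param density_grid Densities scanned per cell (coarser than
#'   [compute_ddr()]'s default keeps the map affordable; folds are still
#'   refined by bisection).
#' @return A data frame with columns `hill_n`, `regulator`, `class`,
#'   `rho_low`, `rho_high`.
#' @export
bifurcation_map <- function(topo, p, n_range = c(1, 4), regulator_range,
                            rho_T = 0.05, resolution = 20,
                            density_grid = exp(seq(log(1e-4), log(1),
                                                   length.out = 120))) {
  if (resolution < 10) stop("resolution must be >= 10", call. = FALSE)
  if (any(n_range <= 0) || any(regulator_range <= 0))
    stop("ranges must be positive", call. = FALSE)
  ns <- seq(n_range[1], n_range[2], length.out = resolution)
  regs <- exp(seq(log(regulator_range[1]), log(regulator_range[2]),
                  length.out = resolution))
  reg_field <- if (topo$kind == "luxR_feedback") "luxI_fixed" else "luxR_fixed"
  rows <- vector("list", resolution^2)
  k <- 0L
  for (n in ns) {
    p_n <- p
    p_n$hill_n <- n
    for (reg in regs) {
      topo_r <- topo
      topo_r[[reg_field]] <- reg
      ddr <- suppressWarnings(
        compute_ddr(topo_r, p_n, density_grid = density_grid, rho_T = rho_T))
      k <- k + 1L
      rows[[k]] <- data.frame(hill_n = n, regulator = reg,
                              class = classify_ddr(ddr),
                              rho_low = ddr$rho_low, rho_high = ddr$rho_high)
    }
  }
  do.call(rbind, rows)
}

#' Dynamic response under logistic growth
#'
#' Co-integrates logistic cell growth
#' `drho/dt = r * rho * (1 - rho / K)` with the feedback circuit ODE
#' (whose PLF is evaluated at the instantaneous density), and overlays the
#' quasi-static target: at each output time, the stable steady state on
#' the history-connected branch of the instantaneous DDR. Because the
#' intracellular kinetics are finite, the dynamic output lags this moving
#' target, most visibly near sharp thresholds (critical slowing down).
#'
#' @param topo A 1-D feedback [topology_spec].
#' @param p A [plf_params].
#' @param growth_rate Logistic rate `r` (1/time, > 0).
#' @param carrying_capacity Carrying capacity `K` (OD600, default 1).
#' @param rho0 Inoculation density (OD600).
#' @param times Output time grid.
#' @param history `"OFF"` (start at basal) or `"ON"` (start saturated).
#' @return A data frame `time`, `density`, `output`, `target` of class
#'   `dynamic_response`.
#' @export
dynamic_response <- function(topo, p, growth_rate, carrying_capacity = 1,
                             rho0 = 1e-4, times = seq(0, 20, length.out = 201),
                             history = c("OFF", "ON")) {
  history <- match.arg(history)
  if (!is.finite(growth_rate) || growth_rate <= 0)
    stop("growth_rate must be > 0", call. = FALSE)
  lambda <- feedback_lambda(topo)
  x0 <- if (history == "OFF") lambda * p$basal_fraction else lambda
  rhs <- function(t, state, parms) {
    rho <- state[1]
    p_t <- p
    p_t$density <- max(rho, 0)
    dx <- ode_rhs(t, state[2], topo = topo, p = p_t)[[1]]
    list(c(growth_rate * rho * (1 - rho / carrying_capacity), dx))
  }
  sol <- deSolve::ode(y = c(rho = rho0, x = x0), times = times, func = rhs,
                      parms = NULL, method = "lsoda")
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failed; see deSolve diagnostics", call. = FALSE)
  out <- as.data.frame(sol)
  names(out) <- c("time", "density", "output")
  # history-connected quasi-static target by nearest-neighbour continuation
  target <- numeric(nrow(out))
  prev <- x0
  for (i in seq_len(nrow(out))) {
    fp <- steady_states_at_density(topo, p, out$density[i])
    st <- fp$level[fp$stability == "stable"]
    if (!length(st)) st <- fp$level
    target[i] <- st[which.min(abs(log(st) - log(prev)))]
    prev <- target[i]
  }
  out$target <- target
  class(out) <- c("dynamic_response", "data.frame")
  out
}
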