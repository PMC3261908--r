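#' Dual positive/negative-feedback oscillator parameters
#'
#' The dual-feedback circuit expresses LuxR (positive feedback) and the
#' repressor LacI (negative feedback) from pR, while LuxI is expressed
#' from the LacI-repressed pLac promoter. With LacI at quasi-steady state
#' proportional to pR activity, the phase plane is two-dimensional:
#' \deqn{dR/dt = \gamma_R (\lambda_R f(I, R; \rho) - R)}
#' \deqn{dI/dt = \gamma_I (\beta_I / (1 + (L/K_L)^{h_L}) - I), \quad
#'       L = \lambda_L f(I, R; \rho)}
#' Cell density is clamped (chemostat); it enters only through the AHL
#' level `A = c * rho * I`. The LuxI response rate `gamma_I` is the free
#' dynamical parameter whose value decides stability of the fixed point.
#'
#' @param plf A [plf_params]; its density is overridden by `density`.
#' @param lambda_R,gamma_R LuxR production scale (fluorescence) and
#'   response rate (1/time).
#' @param beta_I Maximal (unrepressed) LuxI level from pLac (fluorescence).
#' @param gamma_I LuxI response rate (1/time); the free parameter.
#' @param lambda_L LacI level per unit pR transcription (fluorescence).
#' @param K_L LacI level half-repressing pLac (fluorescence).
#' @param h_L Hill coefficient of LacI-pLac repression (default 2,
#'   a tetramer-cooperativity convention; a package choice).
#' @param density Clamped chemostat density (OD600; default 0.185).
#' @return An object of class `oscillator_params`.
#' @export
oscillator_params <- function(plf, lambda_R, gamma_R = 1, beta_I, gamma_I,
                              lambda_L = 1, K_L, h_L = 2, density = 0.185) {
  validate_plf_params(plf)
  plf$density <- density
  vals <- c(lambda_R = lambda_R, gamma_R = gamma_R, beta_I = beta_I,
            gamma_I = gamma_I, lambda_L = lambda_L, K_L = K_L, h_L = h_L,
            density = density)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all oscillator rates and scales must be positive", call. = FALSE)
  structure(list(plf = plf, lambda_R = lambda_R, gamma_R = gamma_R,
                 beta_I = beta_I, gamma_I = gamma_I, lambda_L = lambda_L,
                 K_L = K_L, h_L = h_L, density = density),
            class = "oscillator_params")
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat("Dual positive/negative-feedback oscillator\n")
  cat(sprintf("  lambda_R=%.4g gamma_R=%.4g | beta_I=%.4g gamma_I=%.4g\n",
              x$lambda_R, x$gamma_R, x$beta_I, x$gamma_I))
  cat(sprintf("  LacI: lambda_L=%.4g K_L=%.4g h_L=%.3g | rho=%.4g OD600\n",
              x$lambda_L, x$K_L, x$h_L, x$density))
  invisible(x)
}

# Vector field of the 2-D reduced system; state = c(R, I)
oscillator_field <- function(state, op) {
  R <- max(state[1], 0)
  I <- max(state[2], 0)
  f <- plf_eval(I, R, op$plf)
  L <- op$lambda_L * f
  rep_frac <- 1 / (1 + (L / op$K_L)^op$h_L)
  c(op$gamma_R * (op$lambda_R * f - R),
    op$gamma_I * (op$beta_I * rep_frac - I))
}

#' Nullclines of the oscillator in the (LuxI, LuxR) plane
#'
#' The LuxR nullcline collects all solutions of
#' `R = lambda_R * f(I, R)` for each LuxI level on a log grid (there may
#' be up to three per LuxI level, reflecting the positive feedback); the
#' LuxI nullcline collects all solutions of
#' `I = beta_I / (1 + (lambda_L f(I,R)/K_L)^h_L)` for each LuxR level.
#' Grid columns where no solution lies inside the scanned range are
#' reported in the `empty` counts.
#'
#' @param op An [oscillator_params].
#' @param I_range,R_range Positive length-2 ranges to scan.
#' @param n_grid Grid columns per nullcline.
#' @return A list with data frames `luxR_nullcline` and `luxI_nullcline`
#'   (columns `I`, `R`) and integer `empty` counts per curve.
#' @export
nullclines <- function(op, I_range, R_range, n_grid = 101) {
  stopifnot(inherits(op, "oscillator_params"))
  if (any(I_range <= 0) || any(R_range <= 0))
    stop("ranges must be positive", call. = FALSE)
  Is <- exp(seq(log(I_range[1]), log(I_range[2]), length.out = n_grid))
  Rs <- exp(seq(log(R_range[1]), log(R_range[2]), length.out = n_grid))
  empty <- c(luxR = 0L, luxI = 0L)

  rn <- do.call(rbind, lapply(Is, function(I) {
    g <- function(R) op$lambda_R * plf_eval(I, R, op$plf)
    roots <- scan_roots(g, op$lambda_R, op$plf$basal_fraction)
    roots <- roots[roots >= R_range[1] & roots <= R_range[2]]
    if (!length(roots)) {
      empty["luxR"] <<- empty["luxR"] + 1L
      return(NULL)
    }
    data.frame(I = I, R = roots)
  }))
  inl <- do.call(rbind, lapply(Rs, function(R) {
    g <- function(I) {
      L <- op$lambda_L * plf_eval(I, R, op$plf)
      op$beta_I / (1 + (L / op$K_L)^op$h_L)
    }
    # I-nullcline roots of g(I) - I; g is bounded in (0, beta_I]
    roots <- scan_roots(g, op$beta_I, 1e-6)
    roots <- roots[roots >= I_range[1] & roots <= I_range[2]]
    if (!length(roots)) {
      empty["luxI"] <<- empty["luxI"] + 1L
      return(NULL)
    }
    data.frame(I = roots, R = R)
  }))
  if (any(empty > 0))
    warning("nullcline segments empty in ", sum(empty), " grid column(s)",
            call. = FALSE)
  list(luxR_nullcline = rn, luxI_nullcline = inl, empty = empty)
}

# Central-difference Jacobian of the oscillator field
oscillator_jacobian <- function(state, op, h_rel = 1e-6) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    h <- h_rel * max(abs(state[j]), 1e-8)
    up <- dn <- state
    up[j] <- state[j] + h
    dn[j] <- state[j] - h
    J[, j] <- (oscillator_field(up, op) - oscillator_field(dn, op)) / (2 * h)
  }
  J
}

#' Fixed point(s) of the oscillator and their linear stability
#'
#' Damped Newton iteration (numeric Jacobian, step halving on residual
#' increase) from a lattice of multiplicative starting points; converged
#' solutions are deduplicated and returned with the eigenvalues of the
#' central-difference Jacobian. The first (lowest-LuxR) fixed point is the
#' primary one.
#'
#' @param op An [oscillator_params].
#' @param n_starts Starting points per axis (default 5).
#' @return A list of fixed points; each element has `R`, `I`,
#'   `eigenvalues` (complex pair), `max_re` and `jacobian`. Errors if no
#'   root is found.
#' @export
fixed_point <- function(op, n_starts = 5) {
  stopifnot(inherits(op, "oscillator_params"))
  starts_R <- exp(seq(log(op$lambda_R * op$plf$basal_fraction / 3),
                      log(op$lambda_R * 3), length.out = n_starts))
  starts_I <- exp(seq(log(op$beta_I * 1e-3), log(op$beta_I * 3),
                      length.out = n_starts))
  sols <- list()
  for (R0 in starts_R) for (I0 in starts_I) {
    x <- c(R0, I0)
    ok <- FALSE
    for (it in 1:100) {
      Fx <- oscillator_field(x, op)
      nf <- sqrt(sum(Fx^2))
      if (nf < 1e-10 * max(op$lambda_R, op$beta_I)) {
        ok <- TRUE
        break
      }
      J <- oscillator_jacobian(x, op)
      step <- tryCatch(solve(J, -Fx), error = function(e) NULL)
      if (is.null(step)) break
      t_damp <- 1
      repeat {
        xn <- pmax(x + t_damp * step, 1e-12)
        if (sqrt(sum(oscillator_field(xn, op)^2)) < nf || t_damp < 1e-4) break
        t_damp <- t_damp / 2
      }
      if (max(abs(xn - x) / pmax(abs(x), 1e-12)) < 1e-13) {
        x <- xn
        ok <- sqrt(sum(oscillator_field(x, op)^2)) <
          1e-8 * max(op$lambda_R, op$beta_I)
        break
      }
      x <- xn
    }
    if (!ok) next
    dup <- any(vapply(sols, function(s)
      abs(log(s$R / x[1])) < 1e-6 && abs(log(s$I / x[2])) < 1e-6, TRUE))
    if (!dup) {
      J <- oscillator_jacobian(x, op)
      ev <- eigen(J, only.values = TRUE)$values
      sols[[length(sols) + 1]] <- list(R = x[1], I = x[2],
                                       eigenvalues = ev,
                                       max_re = max(Re(ev)),
                                       jacobian = J)
    }
  }
  if (!length(sols))
    stop("no oscillator fixed point found from any start", call. = FALSE)
  sols[order(vapply(sols, `[[`, 1, "R"))]
}

#' Simulate the oscillator
#'
#' Integrates the two-dimensional reduced system (or the explicit-LacI
#' three-dimensional variant) with [deSolve::ode()] and detects a
#' sustained limit cycle by peak analysis on the second half of the run:
#' the period is the mean inter-peak interval of LuxR maxima and is
#' reported only when at least three consecutive intervals agree within
#' 5%.
#'
#' @param op An [oscillator_params].
#' @param init Numeric `c(R, I)` (or `c(R, I, L)` when
#'   `explicit_lacI = TRUE`); default: basal LuxR, unrepressed LuxI.
#' @param duration Total integration time (should cover >= 10 relaxation
#'   times `1/min(gamma)`).
#' @param dt Output time step.
#' @param explicit_lacI Integrate LacI as a third state variable with
#'   response rate `gamma_L` instead of the quasi-steady-state reduction.
#' @param gamma_L LacI response rate for the 3-D variant.
#' @return An object of class `oscillator_trajectory`: data frame
#'   `time`, `R`, `I` (and `L` for the 3-D variant) with attributes
#'   `period`, `amplitude_R`, `oscillating`.
#' @export
simulate_oscillator <- function(op, init = NULL, duration = 400, dt = 0.05,
                                explicit_lacI = FALSE, gamma_L = 1) {
  stopifnot(inherits(op, "oscillator_params"))
  if (is.null(init)) {
    init <- c(R = op$lambda_R * op$plf$basal_fraction, I = op$beta_I)
    if (explicit_lacI) init <- c(init, L = op$lambda_L * op$plf$basal_fraction)
  }
  rhs <- function(t, y, parms) {
    if (!explicit_lacI) return(list(oscillator_field(y, op)))
    R <- max(y[1], 0); I <- max(y[2], 0); L <- max(y[3], 0)
    f <- plf_eval(I, R, op$plf)
    rep_frac <- 1 / (1 + (L / op$K_L)^op$h_L)
    list(c(op$gamma_R * (op$lambda_R * f - R),
           op$gamma_I * (op$beta_I * rep_frac - I),
           gamma_L * (op$lambda_L * f - L)))
  }
  times <- seq(0, duration, by = dt)
  sol <- deSolve::ode(y = init, times = times, func = rhs, parms = NULL,
                      method = "lsoda")
  if (attr(sol, "istate")[1] < 0)
    stop("oscillator integration failed", call. = FALSE)
  traj <- as.data.frame(sol)
  names(traj)[1] <- "time"
  names(traj)[2:3] <- c("R", "I")
  if (explicit_lacI) names(traj)[4] <- "L"

  # limit-cycle detection on the second half of the run
  tail_i <- traj$time >= duration / 2
  Rt <- traj$R[tail_i]
  tt <- traj$time[tail_i]
  pk <- which(diff(sign(diff(Rt))) == -2) + 1
  period <- NA_real_
  amp <- NA_real_
  oscillating <- FALSE
  if (length(pk) >= 4) {
    iv <- diff(tt[pk])
    rng <- diff(range(Rt))
    prominent <- rng > 0.01 * stats::median(Rt)
    consistent <- length(iv) >= 3 &&
      all(abs(iv - mean(iv)) / mean(iv) < 0.05)
    if (prominent && consistent) {
      period <- mean(iv)
      amp <- (max(Rt) - min(Rt)) / 2
      oscillating <- TRUE
    }
  }
  structure(traj, period = period, amplitude_R = amp,
            oscillating = oscillating,
            class = c("oscillator_trajectory", "data.frame"))
}

#' @export
print.oscillator_trajectory <- function(x, ...) {
  cat(sprintf("Oscillator trajectory: %d steps over t in [%.3g, %.3g]\n",
              nrow(x), min(x$time), max(x$time)))
  if (isTRUE(attr(x, "oscillating")))
    cat(sprintf("  sustained limit cycle: period %.4g, LuxR amplitude %.4g\n",
                attr(x, "period"), attr(x, "amplitude_R")))
  else cat("  no sustained oscillation detected\n")
  invisible(x)
}

#' Locate the Hopf boundary in the LuxI response rate
#'
#' Bisects on the maximal real part of the fixed-point Jacobian
#' eigenvalues over a bracketing range of `gamma_I`, to `1e-4` relative.
#' On one side of the boundary the fixed point is stable (the system
#' settles); on the other it is unstable and a limit cycle emerges.
#'
#' @param op An [oscillator_params] (its `gamma_I` is overridden).
#' @param gamma_I_range Length-2 positive range bracketing a sign change
#'   of the maximal real eigenvalue part.
#' @return A list with `gamma_I_hopf`, `max_re_at_boundary`, and the
#'   bracket endpoints' `max_re`.
#' @export
hopf_scan <- function(op, gamma_I_range) {
  stopifnot(inherits(op, "oscillator_params"))
  if (length(gamma_I_range) != 2 || any(gamma_I_range <= 0) ||
      gamma_I_range[1] >= gamma_I_range[2])
    stop("gamma_I_range must be a positive increasing pair", call. = FALSE)
  max_re_at <- function(g) {
    op$gamma_I <- g
    fps <- fixed_point(op)
    # the dynamically relevant fixed point: largest max Re among those found
    max(vapply(fps, `[[`, 1, "max_re"))
  }
  lo <- gamma_I_range[1]
  hi <- gamma_I_range[2]
  f_lo <- max_re_at(lo)
  f_hi <- max_re_at(hi)
  if (sign(f_lo) == sign(f_hi))
    stop("max Re(eigenvalue) does not change sign over gamma_I_range",
         call. = FALSE)
  while ((hi - lo) / hi > 1e-4) {
    mid <- sqrt(lo * hi)
    f_mid <- max_re_at(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid
      f_lo <- f_mid
    } else {
      hi <- mid
      f_hi <- f_mid
    }
  }
  b <- sqrt(lo * hi)
  list(gamma_I_hopf = b, max_re_at_boundary = max_re_at(b),
       bracket = c(lo, hi), max_re_bracket = c(f_lo, f_hi))
}

#' Canonical default oscillator parameter set
#'
#' The package's reference dual-feedback configuration: PLF constants from
#' [default_plf_params()] at the chemostat density 0.185 OD600, a strong
#' LuxR positive-feedback loop, and LacI-pLac repression tuned so the
#' fixed point loses stability over an accessible range of the LuxI
#' response rate `gamma_I` (the free dynamical parameter).
#'
#' @param gamma_I LuxI response rate (default 0.05, inside the
#'   limit-cycle regime of the defaults; the fixed point restabilizes
#'   above roughly 0.11).
#' @return An [oscillator_params].
#' @export
default_oscillator_params <- function(gamma_I = 0.05) {
  oscillator_params(
    plf = default_plf_params(),
    lambda_R = 800, gamma_R = 1,
    beta_I = 600, gamma_I = gamma_I,
    lambda_L = 1000, K_L = 100, h_L = 2,
    density = 0.185
  )
}
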