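# Replicate aggregation: geometric means per inducer combination, plus the
# standard error of the mean of log outputs (basis for fit weights).
aggregate_grid <- function(grid) {
  stopifnot(inherits(grid, "plf_grid") || is.data.frame(grid))
  key <- interaction(grid$aTc_ng_ml, grid$IPTG_uM, drop = TRUE)
  gm <- function(v) exp(tapply(log(pmax(v, .Machine$double.xmin)), key, mean))
  logsem <- tapply(log(pmax(grid$output_cfp, .Machine$double.xmin)), key,
                   function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  first <- !duplicated(key)
  out <- data.frame(
    aTc_ng_ml = grid$aTc_ng_ml[first],
    IPTG_uM = grid$IPTG_uM[first],
    luxI_cfp = as.numeric(gm(grid$luxI_cfp)[levels(key)[key[first]]]),
    luxR_yfp = as.numeric(gm(grid$luxR_yfp)[levels(key)[key[first]]]),
    output_cfp = as.numeric(gm(grid$output_cfp)[levels(key)[key[first]]]),
    log_sem = as.numeric(logsem[levels(key)[key[first]]])
  )
  out[order(out$aTc_ng_ml, out$IPTG_uM), ]
}

# Fit weights 1/sigma_i^2 on log outputs. Replicate SEMs estimated from 2-3
# replicates are themselves very noisy (few degrees of freedom), so the
# per-point variances are moderated half-way toward the pooled median
# variance; this keeps genuine heteroscedasticity without letting a lucky
# zero-scatter triplet dominate the fit. Unit weights when there is no
# replicate scatter at all (cv = 0).
fit_weights <- function(log_sem) {
  pos <- log_sem[is.finite(log_sem) & log_sem > 0]
  if (!length(pos)) return(rep(1, length(log_sem)))
  med2 <- stats::median(pos)^2
  sem2 <- ifelse(is.finite(log_sem), log_sem^2, med2)
  1 / pmax(0.5 * sem2 + 0.5 * med2, 1e-16)
}

# Model log-output for the transformed parameter vector
# theta = (logit eps, log c_tilde, log K_R, log n, log scale); m fixed.
plf_fit_model <- function(theta, luxI, luxR, m_fixed) {
  eps <- stats::plogis(theta[1])
  c_tilde <- exp(theta[2])
  K_R <- exp(theta[3])
  n <- exp(theta[4])
  scale <- exp(theta[5])
  am <- (c_tilde * luxI)^m_fixed
  afrac <- ifelse(is.infinite(am), 1, am / (1 + am))
  rn <- (luxR * afrac / K_R)^n
  f <- ifelse(is.infinite(rn), 1, (eps + rn) / (1 + rn))
  log(scale) + log(f)
}

#' Fit PLF parameters to a measured grid by nonlinear least squares
#'
#' Minimizes weighted squared residuals between log-transformed,
#' replicate-averaged (geometric mean) output levels and the parameterized
#' PLF, by Levenberg-Marquardt ([minpack.lm::nls.lm()]). Residuals live in
#' log space because the measurement noise is multiplicative. The AHL-LuxR
#' Hill coefficient `m` is held fixed (an unconstrained `m` grows without
#' bound on this model class); the free parameters are the basal fraction
#' `eps`, the scaled AHL constant `c_tilde = c * rho / K_A` (per
#' LuxI-fluorescence unit; `K_A` and `c` are not separately identifiable
#' from a single-density grid), the LuxR-DNA half-saturation `K_R`, the
#' Hill coefficient `n`, and the output scale (maximal output fluorescence).
#'
#' Five log-spaced initializations around a data-driven starting point are
#' tried; the fit with the lowest chi-square is kept (ties broken by first
#' index).
#'
#' @param grid A `plf_grid`.
#' @param m_fixed Fixed AHL-LuxR Hill coefficient (>= 1; default 2).
#' @param init Optional named numeric vector of starting values with any of
#'   `basal_fraction`, `c_tilde`, `luxr_dna_halfsat`, `hill_n`,
#'   `output_scale`.
#' @param weights Optional per-combination weights on log outputs (in the
#'   row order of the aggregated grid, sorted by aTc then IPTG); default:
#'   inverse squared replicate SEMs of log output, floored.
#' @return An object of class `plf_fit`: fitted parameters, standard
#'   errors, `chi_square`, degrees of freedom, convergence info, and the
#'   aggregated data with fitted values.
#' @export
fit_plf <- function(grid, m_fixed = 2, init = NULL, weights = NULL) {
  if (!is.finite(m_fixed) || m_fixed < 1)
    stop("m_fixed must be >= 1", call. = FALSE)
  agg <- aggregate_grid(grid)
  if (length(unique(agg$aTc_ng_ml)) < 2 || length(unique(agg$IPTG_uM)) < 2)
    stop("grid needs >= 2 distinct levels per input axis", call. = FALSE)
  y <- log(pmax(agg$output_cfp, .Machine$double.xmin))
  if (stats::sd(y) == 0)
    stop("flat grid: output shows no variation", call. = FALSE)
  w <- if (is.null(weights)) fit_weights(agg$log_sem) else weights
  if (length(w) != nrow(agg)) stop("weights length mismatch", call. = FALSE)
  sw <- sqrt(w)

  resid_fn <- function(theta)
    sw * (y - plf_fit_model(theta, agg$luxI_cfp, agg$luxR_yfp, m_fixed))

  start <- c(
    basal_fraction = max(min(agg$output_cfp) / max(agg$output_cfp), 1e-4),
    c_tilde = 1 / stats::median(agg$luxI_cfp[agg$luxI_cfp > 0]),
    luxr_dna_halfsat = stats::median(agg$luxR_yfp),
    hill_n = 1.5,
    output_scale = max(agg$output_cfp)
  )
  if (!is.null(init)) start[names(init)] <- init
  theta0 <- c(stats::qlogis(min(max(start[1], 1e-8), 1 - 1e-8)),
              log(start[2]), log(start[3]), log(start[4]), log(start[5]))

  best <- NULL
  best_chi2 <- Inf
  multipliers <- 10^seq(-1, 1, length.out = 5)
  for (k in seq_along(multipliers)) {
    th <- theta0
    th[2] <- theta0[2] + log(multipliers[k])
    th[3] <- theta0[3] + log(multipliers[k])
    res <- tryCatch(
      minpack.lm::nls.lm(par = th, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    chi2 <- sum(res$fvec^2)
    if (is.finite(chi2) && chi2 < best_chi2 - 1e-12) {
      best <- res
      best_chi2 <- chi2
    }
  }
  if (is.null(best))
    stop("PLF fit failed to converge from all initializations", call. = FALSE)

  theta <- best$par
  # Delta-method standard errors on the natural scale
  se_theta <- tryCatch({
    dof <- length(y) - length(theta)
    covm <- solve(best$hessian) * max(best_chi2 / dof, .Machine$double.eps)
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, length(theta)))
  eps <- stats::plogis(theta[1])
  nat <- c(eps, exp(theta[2:5]))
  jac <- c(eps * (1 - eps), nat[2:5])
  se <- se_theta * jac
  names(nat) <- names(se) <- c("basal_fraction", "c_tilde",
                               "luxr_dna_halfsat", "hill_n", "output_scale")

  agg$fitted_log <- plf_fit_model(theta, agg$luxI_cfp, agg$luxR_yfp, m_fixed)
  structure(list(
    params = as.list(nat),
    se = se,
    hill_m = m_fixed,
    fixed_m = TRUE,
    chi_square = best_chi2,
    dof = length(y) - length(theta),
    converged = best$info %in% 1:4,
    info = best$info,
    message = best$message,
    weights = w,
    data = agg
  ), class = "plf_fit")
}

#' @export
print.plf_fit <- function(x, ...) {
  cat("PLF nonlinear least-squares fit (m fixed at", x$hill_m, ")\n")
  for (nm in names(x$params))
    cat(sprintf("  %-18s %.5g  (se %.3g)\n", nm, x$params[[nm]], x$se[[nm]]))
  cat(sprintf("  chi-square %.4g on %d dof;  converged: %s\n",
              x$chi_square, x$dof, x$converged))
  invisible(x)
}

#' Turn a PLF fit into an evaluable parameter set
#'
#' The fitted scaled constant `c_tilde = c * rho / K_A` is unpacked with
#' `K_A = 1` and `c = c_tilde / density`, so that evaluating at `density`
#' reproduces the fitted surface, and rescaling density (or `c`, for
#' cross-protocol prediction) stretches the LuxI axis as the model
#' requires.
#'
#' @param fit A `plf_fit`.
#' @param density Cell density to attribute to the fit (OD600; default 0.1,
#'   the nominal sender-receiver measurement density).
#' @return A [plf_params] object.
#' @export
plf_params_from_fit <- function(fit, density = 0.1) {
  stopifnot(inherits(fit, "plf_fit"))
  plf_params(
    basal_fraction = fit$params$basal_fraction,
    ahl_luxr_halfsat = 1,
    luxr_dna_halfsat = fit$params$luxr_dna_halfsat,
    hill_m = fit$hill_m,
    hill_n = fit$params$hill_n,
    ahl_density_const = fit$params$c_tilde / density,
    density = density
  )
}

#' Rescale the AHL-to-density constant of a parameter set
#'
#' The constant `c` is protocol-specific (sender-receiver broth vs an
#' autonomously accumulating culture); cross-protocol prediction keeps all
#' other PLF parameters fixed and rescales `c` alone.
#'
#' @param p A [plf_params].
#' @param factor Multiplicative factor (> 0).
#' @return A [plf_params] with `ahl_density_const` multiplied by `factor`.
#' @export
rescale_c <- function(p, factor) {
  validate_plf_params(p)
  if (!is.finite(factor) || factor <= 0) stop("factor must be > 0", call. = FALSE)
  p$ahl_density_const <- p$ahl_density_const * factor
  p
}

#' Sweep the fixed AHL-LuxR Hill coefficient
#'
#' Refits the PLF at each value of `m` under a shared initialization
#' policy and tabulates the chi-square and fitted parameters. On grids
#' generated with high AHL-LuxR cooperativity the chi-square decreases
#' monotonically with `m` (which is why `m` is never fitted freely), while
#' the fitted LuxR-DNA coefficient `n` depends only weakly on `m`.
#'
#' @param grid A `plf_grid`.
#' @param m_values Numeric vector of fixed `m` values (>= 2 values).
#' @return A data frame with one row per `m`: chi-square, fitted
#'   parameters, convergence flag; failed fits appear as flagged rows of
#'   `NA`s, not errors.
#' @export
sweep_m <- function(grid, m_values = c(1, 1.5, 2, 3, 4)) {
  if (length(m_values) < 2) stop("need >= 2 m values", call. = FALSE)
  rows <- lapply(m_values, function(m) {
    fit <- tryCatch(fit_plf(grid, m_fixed = m), error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(m = m, chi_square = NA_real_, basal_fraction = NA_real_,
                        c_tilde = NA_real_, luxr_dna_halfsat = NA_real_,
                        hill_n = NA_real_, output_scale = NA_real_,
                        converged = FALSE))
    data.frame(m = m, chi_square = fit$chi_square,
               basal_fraction = fit$params$basal_fraction,
               c_tilde = fit$params$c_tilde,
               luxr_dna_halfsat = fit$params$luxr_dna_halfsat,
               hill_n = fit$params$hill_n,
               output_scale = fit$params$output_scale,
               converged = fit$converged)
  })
  do.call(rbind, rows)
}

#' Monte-Carlo goodness of fit
#'
#' Generates `trials` synthetic replicate datasets from the fitted model
#' with the noise level estimated from the data (pooled replicate scatter
#' of log outputs), refits each with the same fixed `m`, and returns the
#' fraction Q of synthetic chi-squares exceeding the observed one. Q near
#' uniform (median about 0.5) indicates deviations within measurement
#' error; Q near 0 indicates misfit. Synthetic refit failures are counted
#' and reported, never silently dropped.
#'
#' @param grid The observed `plf_grid`.
#' @param fit The `plf_fit` to assess.
#' @param trials Number of Monte-Carlo datasets (>= 100).
#' @param seed Integer RNG seed.
#' @return A list with `Q`, `chi_square_observed`, `chi_squares` (vector),
#'   `n_failed`, `trials`, `cv_estimated`.
#' @export
goodness_of_fit_mc <- function(grid, fit, trials = 1000, seed = 1L) {
  stopifnot(inherits(fit, "plf_fit"))
  if (trials < 100) stop("trials must be >= 100", call. = FALSE)
  agg <- fit$data
  reps <- table(interaction(grid$aTc_ng_ml, grid$IPTG_uM, drop = TRUE))
  n_rep <- as.integer(round(stats::median(reps)))
  # Pooled per-replicate log-sd (SEM * sqrt(n)); fall back to residual sd
  sems <- agg$log_sem[is.finite(agg$log_sem) & agg$log_sem > 0]
  sd_log <- if (length(sems)) stats::median(sems) * sqrt(n_rep)
            else stats::sd(log(agg$output_cfp) - agg$fitted_log)
  sd_log <- max(sd_log, 1e-6)
  cv_est <- sqrt(expm1(sd_log^2))

  model_out <- exp(agg$fitted_log)
  init <- unlist(fit$params)
  chi2s <- rep(NA_real_, trials)
  n_failed <- 0L
  with_seed(seed, {
    for (t in seq_len(trials)) {
      syn_rows <- agg[rep(seq_len(nrow(agg)), each = n_rep),
                      c("aTc_ng_ml", "IPTG_uM", "luxI_cfp", "luxR_yfp")]
      syn_rows$replicate <- rep(seq_len(n_rep), nrow(agg))
      syn_rows$output_cfp <- rep(model_out, each = n_rep) *
        exp(stats::rnorm(nrow(syn_rows), -sd_log^2 / 2, sd_log))
      syn <- structure(syn_rows, class = c("plf_grid", "data.frame"))
      f <- tryCatch(fit_plf(syn, m_fixed = fit$hill_m, init = init),
                    error = function(e) NULL)
      if (is.null(f)) n_failed <- n_failed + 1L else chi2s[t] <- f$chi_square
    }
  })
  ok <- is.finite(chi2s)
  list(Q = mean(chi2s[ok] > fit$chi_square),
       chi_square_observed = fit$chi_square,
       chi_squares = chi2s,
       n_failed = n_failed,
       trials = trials,
       cv_estimated = cv_est)
}
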