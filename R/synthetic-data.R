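#' Multiplicative log-normal measurement noise model
#'
#' Fluorescence measurements are treated as the true level multiplied by an
#' independent log-normal factor with unit mean and coefficient of
#' variation `cv`; single-cell fluorescence in this system is approximately
#' log-normally distributed and replicate averages inherit that structure.
#' `cv = 0` reproduces model output exactly.
#'
#' @param cv Coefficient of variation of the multiplicative factor (>= 0).
#' @param seed Integer RNG seed; every generated table records it.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.15, seed = 1L) {
  if (!is.finite(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  structure(list(cv = as.numeric(cv), seed = as.integer(seed)),
            class = "noise_model")
}

# Unit-mean log-normal factors; exactly 1 when cv = 0 (no RNG draw).
lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# Run expr with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic promoter-logic-function grid
#'
#' Emulates the feedforward sender-receiver measurement design: every
#' combination of the aTc and IPTG levels is measured in `replicates`
#' replicates. For each combination, the LuxI::CFP and LuxR::YFP inputs are
#' the Hill induction responses to the inducers, the output CFP is
#' `output_scale * plf_eval(luxI, luxR, p)`, and each of the three readouts
#' is multiplied by an independent log-normal factor (then offset by its
#' channel background, if any).
#'
#' @param p A [plf_params] object (the generating PLF).
#' @param q_luxI,q_luxR [hill_params] for aTc -> LuxI::CFP and
#'   IPTG -> LuxR::YFP.
#' @param aTc_levels,IPTG_levels Ascending inducer levels (defaults: the
#'   6 x 7 = 42-combination design).
#' @param noise A [noise_model].
#' @param replicates Replicates per combination (>= 1; default 3 so that
#'   replicate standard deviations are estimable).
#' @param output_scale Maximal output CFP level (fluorescence per unit
#'   transcription; the reporter's lambda_Z).
#' @param backgrounds Named numeric vector of additive channel backgrounds
#'   `c(luxI_cfp=, luxR_yfp=, output_cfp=)`, added after the noise factor.
#' @return A `plf_grid`: a data frame with columns `aTc_ng_ml`, `IPTG_uM`,
#'   `replicate`, `luxI_cfp`, `luxR_yfp`, `output_cfp` and attributes
#'   recording the design levels, seed, cv and output scale.
#' @export
generate_plf_grid <- function(p,
                              q_luxI = default_induction_params()$aTc,
                              q_luxR = default_induction_params()$IPTG,
                              aTc_levels = default_inducer_levels()$aTc_ng_ml,
                              IPTG_levels = default_inducer_levels()$IPTG_uM,
                              noise = noise_model(cv = 0.15, seed = 1L),
                              replicates = 3L,
                              output_scale = 1000,
                              backgrounds = c(luxI_cfp = 0, luxR_yfp = 0,
                                              output_cfp = 0)) {
  validate_plf_params(p)
  if (length(aTc_levels) == 0 || length(IPTG_levels) == 0)
    stop("inducer level lists must be non-empty", call. = FALSE)
  if (is.unsorted(aTc_levels, strictly = TRUE) ||
      is.unsorted(IPTG_levels, strictly = TRUE))
    stop("inducer levels must be strictly ascending", call. = FALSE)
  replicates <- as.integer(replicates)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  stopifnot(inherits(noise, "noise_model"))
  bg <- c(luxI_cfp = 0, luxR_yfp = 0, output_cfp = 0)
  bg[names(backgrounds)] <- backgrounds

  design <- expand.grid(replicate = seq_len(replicates),
                        aTc_ng_ml = aTc_levels,
                        IPTG_uM = IPTG_levels,
                        KEEP.OUT.ATTRS = FALSE)
  design <- design[, c("aTc_ng_ml", "IPTG_uM", "replicate")]
  nr <- nrow(design)

  luxI_true <- hill_induction(design$aTc_ng_ml, q_luxI)
  luxR_true <- hill_induction(design$IPTG_uM, q_luxR)
  out_true <- output_scale * plf_eval(luxI_true, luxR_true, p)

  fac <- with_seed(noise$seed, matrix(lognormal_factors(3 * nr, noise$cv), nr, 3))
  grid <- data.frame(
    design,
    luxI_cfp = bg[["luxI_cfp"]] + luxI_true * fac[, 1],
    luxR_yfp = bg[["luxR_yfp"]] + luxR_true * fac[, 2],
    output_cfp = bg[["output_cfp"]] + out_true * fac[, 3]
  )
  structure(grid,
            aTc_levels = aTc_levels, IPTG_levels = IPTG_levels,
            seed = noise$seed, cv = noise$cv,
            output_scale = output_scale, backgrounds = bg,
            class = c("plf_grid", "data.frame"))
}

#' Generate a synthetic line-of-equivalence calibration table
#'
#' Emulates the calibration experiment in which the input-channel protein
#' and the output reporter are expressed from the same inducible promoter
#' at a series of inducer levels, and their fluorescence readouts are
#' paired. Noise-free readings satisfy
#' `y = b_y + true_scale * (x - b_x)`, with `x` the input-channel level
#' (background `b_x` included) spanning the induction range.
#'
#' @param true_scale Input-to-output scale factor (> 0).
#' @param backgrounds Length-2 numeric `c(b_x, b_y)` channel backgrounds.
#' @param IPTG_levels Inducer levels for the series (>= 3).
#' @param q [hill_params] for the shared inducible promoter.
#' @param noise A [noise_model]; the log-normal factor multiplies the
#'   background-free signal in each channel.
#' @param replicates Replicates per level.
#' @return A data frame with columns `IPTG_uM`, `replicate`, `x`, `y` and
#'   attributes `true_scale`, `backgrounds`, `seed`, `cv`.
#' @export
generate_equivalence_table <- function(true_scale,
                                       backgrounds = c(30, 15),
                                       IPTG_levels = c(0, 5, 10, 50, 100, 500),
                                       q = default_induction_params()$IPTG,
                                       noise = noise_model(cv = 0.1, seed = 1L),
                                       replicates = 3L) {
  if (!is.finite(true_scale) || true_scale <= 0)
    stop("true_scale must be > 0", call. = FALSE)
  if (length(IPTG_levels) < 3)
    stop("need >= 3 inducer levels (affine fit underdetermined)", call. = FALSE)
  stopifnot(length(backgrounds) == 2, all(backgrounds >= 0))
  replicates <- as.integer(replicates)
  design <- expand.grid(replicate = seq_len(replicates),
                        IPTG_uM = IPTG_levels, KEEP.OUT.ATTRS = FALSE)
  signal <- hill_induction(design$IPTG_uM, q)
  nr <- nrow(design)
  fac <- with_seed(noise$seed, matrix(lognormal_factors(2 * nr, noise$cv), nr, 2))
  tab <- data.frame(
    IPTG_uM = design$IPTG_uM, replicate = design$replicate,
    x = backgrounds[1] + signal * fac[, 1],
    y = backgrounds[2] + true_scale * signal * fac[, 2]
  )
  structure(tab, true_scale = true_scale, backgrounds = backgrounds,
            seed = noise$seed, cv = noise$cv,
            class = c("equivalence_table", "data.frame"))
}

#' Simulate terminal feedback responses with ON/OFF histories
#'
#' Emulates the hysteresis measurement: for each regulator level, cells are
#' initialized either un-induced (OFF history, feedback variable at its
#' basal level `lambda * eps`) or fully induced (ON history, at the
#' saturated level `lambda`), grown to the terminal density, and their
#' terminal feedback-protein level recorded with measurement noise.
#' Integration runs the feedback ODE at the clamped terminal density until
#' the relative derivative is below `tol`; records that fail to converge
#' are flagged, not dropped.
#'
#' @param topo A 1-D feedback [topology_spec] (`luxR_feedback` or
#'   `luxI_feedback`); its clamped regulator field is overridden per level.
#' @param p A [plf_params]; its density is set to `density_terminal`.
#' @param regulator_levels Clamped regulator levels (fluorescence, >= 0).
#' @param density_terminal Terminal density rho_T (OD600).
#' @param histories Character subset of `c("OFF", "ON")`.
#' @param noise A [noise_model].
#' @param t_max Integration horizon in units of `1/gamma` (default 400).
#' @param tol Relative-derivative convergence tolerance.
#' @return Data frame with columns `regulator`, `history`, `replicate`,
#'   `terminal`, `converged`.
#' @export
generate_feedback_dataset <- function(topo, p, regulator_levels,
                                      density_terminal = 0.05,
                                      histories = c("OFF", "ON"),
                                      noise = noise_model(cv = 0.15, seed = 1L),
                                      replicates = 3L,
                                      t_max = 400, tol = 1e-8) {
  stopifnot(inherits(topo, "topology_spec"),
            topo$kind %in% c("luxR_feedback", "luxI_feedback"))
  if (length(regulator_levels) == 0)
    stop("regulator_levels must be non-empty", call. = FALSE)
  histories <- match.arg(histories, c("OFF", "ON"), several.ok = TRUE)
  validate_plf_params(p)
  p$density <- density_terminal
  lam <- feedback_lambda(topo)
  gam <- if (topo$kind == "luxR_feedback") topo$gamma_R else topo$gamma_I

  rows <- list()
  for (reg in regulator_levels) {
    topo_reg <- topo
    if (topo$kind == "luxR_feedback") topo_reg$luxI_fixed <- reg
    else topo_reg$luxR_fixed <- reg
    for (h in histories) {
      x0 <- if (h == "OFF") lam * p$basal_fraction else lam
      sol <- deSolve::ode(y = c(x = x0), times = c(0, t_max / gam),
                          func = ode_rhs,
                          parms = list(topo = topo_reg, p = p),
                          method = "lsoda")
      xT <- unname(sol[nrow(sol), "x"])
      dxT <- ode_rhs(0, xT, topo = topo_reg, p = p)[[1]]
      converged <- is.finite(xT) && abs(dxT) <= tol * gam * max(abs(xT), lam * p$basal_fraction)
      rows[[length(rows) + 1]] <- data.frame(
        regulator = reg, history = h,
        replicate = seq_len(replicates),
        terminal_true = xT, converged = converged
      )
    }
  }
  out <- do.call(rbind, rows)
  fac <- with_seed(noise$seed, lognormal_factors(nrow(out), noise$cv))
  out$terminal <- out$terminal_true * fac
  out$terminal_true <- NULL
  structure(out[, c("regulator", "history", "replicate", "terminal", "converged")],
            seed = noise$seed, cv = noise$cv,
            density_terminal = density_terminal,
            class = c("feedback_table", "data.frame"))
}
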