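#' AHL concentration from LuxI level and cell density
#'
#' In a growth-clamped (or exponentially growing, measurement-time) culture
#' the steady AHL concentration is proportional to cell density and the
#' LuxI level: `A = c * rho * I`.
#'
#' @param luxI LuxI::CFP level (fluorescence, >= 0); vectorized.
#' @param density Cell density rho (OD600, >= 0).
#' @param ahl_density_const Proportionality constant c (> 0).
#' @return AHL concentration(s), same length as `luxI`.
#' @export
ahl_level <- function(luxI, density, ahl_density_const) {
  if (any(!is.finite(luxI)) || any(luxI < 0))
    stop("luxI must be finite and >= 0", call. = FALSE)
  if (!is.finite(density) || density < 0)
    stop("density must be finite and >= 0", call. = FALSE)
  if (!is.finite(ahl_density_const) || ahl_density_const <= 0)
    stop("ahl_density_const must be > 0", call. = FALSE)
  ahl_density_const * density * luxI
}

#' Evaluate the promoter logic function of pR
#'
#' Transcription rate of pR (fraction of maximum) given LuxI and LuxR
#' levels at the density carried in `p`. The AHL concentration is
#' `A = c * rho * I`; the active-LuxR level is the AHL-saturable fraction
#' `R* = R * A^m / (K_A^m + A^m)`; and the output is the basal-offset Hill
#' in active LuxR,
#' `f = (eps * K_R^n + R*^n) / (K_R^n + R*^n)`.
#'
#' The result is bounded in `[eps, 1]`, monotone nondecreasing in both
#' inputs, and AND-type: basal when either input is zero.
#'
#' @param luxI,luxR Input levels (fluorescence, >= 0); vectorized (recycled
#'   to common length).
#' @param p A [plf_params] object.
#' @return Transcription rate(s) as fraction(s) of maximum.
#' @export
plf_eval <- function(luxI, luxR, p) {
  validate_plf_params(p)
  if (any(!is.finite(luxI)) || any(luxI < 0) ||
      any(!is.finite(luxR)) || any(luxR < 0))
    stop("luxI and luxR must be finite and >= 0", call. = FALSE)
  A <- ahl_level(luxI, p$density, p$ahl_density_const)
  # Hill fractions computed in a ratio form that is safe for large A, R*
  am <- (A / p$ahl_luxr_halfsat)^p$hill_m
  afrac <- ifelse(is.infinite(am), 1, am / (1 + am))
  active_luxR <- luxR * afrac
  rn <- (active_luxR / p$luxr_dna_halfsat)^p$hill_n
  ifelse(is.infinite(rn), 1, (p$basal_fraction + rn) / (1 + rn))
}

#' Hill induction curve
#'
#' Expression level driven by an inducible promoter:
#' `V0 + Vmax * x^h / (K^h + x^h)`.
#'
#' @param inducer Inducer concentration(s) (>= 0).
#' @param q A [hill_params] object.
#' @return Expression level(s) (fluorescence).
#' @export
hill_induction <- function(inducer, q) {
  stopifnot(inherits(q, "hill_params"))
  if (any(!is.finite(inducer)) || any(inducer < 0))
    stop("inducer must be finite and >= 0", call. = FALSE)
  xh <- (inducer / q$halfsat)^q$hill
  q$basal + q$span * xh / (1 + xh)
}

#' Rescale the density of a PLF parameter set
#'
#' Going from the PLF at density rho to the PLF at density `factor * rho`
#' squeezes the surface along the LuxI axis by `factor`, because AHL enters
#' only through the product `c * rho * I`. Equivalently,
#' `plf_eval(I, R, density_rescale(p, k)) == plf_eval(k * I, R, p)`.
#'
#' @param p A [plf_params] object.
#' @param factor Multiplicative density factor (> 0).
#' @return A [plf_params] object with `density` multiplied by `factor`.
#' @export
density_rescale <- function(p, factor) {
  validate_plf_params(p)
  if (!is.finite(factor) || factor <= 0)
    stop("factor must be > 0", call. = FALSE)
  p$density <- p$density * factor
  p
}

#' Right-hand side of the feedback circuit ODEs
#'
#' Time derivatives of the protein levels for a given topology, all driven
#' by the shared promoter logic function `f`:
#' \describe{
#'   \item{feedforward}{`dZ/dt = gamma_Z * (lambda_Z * f(I., R.) - Z)`}
#'   \item{luxR_feedback}{`dR/dt = gamma_R * (lambda_R * f(I., R) - R)`}
#'   \item{luxI_feedback}{`dI/dt = gamma_I * (lambda_I * f(I, R.) - I)`}
#'   \item{dual_positive}{both feedback equations with the shared `f(I, R)`}
#' }
#' where dotted symbols are the clamped regulator levels in `topo`.
#'
#' The signature matches what [deSolve::ode()] expects from a derivative
#' function when called as `ode_rhs(t, state, list(topo = ..., p = ...))`;
#' it can equally be called directly as `ode_rhs(state = x, topo =, p =)`.
#'
#' @param t Time (unused; the system is autonomous).
#' @param state Numeric state vector of length [topology_dim] for `topo`
#'   (named or not: feedforward `Z`; luxR_feedback `R`; luxI_feedback `I`;
#'   dual_positive `c(R, I)`).
#' @param parms Optional list with elements `topo` and `p` (deSolve call
#'   form); alternatively pass `topo` and `p` directly.
#' @param topo A [topology_spec].
#' @param p A [plf_params].
#' @return A list whose first element is the derivative vector (deSolve
#'   convention).
#' @export
ode_rhs <- function(t = 0, state, parms = NULL, topo = NULL, p = NULL) {
  if (!is.null(parms)) {
    topo <- parms$topo
    p <- parms$p
  }
  stopifnot(inherits(topo, "topology_spec"), inherits(p, "plf_params"))
  state <- as.numeric(state)
  if (length(state) != topology_dim(topo))
    stop(sprintf("state has length %d but topology '%s' needs %d",
                 length(state), topo$kind, topology_dim(topo)), call. = FALSE)
  # Levels may dip infinitesimally below 0 inside an integrator step
  s <- pmax(state, 0)
  d <- switch(topo$kind,
    feedforward = {
      f <- plf_eval(topo$luxI_fixed, topo$luxR_fixed, p)
      topo$gamma_Z * (topo$lambda_Z * f - s[1])
    },
    luxR_feedback = {
      f <- plf_eval(topo$luxI_fixed, s[1], p)
      topo$gamma_R * (topo$lambda_R * f - s[1])
    },
    luxI_feedback = {
      f <- plf_eval(s[1], topo$luxR_fixed, p)
      topo$gamma_I * (topo$lambda_I * f - s[1])
    },
    dual_positive = {
      f <- plf_eval(s[2], s[1], p)
      c(topo$gamma_R * (topo$lambda_R * f - s[1]),
        topo$gamma_I * (topo$lambda_I * f - s[2]))
    }
  )
  list(d)
}

# Scalar steady-state map g(x) = lambda * f(x) for the 1-D feedback loops:
# returns a vectorized function of the feedback variable.
feedback_map <- function(topo, p) {
  switch(topo$kind,
    luxR_feedback = function(x) topo$lambda_R * plf_eval(topo$luxI_fixed, x, p),
    luxI_feedback = function(x) topo$lambda_I * plf_eval(x, topo$luxR_fixed, p),
    stop("feedback_map is defined for 1-D feedback topologies only",
         call. = FALSE)
  )
}

# lambda and gamma of the single dynamical variable of a 1-D topology
feedback_lambda <- function(topo) {
  switch(topo$kind,
    feedforward = topo$lambda_Z,
    luxR_feedback = topo$lambda_R,
    luxI_feedback = topo$lambda_I,
    stop("no single lambda for topology ", topo$kind, call. = FALSE)
  )
}
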