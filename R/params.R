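#' Promoter logic function parameters
#'
#' Constructs and validates the biochemical constants of the parameterized
#' two-input promoter logic function (PLF) of the pR promoter, together with
#' the AHL-to-density proportionality constant and the cell density at which
#' the function is evaluated.
#'
#' The PLF maps LuxI and LuxR levels (arbitrary fluorescence units) to a
#' transcription rate expressed as a fraction of the maximal rate, which is
#' normalized to 1. AHL concentration is taken proportional to cell density
#' and the LuxI level, `A = c * rho * I`.
#'
#' @param basal_fraction Basal transcription rate as a fraction of maximum
#'   (dimensionless, 0 < eps < 1).
#' @param ahl_luxr_halfsat Half-saturation AHL concentration for AHL-LuxR
#'   binding, `K_A` (AHL units, > 0).
#' @param luxr_dna_halfsat Half-saturation active-LuxR level for LuxR-DNA
#'   binding, `K_R` (active-LuxR fluorescence units, > 0).
#' @param hill_m Hill coefficient of AHL-LuxR binding (>= 1).
#' @param hill_n Hill coefficient of LuxR-DNA binding (> 0).
#' @param ahl_density_const AHL produced per unit cell density per unit LuxI
#'   fluorescence, `c` (> 0). Protocol-specific; never hard-coded.
#' @param density Cell density `rho` (OD600, >= 0).
#'
#' @return An object of class `plf_params`.
#' @seealso [plf_eval()], [default_plf_params()]
#' @export
plf_params <- function(basal_fraction,
                       ahl_luxr_halfsat,
                       luxr_dna_halfsat,
                       hill_m,
                       hill_n,
                       ahl_density_const,
                       density) {
  p <- list(
    basal_fraction = as.numeric(basal_fraction),
    ahl_luxr_halfsat = as.numeric(ahl_luxr_halfsat),
    luxr_dna_halfsat = as.numeric(luxr_dna_halfsat),
    hill_m = as.numeric(hill_m),
    hill_n = as.numeric(hill_n),
    ahl_density_const = as.numeric(ahl_density_const),
    density = as.numeric(density)
  )
  class(p) <- "plf_params"
  validate_plf_params(p)
  p
}

validate_plf_params <- function(p) {
  stopifnot(inherits(p, "plf_params"))
  with(p, {
    if (!is.finite(basal_fraction) || basal_fraction <= 0 || basal_fraction >= 1)
      stop("basal_fraction must lie strictly between 0 and 1", call. = FALSE)
    if (!is.finite(ahl_luxr_halfsat) || ahl_luxr_halfsat <= 0)
      stop("ahl_luxr_halfsat must be > 0", call. = FALSE)
    if (!is.finite(luxr_dna_halfsat) || luxr_dna_halfsat <= 0)
      stop("luxr_dna_halfsat must be > 0", call. = FALSE)
    if (!is.finite(hill_m) || hill_m < 1)
      stop("hill_m must be >= 1", call. = FALSE)
    if (!is.finite(hill_n) || hill_n <= 0)
      stop("hill_n must be > 0", call. = FALSE)
    if (!is.finite(ahl_density_const) || ahl_density_const <= 0)
      stop("ahl_density_const must be > 0", call. = FALSE)
    if (!is.finite(density) || density < 0)
      stop("density must be >= 0", call. = FALSE)
  })
  invisible(p)
}

#' @export
print.plf_params <- function(x, ...) {
  cat("Promoter logic function parameters\n")
  cat(sprintf("  basal fraction (eps): %.4g\n", x$basal_fraction))
  cat(sprintf("  AHL-LuxR halfsat K_A: %.4g   Hill m: %.3g\n",
              x$ahl_luxr_halfsat, x$hill_m))
  cat(sprintf("  LuxR-DNA halfsat K_R: %.4g   Hill n: %.3g\n",
              x$luxr_dna_halfsat, x$hill_n))
  cat(sprintf("  AHL density const c:  %.4g   density rho: %.4g OD600\n",
              x$ahl_density_const, x$density))
  invisible(x)
}

#' Hill induction curve parameters
#'
#' Parameters of the inducer-to-expression Hill response of an inducible
#' promoter (aTc -> LuxI::CFP via pTet, or IPTG -> LuxR::YFP via pLac).
#' Expression at inducer level x is `V0 + Vmax * x^h / (K^h + x^h)`.
#'
#' @param basal Expression with no inducer, `V0` (fluorescence, >= 0).
#' @param span Inducible span above basal, `Vmax` (fluorescence, > 0).
#' @param halfsat Inducer concentration giving half the span, `K` (> 0).
#' @param hill Hill coefficient `h` (> 0).
#'
#' @return An object of class `hill_params`.
#' @seealso [hill_induction()]
#' @export
hill_params <- function(basal, span, halfsat, hill) {
  q <- list(
    basal = as.numeric(basal),
    span = as.numeric(span),
    halfsat = as.numeric(halfsat),
    hill = as.numeric(hill)
  )
  class(q) <- "hill_params"
  if (!is.finite(q$basal) || q$basal < 0) stop("basal must be >= 0", call. = FALSE)
  if (!is.finite(q$span) || q$span <= 0) stop("span must be > 0", call. = FALSE)
  if (!is.finite(q$halfsat) || q$halfsat <= 0) stop("halfsat must be > 0", call. = FALSE)
  if (!is.finite(q$hill) || q$hill <= 0) stop("hill must be > 0", call. = FALSE)
  q
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill induction curve: V0=%.4g Vmax=%.4g K=%.4g h=%.3g\n",
              x$basal, x$span, x$halfsat, x$hill))
  invisible(x)
}

#' Feedback topology specification
#'
#' Describes which circuit is wired around the pR promoter and the scaled
#' kinetic constants of its dynamical variables. Production rates `lambda`
#' are protein levels (fluorescence units) produced per unit transcription
#' rate, already scaled by decay so that steady states live in fluorescence
#' units; `gamma` are first-order response rates (1/time).
#'
#' Topologies:
#' \describe{
#'   \item{feedforward}{Passive reporter Z from pR; LuxI and LuxR clamped at
#'     `luxI_fixed`, `luxR_fixed`.}
#'   \item{luxR_feedback}{LuxR expressed from pR; LuxI clamped at
#'     `luxI_fixed` (the regulator).}
#'   \item{luxI_feedback}{LuxI expressed from pR; LuxR clamped at
#'     `luxR_fixed` (the regulator).}
#'   \item{dual_positive}{Both LuxI and LuxR expressed from pR.}
#' }
#'
#' @param kind One of `"feedforward"`, `"luxR_feedback"`, `"luxI_feedback"`,
#'   `"dual_positive"`.
#' @param lambda_R,lambda_I,lambda_Z Scaled production rates (fluorescence
#'   per unit transcription) for the variables the topology requires.
#' @param gamma_R,gamma_I,gamma_Z Response rates (1/time).
#' @param luxI_fixed,luxR_fixed Clamped regulator levels (fluorescence),
#'   required only where the topology holds that protein fixed.
#'
#' @return An object of class `topology_spec`.
#' @export
topology_spec <- function(kind = c("feedforward", "luxR_feedback",
                                   "luxI_feedback", "dual_positive"),
                          lambda_R = NULL, lambda_I = NULL, lambda_Z = NULL,
                          gamma_R = 1, gamma_I = 1, gamma_Z = 1,
                          luxI_fixed = NULL, luxR_fixed = NULL) {
  kind <- match.arg(kind)
  need <- function(x, nm) {
    if (is.null(x) || !is.finite(x) || x <= 0)
      stop(sprintf("topology '%s' requires positive %s", kind, nm), call. = FALSE)
    as.numeric(x)
  }
  need0 <- function(x, nm) {
    if (is.null(x) || !is.finite(x) || x < 0)
      stop(sprintf("topology '%s' requires nonnegative %s", kind, nm), call. = FALSE)
    as.numeric(x)
  }
  topo <- switch(kind,
    feedforward = list(
      kind = kind, lambda_Z = need(lambda_Z, "lambda_Z"),
      gamma_Z = need(gamma_Z, "gamma_Z"),
      luxI_fixed = need0(luxI_fixed, "luxI_fixed"),
      luxR_fixed = need0(luxR_fixed, "luxR_fixed")
    ),
    luxR_feedback = list(
      kind = kind, lambda_R = need(lambda_R, "lambda_R"),
      gamma_R = need(gamma_R, "gamma_R"),
      luxI_fixed = need0(luxI_fixed, "luxI_fixed")
    ),
    luxI_feedback = list(
      kind = kind, lambda_I = need(lambda_I, "lambda_I"),
      gamma_I = need(gamma_I, "gamma_I"),
      luxR_fixed = need0(luxR_fixed, "luxR_fixed")
    ),
    dual_positive = list(
      kind = kind, lambda_R = need(lambda_R, "lambda_R"),
      lambda_I = need(lambda_I, "lambda_I"),
      gamma_R = need(gamma_R, "gamma_R"), gamma_I = need(gamma_I, "gamma_I")
    )
  )
  class(topo) <- "topology_spec"
  topo
}

#' @export
print.topology_spec <- function(x, ...) {
  cat("Feedback topology:", x$kind, "\n")
  for (nm in setdiff(names(x), "kind"))
    cat(sprintf("  %s = %.5g\n", nm, x[[nm]]))
  invisible(x)
}

# Number of dynamical state variables for a topology
topology_dim <- function(topo) {
  switch(topo$kind,
    feedforward = 1L, luxR_feedback = 1L, luxI_feedback = 1L,
    dual_positive = 2L
  )
}

#' Canonical default PLF parameter set
#'
#' The package's documented reference parameter set for the pR promoter
#' logic function, in arbitrary fluorescence units at the sender-receiver
#' nominal density of 0.1 OD600. Hill coefficients follow the fitted values
#' reported for the experimental system (m = 2 for AHL-LuxR binding, held
#' fixed during fitting; n = 1.45 for LuxR-DNA binding); the remaining
#' constants are the package's own calibration chosen so the surface is
#' AND-type and spans over two decades across the default inducer grid.
#'
#' @param density Cell density at which the PLF is evaluated (OD600).
#' @return A [plf_params] object.
#' @export
default_plf_params <- function(density = 0.1) {
  plf_params(
    basal_fraction = 0.008,
    ahl_luxr_halfsat = 1,
    luxr_dna_halfsat = 300,
    hill_m = 2,
    hill_n = 1.45,
    ahl_density_const = 0.04,
    density = density
  )
}

#' Default inducer response curves
#'
#' Reference Hill induction parameters for the two inducible promoters:
#' aTc -> LuxI::CFP (pTet) and IPTG -> LuxR::YFP (pLac), in arbitrary
#' fluorescence units. Half-saturation constants sit inside the default
#' inducer ranges (aTc 0-50 ng/ml, IPTG 0-1000 uM) so both inputs are swept
#' from near-basal to near-saturation.
#'
#' @return A list with elements `aTc` and `IPTG`, each a [hill_params].
#' @export
default_induction_params <- function() {
  list(
    aTc = hill_params(basal = 8, span = 800, halfsat = 10, hill = 2),
    IPTG = hill_params(basal = 12, span = 1800, halfsat = 80, hill = 1.6)
  )
}

#' Default feedback circuit topologies
#'
#' Reference topology specifications for the three studied circuits, in
#' the same fluorescence units as [default_plf_params()]:
#' \describe{
#'   \item{feedforward}{reporter Z from pR (`lambda_Z = 1000`).}
#'   \item{luxR_feedback}{LuxR from pR, `lambda_R = 500`; with the default
#'     PLF this loop is monostable at every density and regulator level
#'     (its `lambda_R / K_R` sits below the bistable window of the
#'     n = 1.45 LuxR-DNA Hill).}
#'   \item{luxI_feedback}{LuxI from pR, `lambda_I = 3000`; with the
#'     default PLF this loop runs through un-induced (B-), hysteretic
#'     (B+-) and induced (B+) classes as the LuxR regulator rises.}
#' }
#' Regulator fields default to mid-range levels and are usually
#' overridden.
#'
#' @return A named list of [topology_spec] objects.
#' @export
default_topologies <- function() {
  q <- default_induction_params()
  mid_I <- hill_induction(10, q$aTc)
  mid_R <- hill_induction(100, q$IPTG)
  list(
    feedforward = topology_spec("feedforward", lambda_Z = 1000,
                                luxI_fixed = mid_I, luxR_fixed = mid_R),
    luxR_feedback = topology_spec("luxR_feedback", lambda_R = 500,
                                  luxI_fixed = mid_I),
    luxI_feedback = topology_spec("luxI_feedback", lambda_I = 3000,
                                  luxR_fixed = mid_R)
  )
}

#' Default inducer level grids
#'
#' The 6-level aTc and 7-level IPTG design used throughout: all 42
#' combinations of aTc in \{0, 1, 5, 10, 20, 50\} ng/ml and IPTG in
#' \{0, 5, 10, 50, 100, 500, 1000\} uM.
#'
#' @return A list with numeric vectors `aTc_ng_ml` and `IPTG_uM`.
#' @export
default_inducer_levels <- function() {
  list(
    aTc_ng_ml = c(0, 1, 5, 10, 20, 50),
    IPTG_uM = c(0, 5, 10, 50, 100, 500, 1000)
  )
}
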