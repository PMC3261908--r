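#' Construct an input-output characteristic
#'
#' An IOC is a one-dimensional slice of the PLF at a fixed regulator level:
#' ordered (input, output) pairs in background-subtracted fluorescence
#' units, inputs strictly increasing and all values positive.
#'
#' @param input,output Positive numeric vectors of equal length (inputs
#'   strictly increasing).
#' @param regulator Regulator level the slice was taken at (fluorescence).
#' @param axis Which protein the input axis is (`"luxR"` or `"luxI"`).
#' @return An object of class `ioc`.
#' @export
ioc <- function(input, output, regulator = NA_real_,
                axis = c("luxR", "luxI")) {
  axis <- match.arg(axis)
  if (length(input) != length(output) || length(input) < 1)
    stop("input and output must be non-empty and of equal length", call. = FALSE)
  if (any(!is.finite(input)) || any(input <= 0) ||
      any(!is.finite(output)) || any(output <= 0))
    stop("IOC values must be finite and > 0 (background-subtract and floor first)",
         call. = FALSE)
  if (is.unsorted(input, strictly = TRUE))
    stop("IOC inputs must be strictly increasing", call. = FALSE)
  structure(list(input = as.numeric(input), output = as.numeric(output),
                 regulator = regulator, axis = axis),
            class = "ioc")
}

#' @export
print.ioc <- function(x, ...) {
  cat(sprintf("Input-output characteristic (%s axis, regulator = %.4g): %d nodes\n",
              x$axis, x$regulator, length(x$input)))
  invisible(x)
}

#' Extract an input-output characteristic from a PLF grid
#'
#' Takes the replicate-averaged (geometric mean), background-subtracted
#' slice of the grid at one fixed regulator index. LuxR-feedback
#' predictions use vertical cuts (`axis = "luxR"`: aTc and hence LuxI
#' fixed, LuxR::YFP is the input); LuxI-feedback predictions use
#' horizontal cuts (`axis = "luxI"`: IPTG and hence LuxR fixed, LuxI::CFP
#' is the input). The output is always the pR reporter CFP.
#'
#' @param grid A `plf_grid`.
#' @param axis `"luxR"` or `"luxI"`: the input (would-be feedback) axis.
#' @param regulator_index 1-based index into the fixed axis's levels
#'   (aTc levels for `"luxR"`, IPTG levels for `"luxI"`).
#' @param backgrounds Numeric `c(input, output)` channel backgrounds to
#'   subtract (default none).
#' @param floor Positive clamp applied after background subtraction
#'   (default `1e-6` of the channel maximum).
#' @param input_scale Multiplicative stretch applied to the input axis
#'   (default 1). For `axis = "luxI"` this is the density-rescaling
#'   squeeze: a grid measured at density rho yields the IOC at density
#'   `rho / input_scale`, because AHL enters only through the product of
#'   density and LuxI. It has no such interpretation for `axis = "luxR"`.
#' @return An `ioc`; per-node log-scale replicate SEMs are attached as
#'   attribute `log_sem` (for Monte-Carlo noise).
#' @export
ioc_from_grid <- function(grid, axis = c("luxR", "luxI"), regulator_index,
                          backgrounds = c(0, 0), floor = NULL,
                          input_scale = 1) {
  axis <- match.arg(axis)
  if (!is.finite(input_scale) || input_scale <= 0)
    stop("input_scale must be > 0", call. = FALSE)
  agg <- aggregate_grid(grid)
  if (axis == "luxR") {
    levels_fixed <- sort(unique(agg$aTc_ng_ml))
    if (regulator_index < 1 || regulator_index > length(levels_fixed))
      stop("regulator_index out of range", call. = FALSE)
    sl <- agg[agg$aTc_ng_ml == levels_fixed[regulator_index], ]
    sl <- sl[order(sl$luxR_yfp), ]
    input_raw <- sl$luxR_yfp
    regulator <- stats::median(sl$luxI_cfp)
  } else {
    levels_fixed <- sort(unique(agg$IPTG_uM))
    if (regulator_index < 1 || regulator_index > length(levels_fixed))
      stop("regulator_index out of range", call. = FALSE)
    sl <- agg[agg$IPTG_uM == levels_fixed[regulator_index], ]
    sl <- sl[order(sl$luxI_cfp), ]
    input_raw <- sl$luxI_cfp
    regulator <- stats::median(sl$luxR_yfp)
  }
  if (nrow(sl) < 2) stop("IOC slice has fewer than 2 points", call. = FALSE)
  fl_in <- if (is.null(floor)) 1e-6 * max(input_raw) else floor
  fl_out <- if (is.null(floor)) 1e-6 * max(sl$output_cfp) else floor
  x <- input_scale * subtract_background(input_raw, backgrounds[1], fl_in)
  y <- subtract_background(sl$output_cfp, backgrounds[2], fl_out)
  # collapse ties in input (can arise from the floor clamp)
  o <- order(x)
  x <- x[o]; y <- y[o]; sem <- sl$log_sem[o]
  keep <- !duplicated(x)
  obj <- ioc(x[keep], y[keep], regulator = regulator, axis = axis)
  attr(obj, "log_sem") <- sem[keep]
  obj
}

#' Power-law interpolation of an IOC
#'
#' Piecewise-linear interpolation in log-log space between IOC nodes
#' (equivalent to local power laws), with conservative flat extrapolation
#' (first/last node value) outside the measured input range.
#'
#' @param obj An `ioc`.
#' @param x Positive query input level(s).
#' @return Interpolated output level(s).
#' @export
loglog_interp <- function(obj, x) {
  stopifnot(inherits(obj, "ioc"))
  if (any(!is.finite(x)) || any(x <= 0)) stop("x must be > 0", call. = FALSE)
  if (length(obj$input) == 1) return(rep(obj$output, length(x)))
  exp(stats::approx(log(obj$input), log(obj$output), xout = log(x),
                    rule = 2, ties = "ordered")$y)
}

#' Enumerate intersections of an IOC with a line of equivalence
#'
#' Finds every crossing of the log-log-interpolated IOC (including its
#' flat extrapolation tails) with the background-subtracted line of
#' equivalence `y = s * x`. In log-log coordinates the line is
#' `v = u + log s` and every IOC segment is linear, so each crossing is
#' solved analytically; no iterative root-finding is involved.
#'
#' Stability follows the one-dimensional alternation convention: where the
#' IOC crosses the line from above to below (log-log segment slope < 1)
#' the point is stable; slope > 1, unstable; segments parallel to the line
#' (tangency) count once with stability `"unknown"`. Crossings closer than
#' `1e-9` log units are merged.
#'
#' @param obj An `ioc` (background-subtracted).
#' @param line An `equivalence_line` (only `scale` is used; coordinates
#'   are assumed already background-subtracted).
#' @return An object of class `fixed_points`: a data frame with columns
#'   `level` (input units, ascending), `output`, `stability`
#'   (`"stable"`, `"unstable"`, `"unknown"`). May have zero rows.
#' @export
find_intersections <- function(obj, line) {
  stopifnot(inherits(obj, "ioc"), inherits(line, "equivalence_line"))
  u <- log(obj$input)
  v <- log(obj$output)
  ls <- log(line$scale)
  n <- length(u)
  hits_u <- numeric(0)
  hits_stab <- character(0)
  add <- function(uu, stab) {
    hits_u <<- c(hits_u, uu)
    hits_stab <<- c(hits_stab, stab)
  }
  if (n == 1) {
    # wholly flat IOC: exactly one stable crossing with the line
    add(v[1] - ls, "stable")
  }
  # left flat tail: v = v[1] for u < u[1] (node itself belongs to segment 1)
  if (n > 1) {
    u_star <- v[1] - ls
    if (u_star < u[1]) add(u_star, "stable")
  }
  # internal segments
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      du <- u[i + 1] - u[i]
      a <- (v[i + 1] - v[i]) / du
      if (abs(a - 1) < 1e-12) {
        # parallel to the line: tangency iff it lies on the line
        if (abs(v[i] - u[i] - ls) < 1e-9)
          add((u[i] + u[i + 1]) / 2, "unknown")
        next
      }
      us <- (v[i] - a * u[i] - ls) / (1 - a)
      inside <- if (i < n - 1) (us >= u[i] && us < u[i + 1])
                else (us >= u[i] && us <= u[i + 1])
      if (inside) add(us, if (a < 1) "stable" else "unstable")
    }
  }
  # right flat tail: v = v[n] for u > u[n]
  if (n > 1) {
    u_star <- v[n] - ls
    if (u_star > u[n]) add(u_star, "stable")
  }

  if (!length(hits_u)) {
    return(structure(data.frame(level = numeric(0), output = numeric(0),
                                stability = character(0)),
                     class = c("fixed_points", "data.frame")))
  }
  o <- order(hits_u)
  hits_u <- hits_u[o]
  hits_stab <- hits_stab[o]
  # merge near-coincident crossings (tangencies): one point, stability unknown
  keep_u <- hits_u[1]
  keep_stab <- hits_stab[1]
  for (j in seq_along(hits_u)[-1]) {
    if (hits_u[j] - keep_u[length(keep_u)] < 1e-9) {
      keep_stab[length(keep_stab)] <- "unknown"
    } else {
      keep_u <- c(keep_u, hits_u[j])
      keep_stab <- c(keep_stab, hits_stab[j])
    }
  }
  lev <- exp(keep_u)
  structure(data.frame(level = lev,
                       output = loglog_interp(obj, lev),
                       stability = keep_stab),
            class = c("fixed_points", "data.frame"))
}

#' Monte-Carlo model-independent prediction
#'
#' Propagates measurement uncertainty through the model-independent
#' prediction: per trial, the log of each IOC output node is perturbed by
#' Gaussian noise (scaled by the replicate standard errors of measurement),
#' the interpolation-and-intersection procedure is re-run, and all
#' predicted levels are collected. Reports the fraction of trials whose
#' prediction is multistable (more than one stable point).
#'
#' @param grid A `plf_grid`.
#' @param line An `equivalence_line`.
#' @param axis,regulator_index,backgrounds,input_scale As in
#'   [ioc_from_grid()].
#' @param noise_sd Per-node log-scale noise SD; default: the slice's
#'   replicate SEMs of log output (`NA`s replaced by their median).
#' @param trials Number of Monte-Carlo trials (>= 1).
#' @param seed Integer RNG seed.
#' @return A list with `deterministic` (the unperturbed `fixed_points`),
#'   `levels` (data frame `trial`, `level`, `stability`),
#'   `multistable_fraction`, and `trials`.
#' @export
mc_predict <- function(grid, line, axis = c("luxR", "luxI"), regulator_index,
                       backgrounds = c(0, 0), noise_sd = NULL,
                       trials = 1000, seed = 1L, input_scale = 1) {
  axis <- match.arg(axis)
  if (trials < 1) stop("trials must be >= 1", call. = FALSE)
  base <- ioc_from_grid(grid, axis, regulator_index, backgrounds,
                        input_scale = input_scale)
  if (is.null(noise_sd)) {
    sem <- attr(base, "log_sem")
    if (all(!is.finite(sem))) sem <- rep(0, length(base$input))
    sem[!is.finite(sem)] <- stats::median(sem[is.finite(sem)])
    noise_sd <- sem
  }
  noise_sd <- rep_len(noise_sd, length(base$input))
  det <- find_intersections(base, line)
  res <- with_seed(seed, {
    out <- vector("list", trials)
    for (t in seq_len(trials)) {
      y_t <- exp(log(base$output) + stats::rnorm(length(noise_sd), 0, noise_sd))
      obj_t <- ioc(base$input, y_t, base$regulator, base$axis)
      fp <- find_intersections(obj_t, line)
      out[[t]] <- if (nrow(fp)) data.frame(trial = t, level = fp$level,
                                           stability = fp$stability)
                  else data.frame(trial = t, level = NA_real_,
                                  stability = NA_character_)[0, ]
    }
    out
  })
  levels_df <- do.call(rbind, res)
  n_stable <- tapply(levels_df$stability == "stable", levels_df$trial, sum)
  multi <- sum(n_stable > 1) / trials
  list(deterministic = det, levels = levels_df,
       multistable_fraction = unname(multi), trials = trials)
}

#' Interpolate predictions across regulator levels
#'
#' Feedback predictions are made at the regulator levels realized on the
#' measured grid; the level actually set in an experiment (e.g. an
#' IPTG-induced LuxI::CFP level in the autonomous LuxR-feedback loop)
#' generally falls between them. Predicted stable levels are carried to
#' the target by power-law (log-log linear) interpolation across the
#' regulator axis, branch-wise: when both flanking regulator levels
#' predict the same number of stable branches, lower branches interpolate
#' with lower and upper with upper; when branch counts differ, the common
#' branches are interpolated and a branch-boundary warning is raised.
#'
#' @param predictions A data frame with columns `regulator` (> 0) and
#'   `level` (> 0), optionally `stability` (rows with
#'   `stability != "stable"` are dropped): the predicted stable levels at
#'   each measured regulator value.
#' @param target Regulator level to predict at (> 0); must be bracketed by
#'   (or equal to) measured levels.
#' @return Numeric vector of predicted level(s) at `target`, ascending.
#' @export
interp_across_regulator <- function(predictions, target) {
  stopifnot(is.data.frame(predictions),
            all(c("regulator", "level") %in% names(predictions)))
  if ("stability" %in% names(predictions))
    predictions <- predictions[predictions$stability == "stable", ]
  predictions <- predictions[is.finite(predictions$level), ]
  if (!nrow(predictions)) stop("no stable predictions supplied", call. = FALSE)
  if (!is.finite(target) || target <= 0) stop("target must be > 0", call. = FALSE)
  regs <- sort(unique(predictions$regulator))
  if (length(regs) < 2 && !(target %in% regs))
    stop("need >= 2 measured regulator levels flanking the target", call. = FALSE)
  lev_at <- function(r) sort(predictions$level[predictions$regulator == r])
  if (any(abs(regs - target) / target < 1e-12))
    return(lev_at(regs[which.min(abs(regs - target))]))
  if (target < min(regs) || target > max(regs))
    stop("target lies outside the measured regulator range", call. = FALSE)
  i <- findInterval(target, regs)
  r1 <- regs[i]; r2 <- regs[i + 1]
  l1 <- lev_at(r1); l2 <- lev_at(r2)
  k <- min(length(l1), length(l2))
  if (length(l1) != length(l2))
    warning(sprintf(paste0("branch count changes between regulator %.4g (%d) ",
                           "and %.4g (%d); interpolating the %d common branch(es)"),
                    r1, length(l1), r2, length(l2), k), call. = FALSE)
  w <- (log(target) - log(r1)) / (log(r2) - log(r1))
  sort(exp((1 - w) * log(l1[seq_len(k)]) + w * log(l2[seq_len(k)])))
}

#' Model-based input-output characteristic
#'
#' Evaluates the fitted parameterized PLF densely along the input axis at a
#' fixed regulator level, scaled to output fluorescence units.
#'
#' @param p A [plf_params].
#' @param topo A 1-D feedback [topology_spec] naming the input axis
#'   (`luxR_feedback`: input LuxR; `luxI_feedback`: input LuxI) and
#'   carrying the clamped regulator level.
#' @param input_range Length-2 positive range of input levels.
#' @param n_points Number of log-spaced evaluation points (default 200).
#' @param output_scale Output fluorescence per unit transcription; default
#'   the topology's feedback `lambda`, so that intersections with the
#'   unit-slope line give the feedback steady states directly.
#' @return An `ioc`.
#' @export
model_based_ioc <- function(p, topo, input_range, n_points = 200,
                            output_scale = NULL) {
  validate_plf_params(p)
  stopifnot(inherits(topo, "topology_spec"),
            topo$kind %in% c("luxR_feedback", "luxI_feedback"))
  if (length(input_range) != 2 || any(input_range <= 0) ||
      input_range[1] >= input_range[2])
    stop("input_range must be a positive increasing pair", call. = FALSE)
  if (is.null(output_scale)) output_scale <- feedback_lambda(topo)
  x <- exp(seq(log(input_range[1]), log(input_range[2]), length.out = n_points))
  g <- feedback_map(topo, p)
  y <- output_scale / feedback_lambda(topo) * g(x)
  ioc(x, pmax(y, .Machine$double.xmin),
      regulator = if (topo$kind == "luxR_feedback") topo$luxI_fixed else topo$luxR_fixed,
      axis = if (topo$kind == "luxR_feedback") "luxR" else "luxI")
}
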