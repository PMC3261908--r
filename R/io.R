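#' Write a PLF grid to a tab-delimited file
#'
#' Tables are written with `#`-prefixed metadata lines (design levels,
#' seed, noise cv, output scale) followed by a header row. Units:
#' aTc in ng/ml, IPTG in uM, all fluorescence in arbitrary units.
#'
#' @param grid A `plf_grid` (see [generate_plf_grid()]).
#' @param path Output file path.
#' @param force Overwrite an existing file (default FALSE: refuse).
#' @return `path`, invisibly.
#' @export
write_plf_grid <- function(grid, path, force = FALSE) {
  stopifnot(inherits(grid, "plf_grid"))
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)", call. = FALSE)
  meta <- c(
    "# promoterlogic PLF grid (tab-delimited)",
    "# units: aTc_ng_ml ng/ml; IPTG_uM uM; fluorescence arbitrary units",
    sprintf("# aTc_levels: %s", paste(attr(grid, "aTc_levels"), collapse = ",")),
    sprintf("# IPTG_levels: %s", paste(attr(grid, "IPTG_levels"), collapse = ",")),
    sprintf("# seed: %d", attr(grid, "seed")),
    sprintf("# cv: %g", attr(grid, "cv")),
    sprintf("# output_scale: %g", attr(grid, "output_scale"))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(grid, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

grid_columns <- c("aTc_ng_ml", "IPTG_uM", "replicate",
                  "luxI_cfp", "luxR_yfp", "output_cfp")

#' Read and validate a PLF grid file
#'
#' Reads the tab-delimited grid format written by [write_plf_grid()]
#' (metadata lines prefixed `#`, then a header row). Validation errors name
#' the offending row; an incomplete design (some inducer combinations
#' absent) loads with a completeness warning.
#'
#' @param path File path.
#' @return A `plf_grid` data frame.
#' @export
read_plf_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("grid file has no data rows", call. = FALSE)
  grid <- utils::read.table(text = body, header = TRUE, sep = "\t",
                            colClasses = "character")
  missing_cols <- setdiff(grid_columns, names(grid))
  if (length(missing_cols))
    stop("grid file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in grid_columns) {
    val <- suppressWarnings(as.numeric(grid[[col]]))
    bad <- which(is.na(val) & !is.na(grid[[col]]))
    if (length(bad))
      stop(sprintf("malformed numeric value in column '%s', data row %d: '%s'",
                   col, bad[1], grid[[col]][bad[1]]), call. = FALSE)
    grid[[col]] <- val
  }
  fl <- c("luxI_cfp", "luxR_yfp", "output_cfp")
  for (col in fl) {
    bad <- which(grid[[col]] < 0)
    if (length(bad))
      stop(sprintf("negative fluorescence in column '%s', data row %d",
                   col, bad[1]), call. = FALSE)
  }
  key <- paste(grid$aTc_ng_ml, grid$IPTG_uM, grid$replicate)
  if (anyDuplicated(key))
    stop("duplicated replicate key at data row ", which(duplicated(key))[1],
         call. = FALSE)
  meta_val <- function(tag) {
    ln <- grep(paste0("^# ", tag, ":"), meta, value = TRUE)
    if (!length(ln)) return(NULL)
    as.numeric(strsplit(sub(paste0("^# ", tag, ":\\s*"), "", ln[1]), ",")[[1]])
  }
  aTc_levels <- meta_val("aTc_levels")
  IPTG_levels <- meta_val("IPTG_levels")
  if (is.null(aTc_levels)) aTc_levels <- sort(unique(grid$aTc_ng_ml))
  if (is.null(IPTG_levels)) IPTG_levels <- sort(unique(grid$IPTG_uM))
  combos <- unique(grid[, c("aTc_ng_ml", "IPTG_uM")])
  n_expected <- length(aTc_levels) * length(IPTG_levels)
  if (nrow(combos) < n_expected)
    warning(sprintf("grid is incomplete: %d of %d inducer combinations present",
                    nrow(combos), n_expected), call. = FALSE)
  structure(grid,
            aTc_levels = aTc_levels, IPTG_levels = IPTG_levels,
            seed = if (length(meta_val("seed"))) as.integer(meta_val("seed")) else NA_integer_,
            cv = if (length(meta_val("cv"))) meta_val("cv") else NA_real_,
            output_scale = if (length(meta_val("output_scale"))) meta_val("output_scale") else NA_real_,
            class = c("plf_grid", "data.frame"))
}

#' Write a flat key/value parameter file
#'
#' Parameter sets (PLF constants, Hill induction curves, fitted lines of
#' equivalence) are serialized one `key<TAB>value` pair per line, with
#' `#`-prefixed comment lines, for diff-friendliness.
#'
#' @param params A named list (or `plf_params` / `hill_params` /
#'   `equivalence_line`) of scalar numeric values.
#' @param path Output file path.
#' @param force Overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_param_file <- function(params, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)", call. = FALSE)
  cls <- class(params)[1]
  vals <- unclass(params)
  vals <- vals[vapply(vals, function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v), TRUE)]
  lines <- c(sprintf("# promoterlogic parameter file (class: %s)", cls),
             sprintf("%s\t%.17g", names(vals), unlist(vals)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key/value parameter file
#'
#' @param path File path (format of [write_param_file()]).
#' @param as Reconstruct a typed object: one of `"list"`, `"plf_params"`,
#'   `"hill_params"`, `"equivalence_line"`. The default `"auto"` uses the
#'   class recorded in the file's comment line, falling back to a plain
#'   list.
#' @return A named list or typed parameter object.
#' @export
read_param_file <- function(path, as = "auto") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (as == "auto") {
    m <- regmatches(lines, regexec("\\(class: ([a-z_]+)\\)", lines))
    cls <- unlist(lapply(m, function(x) if (length(x) == 2) x[2] else NULL))
    as <- if (length(cls)) cls[1] else "list"
  }
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  kv <- strsplit(lines, "\t")
  bad <- which(vapply(kv, length, 1L) != 2)
  if (length(bad))
    stop("malformed parameter line ", bad[1], ": '", lines[bad[1]], "'",
         call. = FALSE)
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- vapply(kv, `[`, "", 1)
  if (anyNA(vals)) stop("non-numeric parameter value in ", path, call. = FALSE)
  lst <- as.list(vals)
  switch(as,
    plf_params = do.call(plf_params, lst[names(formals(plf_params))]),
    hill_params = do.call(hill_params, lst[names(formals(hill_params))]),
    equivalence_line = equivalence_line(lst$scale,
                                        lst$background_x %||% 0,
                                        lst$background_y %||% 0),
    lst
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
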