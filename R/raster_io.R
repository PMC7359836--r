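# Landscape cost classes. Integer codes used on disk and in class rasters.
CLASS_CODES <- c(SUITABLE = 0L, UNSUITABLE_LAND = 1L, GLACIER = 2L, SEA = 3L)

#' Landscape class codes
#'
#' Cost-class rasters code every cell as one of four landscape classes:
#' `0 = SUITABLE`, `1 = UNSUITABLE_LAND`, `2 = GLACIER`, `3 = SEA`.
#' @return named integer vector of the four codes.
#' @export
landscape_classes <- function() CLASS_CODES

new_raster <- function(values, grid, kind) {
  stopifnot(length(values) == n_cells(grid))
  structure(list(values = values, grid = grid, kind = kind),
            class = c(paste0(kind, "_raster"), "landscape_raster"))
}

#' @export
print.landscape_raster <- function(x, ...) {
  cat(sprintf("%s raster on ", x$kind))
  print(x$grid)
  invisible(x)
}

#' Build rasters in memory
#'
#' `suitability_raster` holds one logical per cell, `cost_class_raster` one
#' integer class code per cell (see [landscape_classes()]). Values are
#' row-major vectors, or matrices with `n_rows` rows (northernmost row first).
#'
#' @param values logical (suitability) or integer class codes (cost class),
#'   length `n_rows * n_cols` row-major, or a matrix.
#' @param grid a [landscape_grid()].
#' @return a `landscape_raster` object.
#' @export
suitability_raster <- function(values, grid) {
  if (is.matrix(values)) values <- as.vector(t(values))
  values <- as.logical(values)
  if (anyNA(values)) stop("suitability values must be 0/1", call. = FALSE)
  new_raster(values, grid, "suitability")
}

#' @rdname suitability_raster
#' @export
cost_class_raster <- function(values, grid) {
  if (is.matrix(values)) values <- as.vector(t(values))
  values <- as.integer(values)
  if (anyNA(values) || !all(values %in% CLASS_CODES))
    stop("cost class codes must be in {0,1,2,3}", call. = FALSE)
  new_raster(values, grid, "cost_class")
}

#' Read and write ESRI ASCII grids
#'
#' Rasters are exchanged as plain-text ESRI ASCII grids (`.asc`). The header
#' `xllcorner`/`yllcorner` is the lower-left cell *corner*; internally the
#' grid origin is the center of the upper-left cell. `NODATA_value` cells are
#' mapped to unsuitable (`FALSE`) for suitability rasters and to
#' `UNSUITABLE_LAND` for cost-class rasters, which keeps the cost graph fully
#' connected.
#'
#' @param path file path.
#' @param kind `"suitability"` or `"cost_class"`.
#' @return `read_raster` returns a `landscape_raster`; `write_raster` returns
#'   `path` invisibly.
#' @export
read_raster <- function(path, kind = c("suitability", "cost_class")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path, call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  body <- lines[i:length(lines)]
  if (length(body) != nr)
    stop("expected ", nr, " data rows, found ", length(body), call. = FALSE)
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(vals) != nc))
    stop("row length disagrees with ncols header in ", path, call. = FALSE)
  v <- unlist(vals)  # row-major, north row first, as stored
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  grid <- landscape_grid(
    nr, nc,
    origin_lon = hdr$xllcorner + hdr$cellsize / 2,
    origin_lat = hdr$yllcorner + hdr$cellsize / 2 + (nr - 1) * hdr$cellsize,
    cell_size = hdr$cellsize)
  is_na <- v == nodata
  if (kind == "suitability") {
    v[is_na] <- 0
    if (!all(v %in% c(0, 1)))
      stop("suitability raster must be binary 0/1", call. = FALSE)
    suitability_raster(v, grid)
  } else {
    v[is_na] <- CLASS_CODES[["UNSUITABLE_LAND"]]
    if (!all(v %in% CLASS_CODES))
      stop("unknown cost class code in ", path, call. = FALSE)
    cost_class_raster(v, grid)
  }
}

#' @rdname read_raster
#' @param raster a `landscape_raster` to write.
#' @export
write_raster <- function(raster, path) {
  g <- raster$grid
  v <- as.integer(raster$values)
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_lon - g$cell_size / 2),
    sprintf("yllcorner %.10g",
            g$origin_lat - (g$n_rows - 1) * g$cell_size - g$cell_size / 2),
    sprintf("cellsize %.10g", g$cell_size),
    "NODATA_value -9999")
  m <- matrix(v, nrow = g$n_rows, byrow = TRUE)
  rows <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Time series of paired suitability / cost-class rasters
#'
#' The dynamic landscape: an ordered list (oldest first) of binary suitability
#' rasters paired with cost-class rasters on one shared grid, each step
#' spanning `step_years` years (default 100, a centennial hindcast step).
#'
#' @param suitability list of suitability rasters, oldest first.
#' @param cost_class list of cost-class rasters, same length.
#' @param step_years years per step (> 0).
#' @param years_bp optional numeric vector of years-before-present labels.
#' @return an object of class `suitability_series`.
#' @export
suitability_series <- function(suitability, cost_class, step_years = 100,
                               years_bp = NULL) {
  stopifnot(length(suitability) >= 1,
            length(suitability) == length(cost_class), step_years > 0)
  if (is.null(years_bp))
    years_bp <- (length(suitability) - seq_along(suitability)) * step_years
  structure(list(suitability = suitability, cost_class = cost_class,
                 step_years = step_years, years_bp = years_bp,
                 grid = suitability[[1]]$grid),
            class = "suitability_series")
}

#' @export
print.suitability_series <- function(x, ...) {
  cat(sprintf("suitability_series: %d steps of %g years on ",
              length(x$suitability), x$step_years))
  print(x$grid)
  invisible(x)
}

#' @export
length.suitability_series <- function(x) length(x$suitability)

#' Validate a suitability series
#'
#' Checks the structural invariants of a [suitability_series()]: every raster
#' on the shared grid, suitability and cost class mutually consistent
#' (`suitable == TRUE` iff class `SUITABLE`). Steps with zero suitable cells
#' are reported as warnings, not violations.
#'
#' @param series a [suitability_series()].
#' @return list with character vectors `violations` and `warnings`; both
#'   empty iff the series is fully consistent.
#' @export
validate_series <- function(series) {
  violations <- character()
  warnings <- character()
  g <- series$grid
  for (s in seq_along(series$suitability)) {
    su <- series$suitability[[s]]
    cc <- series$cost_class[[s]]
    if (!same_grid(su$grid, g))
      violations <- c(violations,
        sprintf("step %d: suitability raster on a different grid", s))
    if (!same_grid(cc$grid, g))
      violations <- c(violations,
        sprintf("step %d: cost-class raster on a different grid", s))
    if (same_grid(su$grid, g) && same_grid(cc$grid, g)) {
      mism <- which(su$values != (cc$values == CLASS_CODES[["SUITABLE"]]))
      for (cell in mism)
        violations <- c(violations,
          sprintf("step %d, cell %d: suitability=%s but class code %d",
                  s, cell, su$values[cell], cc$values[cell]))
      if (!any(su$values))
        warnings <- c(warnings, sprintf("step %d: zero suitable cells", s))
    }
  }
  list(violations = violations, warnings = warnings)
}

#' Read and write series manifests
#'
#' A series manifest is a CSV with columns `step`, `years_bp`, `suitability`,
#' `cost_class`; raster paths are relative to the manifest's directory.
#'
#' @param path manifest CSV path.
#' @param step_years years per step.
#' @return `read_series` returns a [suitability_series()].
#' @export
read_series <- function(path, step_years = 100) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("step", "years_bp", "suitability", "cost_class")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  man <- man[order(man$step), , drop = FALSE]
  dir <- dirname(path)
  su <- lapply(file.path(dir, man$suitability), read_raster, "suitability")
  cc <- lapply(file.path(dir, man$cost_class), read_raster, "cost_class")
  suitability_series(su, cc, step_years = step_years,
                     years_bp = man$years_bp)
}

#' @rdname read_series
#' @param series a [suitability_series()] to write.
#' @param dir output directory (created if absent).
#' @param prefix filename prefix for the rasters.
#' @export
write_series <- function(series, dir, prefix = "step") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(series)
  su_files <- sprintf("%s_%03d_suit.asc", prefix, seq_len(n))
  cc_files <- sprintf("%s_%03d_class.asc", prefix, seq_len(n))
  for (s in seq_len(n)) {
    write_raster(series$suitability[[s]], file.path(dir, su_files[s]))
    write_raster(series$cost_class[[s]], file.path(dir, cc_files[s]))
  }
  man <- data.frame(step = seq_len(n), years_bp = series$years_bp,
                    suitability = su_files, cost_class = cc_files)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE, quote = FALSE)
  invisible(man_path)
}
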