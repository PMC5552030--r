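#' Construct a landscape grid
#'
#' Bundles an aligned elevation raster and categorical land-cover raster into
#' the container the model operates on. Elevations are metres above mean
#' lagoon high water (MLHW); the land-cover grid holds integer codes
#' (`1..K` indexing `classes`, `0` open water, `NA` nodata).
#'
#' @param elevation Numeric matrix of ground elevation (m above MLHW).
#' @param community Integer matrix of the same shape: `0` = open water,
#'   `1..K` = index into `classes`, `NA` = nodata.
#' @param classes Character vector of community codes.
#' @param cell_size Cell edge length in metres.
#' @param datum_offset_mlhw NAVD88 elevation of MLHW (m) that was subtracted
#'   at ingestion; retained as metadata.
#' @param georeference List with `xll`, `yll` (lower-left corner, projected
#'   metres) and `crs` (opaque CRS string). Carried through, never used in
#'   computation except to place cell-centre coordinates.
#' @return An object of class `landscape_grid`.
#' @export
landscape_grid <- function(elevation, community, classes = ccbic_communities(),
                           cell_size = 3,
                           datum_offset_mlhw = 0,
                           georeference = list(xll = 0, yll = 0, crs = "")) {
  stopifnot(is.matrix(elevation), is.matrix(community))
  if (!identical(dim(elevation), dim(community))) {
    stop("alignment error: elevation and community grids differ in shape", call. = FALSE)
  }
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  storage.mode(community) <- "integer"
  codes <- unique(community[!is.na(community)])
  bad <- codes[codes < 0L | codes > length(classes)]
  if (length(bad) > 0) {
    stop(
      "schema error: unknown land-cover code(s): ", paste(sort(bad), collapse = ", "),
      call. = FALSE
    )
  }
  valid <- !is.na(community) & community > 0L
  if (any(valid & !is.finite(elevation))) {
    stop("every community cell must have a finite elevation", call. = FALSE)
  }
  structure(
    list(
      elevation = elevation, community = community, classes = classes,
      cell_size = cell_size, datum_offset_mlhw = datum_offset_mlhw,
      georeference = georeference
    ),
    class = "landscape_grid"
  )
}

#' @export
print.landscape_grid <- function(x, ...) {
  n_land <- sum(!is.na(x$community) & x$community > 0L)
  cat(
    "<landscape_grid> ", nrow(x$elevation), "x", ncol(x$elevation),
    " cells (", x$cell_size, " m), ", n_land, " community pixels, ",
    length(x$classes), " classes\n",
    sep = ""
  )
  invisible(x)
}

# ---- ESRI ASCII grid + TIFF primitives ------------------------------------

read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else {
      break
    }
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]])) stop("I/O error: malformed ASCII grid header in ", path, call. = FALSE)
  }
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("I/O error: cell count mismatch in ", path, call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  prj <- sub("\\.[^.]+$", ".prj", path)
  crs <- if (file.exists(prj)) paste(readLines(prj), collapse = "\n") else ""
  list(
    data = m, xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0,
    cellsize = hdr$cellsize, crs = crs
  )
}

write_ascii_grid <- function(m, path, xll = 0, yll = 0, cellsize = 3,
                             nodata = -9999, crs = "") {
  vals <- m
  vals[is.na(vals)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(xll, digits = 15)),
    paste("yllcorner", format(yll, digits = 15)),
    paste("cellsize", format(cellsize, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  writeLines(apply(vals, 1, function(r) paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = " ")), con)
  if (nzchar(crs)) writeLines(crs, sub("\\.[^.]+$", ".prj", path))
  invisible(path)
}

# Single-band float TIFF with a JSON sidecar carrying the linear scaling and
# georeference (the in-package TIFF writer stores samples in [0,1]).
read_tiff_grid <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read ", path, call. = FALSE)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("I/O error: missing sidecar ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- img * (meta$max - meta$min) + meta$min
  if (!is.null(meta$nodata)) m[abs(m - meta$nodata) < 1e-6 * max(1, abs(meta$nodata))] <- NA_real_
  list(
    data = m, xll = meta$xll %||% 0, yll = meta$yll %||% 0,
    cellsize = meta$cellsize, crs = meta$crs %||% ""
  )
}

write_tiff_grid <- function(m, path, xll = 0, yll = 0, cellsize = 3,
                            nodata = -9999, crs = "") {
  vals <- m
  vals[is.na(vals)] <- nodata
  lo <- min(vals)
  hi <- max(vals)
  if (hi <= lo) hi <- lo + 1
  tiff::writeTIFF((vals - lo) / (hi - lo), path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(min = lo, max = hi, nodata = nodata, xll = xll, yll = yll,
         cellsize = cellsize, crs = crs),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

grid_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff")) "tiff" else "ascii"
}

read_grid_file <- function(path) {
  if (grid_format(path) == "tiff") read_tiff_grid(path) else read_ascii_grid(path)
}

write_grid_file <- function(m, path, ...) {
  if (grid_format(path) == "tiff") write_tiff_grid(m, path, ...) else write_ascii_grid(m, path, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- user-facing I/O -------------------------------------------------------

#' Read an aligned elevation / land-cover raster pair
#'
#' Reads the digital terrain model (DTM) and categorical land-cover raster,
#' validates that they are aligned, converts elevations from the raster's
#' vertical datum to metres above MLHW (`raw - datum_offset_mlhw`), and
#' validates land-cover codes against the configured class list.
#'
#' Supported formats, chosen by file extension: ESRI ASCII grid (`.asc`,
#' exact text round-trip; CRS in a `.prj` sidecar) and single-band TIFF
#' (`.tif`/`.tiff`, values rescaled via a JSON sidecar; reduced precision).
#'
#' @param dtm_path,landcover_path Paths to the two single-band rasters.
#' @param datum_offset_mlhw NAVD88 elevation of MLHW in metres (default 0).
#' @param classes Community code list; land-cover integers `1..K` index it.
#' @param code_map Optional named integer vector mapping raw land-cover codes
#'   to grouped community codes (names = raw code, value = index into
#'   `classes`, or 0 for open water), applied at read time.
#' @return A [landscape_grid()].
#' @export
read_landscape <- function(dtm_path, landcover_path, datum_offset_mlhw = 0,
                           classes = ccbic_communities(), code_map = NULL) {
  dtm <- read_grid_file(dtm_path)
  lc <- read_grid_file(landcover_path)
  if (!identical(dim(dtm$data), dim(lc$data))) {
    stop("alignment error: DTM and land-cover rasters differ in shape", call. = FALSE)
  }
  tol <- 1e-6 * max(1, dtm$cellsize)
  if (abs(dtm$cellsize - lc$cellsize) > tol ||
    abs(dtm$xll - lc$xll) > tol || abs(dtm$yll - lc$yll) > tol) {
    stop("alignment error: DTM and land-cover georeferences disagree", call. = FALSE)
  }
  comm <- round(lc$data)
  if (!is.null(code_map)) {
    remapped <- comm
    raw_codes <- as.integer(names(code_map))
    known <- comm %in% raw_codes | is.na(comm)
    if (any(!known)) {
      stop(
        "schema error: land-cover code(s) absent from code_map: ",
        paste(sort(unique(comm[!known])), collapse = ", "),
        call. = FALSE
      )
    }
    idx <- match(comm, raw_codes)
    remapped[!is.na(idx)] <- code_map[idx[!is.na(idx)]]
    comm <- remapped
  }
  storage.mode(comm) <- "integer"
  landscape_grid(
    elevation = dtm$data - datum_offset_mlhw,
    community = comm,
    classes = classes,
    cell_size = dtm$cellsize,
    datum_offset_mlhw = datum_offset_mlhw,
    georeference = list(xll = dtm$xll, yll = dtm$yll, crs = dtm$crs)
  )
}

#' Write a landscape grid to a raster pair
#'
#' Inverse of [read_landscape()]: elevations are written back on the raster
#' datum (`elevation_mlhw + datum_offset_mlhw`), land cover as integer codes.
#'
#' @param grid A [landscape_grid()].
#' @param dtm_path,landcover_path Output paths (`.asc` or `.tif`).
#' @return The grid, invisibly.
#' @export
write_landscape <- function(grid, dtm_path, landcover_path) {
  stopifnot(inherits(grid, "landscape_grid"))
  g <- grid$georeference
  write_grid_file(
    grid$elevation + grid$datum_offset_mlhw, dtm_path,
    xll = g$xll, yll = g$yll, cellsize = grid$cell_size, crs = g$crs %||% ""
  )
  write_grid_file(
    grid$community, landcover_path,
    xll = g$xll, yll = g$yll, cellsize = grid$cell_size, nodata = -9999,
    crs = g$crs %||% ""
  )
  invisible(grid)
}

#' Flatten a landscape grid to a pixel table
#'
#' One record per cell carrying a natural community (open water and nodata
#' cells are dropped), with cell-centre projected coordinates for the
#' spatial regression.
#'
#' @param grid A [landscape_grid()].
#' @return A tibble with columns `row`, `col`, `x`, `y` (projected metres),
#'   `elevation` (m above MLHW) and `community` (character code).
#' @export
#' @examples
#' grid <- generate_landscape(synthetic_config(rows = 40, cols = 40, seed = 1))
#' to_pixel_table(grid)
to_pixel_table <- function(grid) {
  stopifnot(inherits(grid, "landscape_grid"))
  keep <- !is.na(grid$community) & grid$community > 0L
  idx <- which(keep, arr.ind = TRUE)
  g <- grid$georeference
  nr <- nrow(grid$elevation)
  tibble::tibble(
    row = as.integer(idx[, 1]),
    col = as.integer(idx[, 2]),
    x = (g$xll %||% 0) + (as.numeric(idx[, 2]) - 0.5) * grid$cell_size,
    y = (g$yll %||% 0) + (nr - as.numeric(idx[, 1]) + 0.5) * grid$cell_size,
    elevation = grid$elevation[keep],
    community = grid$classes[grid$community[keep]]
  )
}
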