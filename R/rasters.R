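# Lightweight lon/lat grid rasters. Row 1 is the northernmost row; cell values
# refer to cell centres; point-in-cell lookup uses half-open cells
# [x0, x0 + res) in both axes, so a point on a shared edge belongs to the cell
# whose origin it is (the east/north neighbour).

#' Define a lon/lat grid
#'
#' @param nrow,ncol grid dimensions.
#' @param xmin,ymin lower-left corner (degrees).
#' @param res_arcmin cell size in arc-minutes.
#' @param nodata nodata sentinel written to files (default -9999).
#' @return a `grid_def` list.
#' @export
grid_def <- function(nrow, ncol, xmin, ymin, res_arcmin, nodata = -9999) {
  stopifnot(nrow >= 1, ncol >= 1, res_arcmin > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 xmin = xmin, ymin = ymin,
                 res = res_arcmin / 60, res_arcmin = res_arcmin,
                 nodata = nodata),
            class = "grid_def")
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(a[c("nrow", "ncol", "xmin", "ymin", "res")],
                   b[c("nrow", "ncol", "xmin", "ymin", "res")]))
}

#' Single-layer raster on a grid
#'
#' @param grid a [grid_def()].
#' @param values numeric matrix `nrow x ncol` (row 1 = north) or a scalar.
#' @return a `grid_raster`.
#' @export
grid_raster <- function(grid, values = NA_real_) {
  if (length(values) == 1) values <- matrix(values, grid$nrow, grid$ncol)
  stopifnot(nrow(values) == grid$nrow, ncol(values) == grid$ncol)
  structure(list(grid = grid, values = values), class = "grid_raster")
}

#' Row/column index of the cell containing points
#'
#' Half-open convention: a point on a shared edge belongs to the cell whose
#' lower/left edge it lies on. Points outside the extent get NA.
#'
#' @param grid a [grid_def()].
#' @param lon,lat coordinates.
#' @return data.frame with `row`, `col` (row 1 = north), and `cell`
#'   (column-major linear index into the value matrix).
#' @export
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$xmin) / grid$res) + 1
  row_s <- floor((lat - grid$ymin) / grid$res) + 1  # from south
  row <- grid$nrow - row_s + 1
  bad <- col < 1 | col > grid$ncol | row < 1 | row > grid$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer(row + (col - 1) * grid$nrow))
}

#' Centre coordinates of cells
#'
#' @param grid a [grid_def()].
#' @param row,col cell indices (row 1 = north).
#' @return data.frame with `lon`, `lat`.
#' @export
cell_centre <- function(grid, row, col) {
  data.frame(lon = grid$xmin + (col - 0.5) * grid$res,
             lat = grid$ymin + (grid$nrow - row + 0.5) * grid$res)
}

#' Look up raster values at points
#'
#' @param raster a `grid_raster`.
#' @param lon,lat coordinates.
#' @return numeric vector; NA outside the extent or on nodata cells.
#' @export
raster_lookup <- function(raster, lon, lat) {
  ix <- cell_index(raster$grid, lon, lat)
  v <- rep(NA_real_, length(lon))
  ok <- !is.na(ix$cell)
  v[ok] <- raster$values[cbind(ix$row[ok], ix$col[ok])]
  v[!is.na(v) & v == raster$grid$nodata] <- NA_real_
  v
}

#' Names of the 19 bioclimatic layers
#' @export
BIOCLIM_NAMES <- paste0("BIO", 1:19)

#' Bundle of 19 bioclimatic layers on a common grid
#'
#' Temperature layers are in degrees Celsius, precipitation layers in mm.
#' Nodata cells (NA) must coincide across layers.
#'
#' @param grid a [grid_def()].
#' @param layers named list of 19 matrices keyed BIO1..BIO19.
#' @return a `climate_stack`.
#' @export
climate_stack <- function(grid, layers) {
  if (length(layers) != 19) {
    stop("expected 19 bioclim layers, found ", length(layers), ": ",
         paste(names(layers), collapse = ", "))
  }
  if (!setequal(names(layers), BIOCLIM_NAMES)) {
    stop("layer names must be BIO1..BIO19; found: ",
         paste(names(layers), collapse = ", "))
  }
  layers <- layers[BIOCLIM_NAMES]
  na0 <- is.na(layers[[1]])
  for (nm in BIOCLIM_NAMES) {
    m <- layers[[nm]]
    if (nrow(m) != grid$nrow || ncol(m) != grid$ncol) {
      stop("grid mismatch in layer ", nm)
    }
    if (!identical(which(is.na(m)), which(na0))) {
      stop("nodata cells differ between BIO1 and ", nm)
    }
  }
  structure(list(grid = grid, layers = layers), class = "climate_stack")
}

#' Extract all 19 layer values at points
#'
#' @param stack a `climate_stack`.
#' @param lon,lat coordinates.
#' @return numeric matrix, one column per BIO layer; NA rows for points on
#'   nodata cells or outside the extent.
#' @export
stack_lookup <- function(stack, lon, lat) {
  out <- sapply(BIOCLIM_NAMES, function(nm) {
    raster_lookup(grid_raster(stack$grid, stack$layers[[nm]]), lon, lat)
  })
  if (length(lon) == 1) out <- matrix(out, 1, dimnames = list(NULL, BIOCLIM_NAMES))
  out
}

# ---- ESRI ASCII grid I/O -----------------------------------------------

#' Write a raster as an ESRI ASCII grid
#'
#' @param raster a `grid_raster`.
#' @param path output path (conventionally `.asc`).
#' @param digits significant digits written (default 10).
#' @export
write_ascii_grid <- function(raster, path, digits = 10) {
  g <- raster$grid
  v <- raster$values
  v[is.na(v)] <- g$nodata
  hdr <- c(
    paste("ncols", g$ncol), paste("nrows", g$nrow),
    paste("xllcorner", format(g$xmin, digits = 15)),
    paste("yllcorner", format(g$ymin, digits = 15)),
    paste("cellsize", format(g$res, digits = 15)),
    paste("NODATA_value", g$nodata)
  )
  body <- apply(v, 1, function(r) paste(format(r, digits = digits, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return a `grid_raster` (nodata cells as NA).
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  g <- grid_def(hdr$nrows, hdr$ncols, hdr$xllcorner, hdr$yllcorner,
                hdr$cellsize * 60,
                nodata = if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value)
  vals <- lapply(lines[i:length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  v <- do.call(rbind, vals)
  if (nrow(v) != g$nrow || ncol(v) != g$ncol) stop("malformed ASCII grid: ", path)
  v[v == g$nodata] <- NA_real_
  grid_raster(g, v)
}

#' Read a 19-layer bioclim stack from a directory of ASCII grids
#'
#' Files must be named `BIO1.asc` .. `BIO19.asc`.
#'
#' @param dir directory containing the 19 files, or a character vector of 19
#'   file paths named by layer.
#' @return a `climate_stack`.
#' @export
read_raster_stack <- function(dir) {
  if (length(dir) == 1 && dir.exists(dir)) {
    paths <- file.path(dir, paste0(BIOCLIM_NAMES, ".asc"))
    names(paths) <- BIOCLIM_NAMES
    found <- basename(paths)[file.exists(paths)]
    if (!all(file.exists(paths))) {
      stop("expected 19 layers BIO1.asc..BIO19.asc in ", dir,
           "; found: ", paste(found, collapse = ", "))
    }
  } else {
    paths <- dir
    if (length(paths) != 19) {
      stop("expected 19 layer paths, found ", length(paths), ": ",
           paste(names(paths), collapse = ", "))
    }
  }
  rs <- lapply(paths, read_ascii_grid)
  g <- rs[[1]]$grid
  for (nm in names(rs)) {
    if (!grid_equal(g, rs[[nm]]$grid)) stop("grid mismatch in layer ", nm)
  }
  climate_stack(g, lapply(rs, `[[`, "values"))
}

#' Write a climate stack as ESRI ASCII grids
#'
#' @param stack a `climate_stack`.
#' @param dir output directory (created if absent).
#' @export
write_raster_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in BIOCLIM_NAMES) {
    write_ascii_grid(grid_raster(stack$grid, stack$layers[[nm]]),
                     file.path(dir, paste0(nm, ".asc")))
  }
  invisible(dir)
}
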