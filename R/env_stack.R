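#' Build an environmental layer stack
#'
#' A stack of named, grid-shaped environmental layers (typically bioclimatic
#' temperature/precipitation variables plus soil variables) sharing one
#' no-data mask. Cells that are missing in any layer are masked in all
#' layers, so every valid cell has a complete predictor vector.
#'
#' @param grid a [grid_spec()].
#' @param layers named list of numeric matrices of dimension
#'   `n_rows x n_cols` (`NA` = no data).
#' @return Object of class `env_stack`: list with `grid`, `layers`
#'   (mask-harmonised), `mask` (logical matrix, TRUE = valid).
#' @export
env_stack <- function(grid, layers) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1,
            !is.null(names(layers)), !anyDuplicated(names(layers)))
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!is.matrix(l) || nrow(l) != grid$n_rows || ncol(l) != grid$n_cols) {
      stop("layer '", nm, "' does not match the grid shape", call. = FALSE)
    }
    storage.mode(layers[[nm]]) <- "double"
  }
  mask <- Reduce(`&`, lapply(layers, function(l) !is.na(l)))
  layers <- lapply(layers, function(l) { l[!mask] <- NA_real_; l })
  structure(list(grid = grid, layers = layers, mask = mask),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layer(s) [%s] on %d x %d grid, %d valid cells\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols, sum(x$mask)))
  invisible(x)
}

#' Valid (unmasked) cells of a stack
#'
#' @param env an [env_stack()].
#' @return A [cell_set()] of all cells with data in every layer.
#' @export
valid_cells <- function(env) {
  idx <- which(env$mask, arr.ind = TRUE)
  cell_set(cbind(row = idx[, 1] - 1L, col = idx[, 2] - 1L))
}

#' Extract layer values at cells
#'
#' Row order follows the input (no set normalisation), so values stay
#' aligned with any label vector built alongside the cells.
#'
#' @param env an [env_stack()].
#' @param cells matrix with `row`/`col` columns (zero-based).
#' @return Numeric matrix, one row per cell, one column per layer.
#' @export
env_values <- function(env, cells) {
  if (is.data.frame(cells)) cells <- as.matrix(cells[, c("row", "col")])
  stopifnot(all(cells[, 1] >= 0), all(cells[, 1] < env$grid$n_rows),
            all(cells[, 2] >= 0), all(cells[, 2] < env$grid$n_cols))
  lin <- cells[, 1] + 1L + cells[, 2] * env$grid$n_rows
  out <- vapply(env$layers, function(l) l[lin], numeric(nrow(cells)))
  if (nrow(cells) == 1) out <- matrix(out, nrow = 1,
                                      dimnames = list(NULL, names(env$layers)))
  out
}

#' Read an ESRI ASCII grid
#'
#' Plain-text raster format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`, optional
#' `NODATA_value`) followed by rows of values, north row first.
#'
#' @param file path to an `.asc` file.
#' @return List with `grid` (a [grid_spec()]) and `values` (matrix, `NA`
#'   where no data).
#' @export
read_ascii_grid <- function(file) {
  con <- file(file, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1)
    parts <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", file, call. = FALSE)
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  half <- hdr$cellsize / 2
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - half
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - half
  vals <- scan(con, what = double(), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  grid <- grid_spec(lon_min = xll, lat_max = yll + nr * hdr$cellsize,
                    res_arcmin = hdr$cellsize * 60, n_rows = nr, n_cols = nc)
  list(grid = grid, values = m)
}

#' Write an ESRI ASCII grid
#'
#' @param values numeric matrix (north row first); `NA` written as the
#'   no-data value.
#' @param grid a [grid_spec()].
#' @param file output path.
#' @param nodata no-data sentinel (default -9999).
#' @export
write_ascii_grid <- function(values, grid, file, nodata = -9999) {
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.10g", grid$lon_min),
           sprintf("yllcorner %.10g", grid$lat_min),
           sprintf("cellsize %.10g", grid$res_deg),
           sprintf("NODATA_value %.10g", nodata))
  values[is.na(values)] <- nodata
  body <- apply(values, 1, paste, collapse = " ")
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read several ASCII grids as one stack
#'
#' Layer names are the file stems.
#'
#' @param files character vector of `.asc` paths.
#' @return An [env_stack()]; all files must share one grid.
#' @export
read_env_stack <- function(files) {
  stopifnot(length(files) >= 1)
  parsed <- lapply(files, read_ascii_grid)
  g <- parsed[[1]]$grid
  for (p in parsed[-1]) {
    if (!isTRUE(all.equal(unclass(p$grid), unclass(g)))) {
      stop("raster layers do not share one grid", call. = FALSE)
    }
  }
  layers <- lapply(parsed, `[[`, "values")
  names(layers) <- sub("\\.[^.]*$", "", basename(files))
  env_stack(g, layers)
}

#' Write every layer of a stack as ASCII grids
#'
#' @param env an [env_stack()].
#' @param dir output directory; one `<layer>.asc` per layer.
#' @return Paths written, invisibly.
#' @export
write_env_stack <- function(env, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(env$layers), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(env$layers[[nm]], env$grid, p)
    p
  }, character(1))
  invisible(paths)
}
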