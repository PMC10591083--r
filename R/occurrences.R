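#' Read a Darwin-Core-style occurrence table
#'
#' Reads the delimited dialect of GBIF occurrence downloads: columns
#' `species` or `scientificName` for the taxon, `decimalLongitude` and
#' `decimalLatitude` for the coordinates; extra columns are ignored.
#' Coordinates are kept as text here so that [clean_occurrences()] can log
#' non-numeric entries as rejections rather than silently coercing them.
#'
#' @param file path to a comma- or tab-delimited file.
#' @return Data frame with `taxon_name`, `lon`, `lat` (character), and
#'   `source_id` when `gbifID` or `occurrenceID` is present.
#' @export
read_occurrences <- function(file) {
  tab <- read_delimited(file)
  lownames <- tolower(names(tab))
  pick <- function(cands) {
    i <- match(tolower(cands), lownames)
    i <- i[!is.na(i)]
    if (length(i)) tab[[i[1]]] else NULL
  }
  name <- pick(c("species", "scientificName"))
  lon <- pick("decimalLongitude")
  lat <- pick("decimalLatitude")
  if (is.null(name) || is.null(lon) || is.null(lat)) {
    stop("occurrence table needs species/scientificName, decimalLongitude, ",
         "decimalLatitude", call. = FALSE)
  }
  out <- data.frame(taxon_name = squeeze_ws(name), lon = lon, lat = lat,
                    stringsAsFactors = FALSE)
  id <- pick(c("gbifID", "occurrenceID"))
  if (!is.null(id)) out$source_id <- id
  out
}

#' Clean occurrence records
#'
#' Drops records with missing or non-numeric coordinates, coordinates
#' outside the valid lon/lat domain, and records outside the study region.
#' Each rejection is logged with its reason.
#'
#' @param records data frame with `lon` and `lat` columns (numeric or
#'   character, e.g. from [read_occurrences()]).
#' @param region a [grid_spec()] or a numeric vector
#'   `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return List with `records` (cleaned, `lon`/`lat` numeric) and
#'   `rejected` (the dropped rows plus a `reason` column: `"missing"`,
#'   `"invalid"`, or `"outside_region"`).
#' @export
clean_occurrences <- function(records, region) {
  if (inherits(region, "grid_spec")) {
    bbox <- c(region$lon_min, region$lon_max, region$lat_min, region$lat_max)
  } else {
    stopifnot(is.numeric(region), length(region) == 4)
    bbox <- region
  }
  lon_raw <- records$lon
  lat_raw <- records$lat
  missing <- is.na(lon_raw) | is.na(lat_raw) |
    (is.character(lon_raw) & !nzchar(trimws(lon_raw))) |
    (is.character(lat_raw) & !nzchar(trimws(lat_raw)))
  lon <- suppressWarnings(as.numeric(lon_raw))
  lat <- suppressWarnings(as.numeric(lat_raw))
  invalid <- !missing & (is.na(lon) | is.na(lat) |
                           lon < -180 | lon > 180 | lat < -90 | lat > 90)
  outside <- !missing & !invalid &
    (lon < bbox[1] | lon > bbox[2] | lat < bbox[3] | lat > bbox[4])
  reason <- rep(NA_character_, nrow(records))
  reason[outside] <- "outside_region"
  reason[invalid] <- "invalid"
  reason[missing] <- "missing"
  keep <- is.na(reason)
  cleaned <- records[keep, , drop = FALSE]
  cleaned$lon <- lon[keep]
  cleaned$lat <- lat[keep]
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rownames(cleaned) <- rownames(rejected) <- NULL
  list(records = cleaned, rejected = rejected)
}

#' Reduce records to one observation per grid cell
#'
#' @param records cleaned occurrence records (numeric `lon`, `lat`).
#' @param grid a [grid_spec()].
#' @return A [cell_set()] of occupied cells; record multiplicity and order
#'   are discarded.
#' @export
dedupe_cells <- function(records, grid) {
  if (!nrow(records)) return(cell_set(NULL))
  cell_set(grid_index(records$lon, records$lat, grid), grid)
}

#' Spatial thinning of occupied cells
#'
#' Retains a subset of cells in which every pair is separated by at least
#' one empty grid cell, the standard mitigation for spatial autocorrelation
#' before niche modelling. Separation is Chebyshev (8-neighbourhood)
#' distance >= 2 by default, so diagonal neighbours conflict; `mode =
#' "rook"` relaxes this to 4-neighbour separation (diagonal neighbours
#' allowed). The scan is greedy in row-major order: a cell is kept iff it
#' conflicts with no already-kept cell, which makes the result
#' deterministic, maximal (no rejected cell could be re-added) and
#' idempotent.
#'
#' @param cells a [cell_set()].
#' @param mode `"chebyshev"` (default) or `"rook"`.
#' @return A [cell_set()], subset of the input.
#' @export
thin_cells <- function(cells, mode = c("chebyshev", "rook")) {
  mode <- match.arg(mode)
  cells <- cell_set(cells)
  n <- nrow(cells)
  if (n <= 1) return(cells)
  # cell_set() is already row-major sorted
  kept <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(n)
  if (mode == "chebyshev") {
    dr <- rep(-1:1, each = 3); dc <- rep(-1:1, times = 3)
  } else {
    dr <- c(0, -1, 1, 0, 0); dc <- c(0, 0, 0, -1, 1)
  }
  for (i in seq_len(n)) {
    r <- cells[i, 1]; cc <- cells[i, 2]
    nb <- paste(r + dr, cc + dc, sep = ":")
    if (!any(vapply(nb, exists, logical(1), envir = kept,
                    inherits = FALSE))) {
      keep[i] <- TRUE
      assign(paste(r, cc, sep = ":"), TRUE, envir = kept)
    }
  }
  cell_set(cells[keep, , drop = FALSE])
}

#' Are there enough cells to model a taxon?
#'
#' Taxa whose thinned occurrence set is too small are excluded from niche
#' modelling ("insufficient records").
#'
#' @param cells a [cell_set()] (after thinning).
#' @param min_cells minimum number of cells required (default 10).
#' @return TRUE iff `nrow(cells) >= min_cells`.
#' @export
is_modellable <- function(cells, min_cells = 10) {
  stopifnot(min_cells >= 1)
  NROW(cells) >= min_cells
}
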