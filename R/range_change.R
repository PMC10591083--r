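#' Range size in grid cells
#'
#' @param cells a [cell_set()] (duplicates removed by construction).
#' @return Number of occupied cells.
#' @export
range_size <- function(cells) nrow(cell_set(cells))

#' Range change assuming full migration
#'
#' Percentage change of range size if the species can occupy every newly
#' suitable cell: `100 * (|future| - |current|) / |current|`, rounded half
#' away from zero to one decimal place.
#'
#' @param current,future [cell_set()]s of suitable cells.
#' @return Percent change (positive = expansion).
#' @export
change_with_migration <- function(current, future) {
  current <- cell_set(current); future <- cell_set(future)
  if (!nrow(current)) stop("current range is empty; change undefined",
                           call. = FALSE)
  round_half_away(100 * (nrow(future) - nrow(current)) / nrow(current), 1)
}

#' Range change assuming no migration
#'
#' If the species cannot disperse, only cells suitable both now and in the
#' future remain occupied: `100 * (|future & current| - |current|) /
#' |current|`, rounded half away from zero to one decimal place. Always in
#' `[-100, 0]` and never above the full-migration change.
#'
#' @param current,future [cell_set()]s of suitable cells.
#' @return Percent change (<= 0).
#' @export
change_no_migration <- function(current, future) {
  current <- cell_set(current); future <- cell_set(future)
  if (!nrow(current)) stop("current range is empty; change undefined",
                           call. = FALSE)
  kept <- nrow(cells_intersect(current, future))
  round_half_away(100 * (kept - nrow(current)) / nrow(current), 1)
}

#' Build the per-taxon range-change table
#'
#' One row per taxon with its current range size (cells) and the percentage
#' change under each scenario and migration assumption; taxa that could not
#' be modelled carry their reason instead.
#'
#' @param projections named list (per taxon). Each element is either
#'   `list(reason = "cultivated" | "outside_study_area" |
#'   "insufficient_records")` or `list(current = cells, future =
#'   list(<scenario> = cells, ...))` with scenarios `"RCP2.6"`,
#'   `"RCP8.5"`.
#' @param scenarios scenario names expected in `future` (default
#'   `c("RCP2.6", "RCP8.5")`).
#' @return Data frame with `taxon`, `current_size`, per-scenario
#'   `change_mig_*` and `change_nomig_*` columns, and `reason`.
#' @export
build_range_table <- function(projections,
                              scenarios = c("RCP2.6", "RCP8.5")) {
  stopifnot(is.list(projections), !is.null(names(projections)))
  scen_id <- gsub("[^0-9A-Za-z]", "", tolower(scenarios))
  rows <- lapply(names(projections), function(tx) {
    p <- projections[[tx]]
    out <- data.frame(taxon = tx, current_size = NA_integer_,
                      stringsAsFactors = FALSE)
    for (id in scen_id) {
      out[[paste0("change_mig_", id)]] <- NA_real_
      out[[paste0("change_nomig_", id)]] <- NA_real_
    }
    out$reason <- NA_character_
    if (!is.null(p$reason)) {
      out$reason <- p$reason
      return(out)
    }
    if (is.null(p$current)) stop("taxon '", tx,
                                 "' has neither projection nor reason",
                                 call. = FALSE)
    cur <- cell_set(p$current)
    out$current_size <- nrow(cur)
    for (i in seq_along(scenarios)) {
      fut <- p$future[[scenarios[i]]]
      if (is.null(fut)) next
      out[[paste0("change_mig_", scen_id[i])]] <-
        change_with_migration(cur, fut)
      out[[paste0("change_nomig_", scen_id[i])]] <-
        change_no_migration(cur, fut)
    }
    out
  })
  do.call(rbind, rows)
}
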