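fixture_path <- function(file, check = TRUE) {
  path <- system.file("extdata", file, package = "cwrgap")
  if (!nzchar(path)) stop("fixture not found: ", file, call. = FALSE)
  if (check) {
    sums <- utils::read.delim(system.file("extdata", "fixture_checksums.tsv",
                                          package = "cwrgap"),
                              stringsAsFactors = FALSE)
    want <- sums$md5[sums$file == file]
    got <- unname(tools::md5sum(path))
    if (length(want) == 1 && !identical(got, want)) {
      stop("fixture ", file, " fails its checksum", call. = FALSE)
    }
  }
  path
}

#' Published rapeseed gene-pool inventory
#'
#' The gene-pool inventory of rapeseed (*Brassica napus*) shipped with the
#' package: 51 taxa in 16 genera with gene-pool tier, cultivation status,
#' accession counts in European genebank collections, countries of native
#' occurrence, native-collected counts and IUCN Red List category. The
#' file's checksum is verified on every load.
#'
#' @return `gene_pool_inventory()`: the inventory as a data frame (counts
#'   numeric, countries "|"-separated). `gene_pool_registry()`: the same
#'   inventory loaded as a `cwr_registry` via [load_registry()].
#' @export
gene_pool_inventory <- function() {
  tab <- read_delimited(fixture_path("gene_pool_inventory.tsv"))
  tab$accessions <- as.numeric(tab$accessions)
  tab$native_collected <- as.numeric(tab$native_collected)
  tab
}

#' @rdname gene_pool_inventory
#' @export
gene_pool_registry <- function() {
  load_registry(fixture_path("gene_pool_inventory.tsv"))
}

#' Published range-change projections
#'
#' The per-taxon niche-modelling results shipped with the package: current
#' range size (2.5-arc-minute cells) and percentage range change by 2070
#' under the optimistic (RCP 2.6) and pessimistic (RCP 8.5) scenarios,
#' with and without migration; taxa that were not modelled carry a reason
#' (`cultivated`, `outside_study_area`, `insufficient_records`). These are
#' results of the original large-scale analysis (GBIF occurrences,
#' WorldClim and soil layers) and are packaged as a fixture -- they are not
#' recomputable at package scale.
#'
#' @return Data frame with `taxon`, `tier`, `current_size`,
#'   `change_mig_rcp26`, `change_mig_rcp85`, `change_nomig_rcp26`,
#'   `change_nomig_rcp85`, `reason`, `reason_detail`.
#' @export
range_change_published <- function() {
  tab <- read_delimited(fixture_path("range_change_published.tsv"))
  for (col in c("current_size", "change_mig_rcp26", "change_mig_rcp85",
                "change_nomig_rcp26", "change_nomig_rcp85")) {
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  tab$reason[!is.na(tab$reason) & !nzchar(tab$reason)] <- NA_character_
  tab
}

#' Published collecting-priority list
#'
#' The published priority assignments (38 wild taxa: 18 high, 17 medium,
#' 3 low) used as the regression fixture for [build_priority_table()] with
#' the default [rule_config()].
#'
#' @return Data frame with `taxon`, `priority`.
#' @export
priority_published <- function() {
  read_delimited(fixture_path("priority_published.tsv"))
}
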