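#' Parse an MCPD-style passport file
#'
#' Reads a genebank passport table in the Multi-Crop Passport Descriptor
#' column vocabulary (the EURISCO exchange dialect): comma- or tab-delimited
#' UTF-8 text whose header uses MCPD names (`ACCENUMB`, `INSTCODE`, `GENUS`,
#' `SPECIES`, `SPAUTHOR`, `SUBTAXA`, `ORIGCTY`, `COLLSRC`, `SAMPSTAT`).
#' Unknown columns are ignored. Rows with an unparseable origin country are
#' kept with `origcty = NA` and a warning; duplicated `(instcode, accenumb)`
#' pairs are an error.
#'
#' @param file path to the passport table.
#' @return Data frame with lower-case columns `accenumb`, `instcode`,
#'   `genus`, `species`, `spauthor`, `subtaxa`, `origcty` (alpha-3 or NA),
#'   `collsrc`, `sampstat` (integer or NA).
#' @export
parse_passport <- function(file) {
  tab <- read_delimited(file)
  names(tab) <- tolower(names(tab))
  if (!"accenumb" %in% names(tab)) {
    stop("not an MCPD table: required column ACCENUMB is missing",
         call. = FALSE)
  }
  n <- nrow(tab)
  pick <- function(col) {
    if (col %in% names(tab)) {
      v <- trimws(tab[[col]])
      v[!nzchar(v)] <- NA_character_
      v
    } else rep(NA_character_, n)
  }
  rec <- data.frame(accenumb = pick("accenumb"), instcode = pick("instcode"),
                    genus = pick("genus"), species = pick("species"),
                    spauthor = pick("spauthor"), subtaxa = pick("subtaxa"),
                    origcty = pick("origcty"), stringsAsFactors = FALSE)
  rec$collsrc <- suppressWarnings(as.integer(pick("collsrc")))
  rec$sampstat <- suppressWarnings(as.integer(pick("sampstat")))
  if (any(is.na(rec$accenumb))) {
    stop("passport rows with empty ACCENUMB", call. = FALSE)
  }
  key <- paste(rec$instcode, rec$accenumb, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate accession identifier(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  bad_cty <- !is.na(rec$origcty) & !grepl("^[A-Za-z]{3}$", rec$origcty)
  if (any(bad_cty)) {
    warning(sum(bad_cty), " record(s) with unparseable ORIGCTY kept with ",
            "unknown origin", call. = FALSE)
    rec$origcty[bad_cty] <- NA_character_
  }
  rec$origcty <- toupper(rec$origcty)
  rec
}

# "Genus species [authority]" label for registry matching
passport_label <- function(records, with_subtaxa = FALSE) {
  lab <- trimws(paste(ifelse(is.na(records$genus), "", records$genus),
                      ifelse(is.na(records$species), "", records$species),
                      ifelse(is.na(records$spauthor), "", records$spauthor)))
  if (with_subtaxa) {
    sub <- !is.na(records$subtaxa) & nzchar(records$subtaxa)
    lab[sub] <- trimws(paste(lab[sub], records$subtaxa[sub]))
  }
  squeeze_ws(lab)
}

resolve_labels <- function(labels, registry) {
  u <- unique(labels)
  canon <- vapply(u, function(l) as.character(resolve_name(l, registry)),
                  character(1))
  canon[match(labels, u)]
}

# subtaxon text is ignored (it folds records into their species) except
# where the registry itself lists the trinomial, which is tried first
resolve_records <- function(records, registry) {
  canon <- resolve_labels(passport_label(records, with_subtaxa = TRUE),
                          registry)
  miss <- is.na(canon)
  if (any(miss)) {
    canon[miss] <- resolve_labels(passport_label(records[miss, , drop = FALSE]),
                                  registry)
  }
  canon
}

#' Count accessions per registry taxon
#'
#' Assembles a taxon label from `GENUS` + `SPECIES` (+ authority, + subtaxon
#' text where present) for each record, resolves it through the registry
#' (synonyms fold into canonical names, authority-stripped fallback
#' allowed) and tallies records per canonical name. Records whose label
#' does not resolve are excluded from the counts and reported in the
#' `"unmatched"` attribute.
#'
#' @param records data frame from [parse_passport()].
#' @param registry a `cwr_registry`.
#' @return Named integer vector over all registry taxa (zero where absent),
#'   with attribute `unmatched`: a data frame of unresolved labels and
#'   their record counts.
#' @export
accession_counts <- function(records, registry) {
  canon_all <- registry$taxa$canonical_name
  out <- stats::setNames(integer(length(canon_all)), canon_all)
  if (nrow(records)) {
    labels <- passport_label(records, with_subtaxa = TRUE)
    canon <- resolve_records(records, registry)
    tab <- table(canon[!is.na(canon)])
    out[names(tab)] <- out[names(tab)] + as.integer(tab)
    un <- table(labels[is.na(canon)])
    attr(out, "unmatched") <- data.frame(label = names(un),
                                         n = as.integer(un),
                                         stringsAsFactors = FALSE)
  } else {
    attr(out, "unmatched") <- data.frame(label = character(0), n = integer(0))
  }
  out
}

#' Is a record "collected material"?
#'
#' MCPD does not force a single field for acquisition provenance, and
#' EURISCO records populate `COLLSRC` and `SAMPSTAT` inconsistently. The
#' default rule: a record qualifies when `COLLSRC` is a collecting/wild
#' source (codes 10-19); when `COLLSRC` is absent, `SAMPSTAT` in the wild
#' range (100-199) qualifies. Both code sets are configurable.
#'
#' @param records data frame from [parse_passport()].
#' @param collsrc_codes integer codes of qualifying collecting sources.
#' @param sampstat_codes integer codes of qualifying biological statuses.
#' @return Logical vector.
#' @export
is_collected <- function(records, collsrc_codes = 10:19,
                         sampstat_codes = 100:199) {
  has_src <- !is.na(records$collsrc)
  (has_src & records$collsrc %in% collsrc_codes) |
    (!has_src & !is.na(records$sampstat) &
       records$sampstat %in% sampstat_codes)
}

#' Per-taxon representation statistics
#'
#' For every registry taxon: the total number of accessions, and the number
#' collected in the taxon's native-range countries ("native-collected"),
#' i.e. records whose origin country is in the native range *and* whose
#' status qualifies under [is_collected()]. Records with unknown origin
#' count toward totals but never toward native-collected.
#'
#' @param records data frame from [parse_passport()].
#' @param registry a `cwr_registry`.
#' @param collsrc_codes,sampstat_codes passed to [is_collected()].
#' @return Data frame of class `taxon_stats` with columns `canonical_name`,
#'   `tier`, `total_accessions`, `native_collected`, and attribute
#'   `per_country`: a named list (per taxon) of named integer vectors of
#'   collected counts per native country.
#' @export
native_collected_counts <- function(records, registry,
                                    collsrc_codes = 10:19,
                                    sampstat_codes = 100:199) {
  canon_all <- registry$taxa$canonical_name
  totals <- accession_counts(records, registry)
  natcol <- stats::setNames(integer(length(canon_all)), canon_all)
  per_country <- stats::setNames(vector("list", length(canon_all)), canon_all)
  for (i in seq_along(canon_all)) {
    nat <- registry$native[[canon_all[i]]]
    per_country[[i]] <- stats::setNames(integer(length(nat)), nat)
  }
  if (nrow(records)) {
    canon <- resolve_records(records, registry)
    coll <- is_collected(records, collsrc_codes, sampstat_codes)
    sel <- !is.na(canon) & coll & !is.na(records$origcty)
    if (any(sel)) {
      df <- data.frame(canon = canon[sel], cty = records$origcty[sel])
      for (tx in unique(df$canon)) {
        nat <- registry$native[[tx]]
        cts <- table(df$cty[df$canon == tx & df$cty %in% nat])
        per_country[[tx]][names(cts)] <- per_country[[tx]][names(cts)] +
          as.integer(cts)
        natcol[tx] <- sum(per_country[[tx]])
      }
    }
  }
  out <- data.frame(canonical_name = canon_all,
                    tier = registry$taxa$tier,
                    total_accessions = as.integer(totals),
                    native_collected = as.integer(natcol),
                    stringsAsFactors = FALSE)
  attr(out, "per_country") <- per_country
  attr(out, "unmatched") <- attr(totals, "unmatched")
  class(out) <- c("taxon_stats", class(out))
  out
}

#' Native-range countries with no collected accession
#'
#' The per-country gap of the analysis: countries in a taxon's native
#' distribution range from which no qualifying accession was collected.
#'
#' @param stats a `taxon_stats` data frame (from
#'   [native_collected_counts()]), or a named integer vector of per-country
#'   collected counts for one taxon.
#' @param registry a `cwr_registry`.
#' @param taxon canonical name (required when `stats` covers several taxa).
#' @return Character vector of alpha-3 codes.
#' @export
country_gaps <- function(stats, registry, taxon = NULL) {
  if (is.numeric(stats) && !is.null(names(stats))) {
    stopifnot(!is.null(taxon))
    per <- stats
  } else {
    pc <- attr(stats, "per_country")
    if (is.null(pc)) stop("stats carry no per-country counts", call. = FALSE)
    if (is.null(taxon)) {
      if (nrow(stats) != 1) stop("give `taxon` for multi-taxon stats",
                                 call. = FALSE)
      taxon <- stats$canonical_name
    }
    per <- pc[[taxon]]
  }
  nat <- native_countries(taxon, registry)
  sort(setdiff(nat, names(per)[per > 0]))
}

#' Gene-pool level summary
#'
#' Aggregates per-taxon statistics into the inventory summary: accession
#' totals per gene-pool tier, the grand total, the native-collected total,
#' and for each count threshold `t` the percentage (rounded to the nearest
#' integer, half away from zero) of tertiary-pool taxa held in fewer than
#' `t` accessions.
#'
#' @param stats data frame with `canonical_name`, `total_accessions`,
#'   `native_collected` (a `taxon_stats`, or fixture columns). Registry
#'   taxa absent from `stats` count as zero.
#' @param registry a `cwr_registry`.
#' @param thresholds integer vector of under-representation thresholds.
#' @return List of class `gene_pool_summary`: `totals_by_tier`,
#'   `grand_total`, `native_collected_total`, `tertiary_fraction_below`
#'   (named integer percentages), `n_taxa`, `n_genera`, and `per_taxon`
#'   (the completed stats with a `native_share_pct` column).
#' @export
summarize_gene_pool <- function(stats, registry, thresholds = c(10, 20)) {
  canon_all <- registry$taxa$canonical_name
  idx <- match(canon_all, stats$canonical_name)
  total <- ifelse(is.na(idx), 0, stats$total_accessions[idx])
  natcol <- ifelse(is.na(idx), 0, stats$native_collected[idx])
  total[is.na(total)] <- 0
  natcol[is.na(natcol)] <- 0
  stopifnot(all(natcol <= total))
  tier <- registry$taxa$tier
  totals_by_tier <- vapply(c("primary", "secondary", "tertiary"),
                           function(tr) sum(total[tier == tr]), numeric(1))
  tert <- total[tier == "tertiary"]
  frac <- vapply(thresholds, function(t) {
    if (!length(tert)) return(100)
    as.numeric(round_half_away(100 * mean(tert < t)))
  }, numeric(1))
  share <- ifelse(total > 0, round_half_away(100 * natcol / total), NA)
  per_taxon <- data.frame(canonical_name = canon_all, tier = tier,
                          total_accessions = total,
                          native_collected = natcol,
                          native_share_pct = share,
                          stringsAsFactors = FALSE)
  out <- list(totals_by_tier = totals_by_tier,
              grand_total = sum(total),
              native_collected_total = sum(natcol),
              tertiary_fraction_below = stats::setNames(frac,
                paste0("<", thresholds)),
              n_taxa = length(canon_all),
              n_genera = length(unique(registry$taxa$genus)),
              per_taxon = per_taxon)
  class(out) <- "gene_pool_summary"
  out
}

#' @export
print.gene_pool_summary <- function(x, ...) {
  cat(sprintf("Gene pool: %d taxa, %d genera\n", x$n_taxa, x$n_genera))
  cat(sprintf("Accessions: %s total (%s primary / %s secondary / %s tertiary)\n",
              format(x$grand_total, big.mark = ","),
              format(x$totals_by_tier[["primary"]], big.mark = ","),
              format(x$totals_by_tier[["secondary"]], big.mark = ","),
              format(x$totals_by_tier[["tertiary"]], big.mark = ",")))
  cat(sprintf("Native-collected: %s\n",
              format(x$native_collected_total, big.mark = ",")))
  for (nm in names(x$tertiary_fraction_below)) {
    cat(sprintf("Tertiary taxa with %s accessions: %d%%\n", nm,
                as.integer(x$tertiary_fraction_below[[nm]])))
  }
  invisible(x)
}

#' Write the gap report
#'
#' Per-taxon statistics as tab-delimited text plus a machine-readable
#' key-value summary (YAML).
#'
#' @param summary a `gene_pool_summary`.
#' @param dir output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_gap_report <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab_path <- file.path(dir, "taxon_stats.tsv")
  utils::write.table(summary$per_taxon, tab_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  sum_path <- file.path(dir, "gene_pool_summary.yml")
  yaml::write_yaml(list(
    n_taxa = summary$n_taxa, n_genera = summary$n_genera,
    grand_total = summary$grand_total,
    totals_by_tier = as.list(summary$totals_by_tier),
    native_collected_total = summary$native_collected_total,
    tertiary_fraction_below = as.list(summary$tertiary_fraction_below)
  ), sum_path)
  invisible(c(tab_path, sum_path))
}
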