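#' Collecting-priority rule configuration
#'
#' Thresholds of the rule-based classifier that turns Red List status,
#' native-collected accession counts and projected range loss (pessimistic
#' scenario, no migration) into a collecting priority. The defaults
#' reproduce the published rapeseed priority list; every threshold is
#' configurable and each assignment reports the rule that fired, so the
#' classification is auditable.
#'
#' @param redlist_high Red List categories forcing high priority
#'   (default EN, NT).
#' @param acc_floor_high native-collected count at or below which a taxon
#'   is high priority regardless of modelling (default 2).
#' @param loss_high magnitude (percentage points) of projected no-migration
#'   range loss that triggers high priority (default 60).
#' @param acc_cap_for_loss_rule the loss rule only fires for taxa with
#'   fewer than this many native-collected accessions (default 50).
#' @param acc_low native-collected count at or above which a taxon is low
#'   priority (default 100).
#' @param exclusions taxa excluded by name, on top of the structural
#'   exclusions (cultivated / partly cultivated / outside the study area).
#'   The default excludes *Sinapis alba* L. and *Raphanus raphanistrum* L.,
#'   the two wild taxa absent from the published priority list.
#' @return List of class `rule_config`.
#' @export
rule_config <- function(redlist_high = c("EN", "NT"),
                        acc_floor_high = 2,
                        loss_high = 60,
                        acc_cap_for_loss_rule = 50,
                        acc_low = 100,
                        exclusions = c("Sinapis alba L.",
                                       "Raphanus raphanistrum L.")) {
  stopifnot(acc_floor_high < acc_cap_for_loss_rule,
            acc_cap_for_loss_rule < acc_low, loss_high >= 0)
  structure(list(redlist_high = redlist_high,
                 acc_floor_high = acc_floor_high,
                 loss_high = loss_high,
                 acc_cap_for_loss_rule = acc_cap_for_loss_rule,
                 acc_low = acc_low,
                 exclusions = exclusions),
            class = "rule_config")
}

#' Assign a collecting priority to one taxon
#'
#' Decision order (first rule that applies wins):
#' 1. `excluded` -- cultivated or partly cultivated, listed in
#'    `rules$exclusions`, or carrying an exclusion reason (e.g. outside the
#'    study area);
#' 2. `high` -- Red List category in `rules$redlist_high`;
#' 3. `high` -- `native_collected <= rules$acc_floor_high`;
#' 4. `high` -- projected loss present, `|loss| >= rules$loss_high`, and
#'    `native_collected < rules$acc_cap_for_loss_rule`;
#' 5. `low`  -- `native_collected >= rules$acc_low`;
#' 6. `medium` otherwise.
#'
#' @param taxon canonical name.
#' @param redlist Red List category (`EN`, `NT`, `LC`, `DD`, `NOT_LISTED`).
#' @param cultivation `wild`, `cultivated`, or `partly_cultivated`.
#' @param native_collected count of native-collected accessions.
#' @param loss_rcp85_nomig projected no-migration range change under the
#'   pessimistic scenario, in percent (negative = loss); `NA` if the taxon
#'   was not modelled.
#' @param excluded_reason optional exclusion tag (e.g.
#'   `"outside_study_area"`).
#' @param rules a [rule_config()].
#' @return List with `taxon`, `category` (`high`/`medium`/`low`/
#'   `excluded`), `rule_fired`.
#' @export
assign_priority <- function(taxon, redlist = "NOT_LISTED",
                            cultivation = "wild",
                            native_collected = 0,
                            loss_rcp85_nomig = NA_real_,
                            excluded_reason = NULL,
                            rules = rule_config()) {
  res <- function(category, rule) list(taxon = taxon, category = category,
                                       rule_fired = rule)
  if (cultivation %in% c("cultivated", "partly_cultivated")) {
    return(res("excluded", cultivation))
  }
  if (taxon %in% rules$exclusions) return(res("excluded", "listed_exclusion"))
  if (!is.null(excluded_reason) && !is.na(excluded_reason)) {
    return(res("excluded", excluded_reason))
  }
  if (redlist %in% rules$redlist_high) return(res("high", "redlist"))
  if (native_collected <= rules$acc_floor_high) {
    return(res("high", "few_native_collected"))
  }
  if (!is.na(loss_rcp85_nomig) &&
      abs(loss_rcp85_nomig) >= rules$loss_high &&
      native_collected < rules$acc_cap_for_loss_rule) {
    return(res("high", "projected_loss"))
  }
  if (native_collected >= rules$acc_low) {
    return(res("low", "well_collected"))
  }
  res("medium", "default")
}

#' Priority assignments for a whole registry
#'
#' Applies [assign_priority()] to every registry taxon, pulling
#' native-collected counts from `stats` (taxa missing there count 0, with
#' a warning) and the pessimistic no-migration range change from
#' `range_table`. Taxa whose range-table reason is `outside_study_area`
#' are excluded; `insufficient_records` taxa stay in and are classified
#' without a loss value.
#'
#' @param registry a `cwr_registry`.
#' @param stats data frame with `canonical_name` and `native_collected`.
#' @param range_table data frame from [build_range_table()] (needs `taxon`,
#'   `change_nomig_rcp85`, `reason`), or NULL if no modelling was done.
#' @param rules a [rule_config()].
#' @return Data frame with `taxon`, `category`, `rule_fired`; attribute
#'   `counts` tabulates the categories.
#' @export
build_priority_table <- function(registry, stats, range_table = NULL,
                                 rules = rule_config()) {
  canon <- registry$taxa$canonical_name
  idx <- match(canon, stats$canonical_name)
  if (any(is.na(idx))) {
    warning("taxa missing from stats treated as native_collected = 0: ",
            paste(canon[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  natcol <- ifelse(is.na(idx), 0, stats$native_collected[idx])
  loss <- rep(NA_real_, length(canon))
  reason <- rep(NA_character_, length(canon))
  if (!is.null(range_table)) {
    ridx <- match(canon, range_table$taxon)
    loss <- range_table$change_nomig_rcp85[ridx]
    reason <- range_table$reason[ridx]
  }
  # only the outside-study-area tag excludes; cultivation is already a
  # field, and insufficient-record taxa are still prioritised
  reason[!is.na(reason) & reason != "outside_study_area"] <- NA_character_
  note <- registry$taxa$modellable_note
  reason[is.na(reason) & note == "outside_study_area"] <- "outside_study_area"
  rows <- lapply(seq_along(canon), function(i) {
    a <- assign_priority(canon[i], redlist = registry$taxa$redlist[i],
                         cultivation = registry$taxa$cultivation[i],
                         native_collected = natcol[i],
                         loss_rcp85_nomig = loss[i],
                         excluded_reason = reason[i], rules = rules)
    data.frame(taxon = a$taxon, category = a$category,
               rule_fired = a$rule_fired, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "counts") <- table(factor(out$category,
                                      c("high", "medium", "low", "excluded")))
  out
}
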