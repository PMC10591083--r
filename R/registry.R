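#' Country-name to ISO 3166-1 alpha-3 lookup
#'
#' Bundled English-name lookup (including common historical and variant
#' names, e.g. "Syria" -> SYR, "Czechia" -> CZE) used when registry sources
#' give countries as names rather than codes. Alpha-3 codes pass through
#' unchanged. All statistics in the package use alpha-3 internally, the
#' MCPD ORIGCTY convention.
#'
#' @param names character vector of country names or alpha-3 codes.
#' @return Character vector of alpha-3 codes, `NA` where unresolved.
#' @export
country_to_alpha3 <- function(names) {
  lut <- country_code_table()
  x <- trimws(names)
  out <- rep(NA_character_, length(x))
  is_code <- grepl("^[A-Za-z]{3}$", x) & toupper(x) %in% lut$alpha3
  out[is_code] <- toupper(x[is_code])
  idx <- match(tolower(x[!is_code]), tolower(lut$name))
  out[!is_code] <- lut$alpha3[idx]
  out
}

country_code_table <- function() {
  path <- system.file("extdata", "country_codes.tsv", package = "cwrgap")
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
}

split_multi <- function(x) {
  lapply(as.character(x), function(v) {
    if (is.na(v) || !nzchar(trimws(v))) return(character(0))
    trimws(strsplit(v, "|", fixed = TRUE)[[1]])
  })
}

squeeze_ws <- function(x) gsub("[[:space:]]+", " ", trimws(x))

#' Strip the author citation from a botanical name
#'
#' Keeps the genus and specific epithet and, when present, an infraspecific
#' marker (`subsp.`, `var.`, `subvar.`, `f.`) with its epithet; authority
#' strings are dropped. Used for the fallback match when passport or
#' occurrence data omit authorities.
#'
#' @param name character vector of taxon names.
#' @return Character vector of authority-free names.
#' @export
strip_authority <- function(name) {
  vapply(squeeze_ws(name), function(n) {
    toks <- strsplit(n, " ", fixed = TRUE)[[1]]
    if (length(toks) < 2) return(n)
    keep <- toks[1:2]
    markers <- c("subsp.", "ssp.", "var.", "subvar.", "f.")
    i <- which(tolower(toks) %in% markers)
    i <- i[i > 2 & i < length(toks)]
    if (length(i)) {
      i <- i[1]
      keep <- c(keep, toks[i], toks[i + 1])
    }
    paste(keep, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Load a gene-pool registry
#'
#' Reads the inventory of a crop's gene pool: one row per taxon with its
#' gene-pool tier (Harlan & de Wet primary/secondary/tertiary), cultivation
#' status, countries of native occurrence, IUCN Red List category and known
#' synonyms. Builds a name index so that any canonical name or synonym
#' resolves to its canonical name.
#'
#' @param source path to a comma- or tab-delimited UTF-8 table with a header
#'   row, or a data frame. Recognised columns (case-insensitive):
#'   `taxon` (or `canonical_name`), `tier`, `cultivation`, `redlist`,
#'   `native_countries` ("|"-separated names or alpha-3 codes),
#'   `synonyms` ("|"-separated), and optional `genus`, `note`,
#'   `accessions`, `native_collected` (carried through untouched).
#' @return An object of class `cwr_registry`: list with `taxa` (data frame),
#'   `native` (named list of alpha-3 sets), `synonyms` (named list),
#'   `name_index` (named character). Unresolvable country names are reported
#'   via a warning and stored in `attr(, "unresolved_countries")`.
#' @export
load_registry <- function(source) {
  tab <- if (is.data.frame(source)) source else read_delimited(source)
  names(tab) <- tolower(names(tab))
  if (!nrow(tab)) stop("registry source has no rows", call. = FALSE)
  if (!"taxon" %in% names(tab) && "canonical_name" %in% names(tab)) {
    tab$taxon <- tab$canonical_name
  }
  req <- c("taxon", "tier")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("registry source lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  canon <- squeeze_ws(tab$taxon)
  if (any(!nzchar(canon))) stop("empty canonical name in registry", call. = FALSE)
  dup <- canon[duplicated(canon)]
  if (length(dup)) stop("duplicate canonical name(s): ",
                        paste(unique(dup), collapse = ", "), call. = FALSE)

  tier <- tolower(trimws(tab$tier))
  stopifnot(all(tier %in% c("primary", "secondary", "tertiary")))
  cultivation <- if ("cultivation" %in% names(tab)) {
    tolower(trimws(tab$cultivation))
  } else rep("wild", nrow(tab))
  stopifnot(all(cultivation %in% c("wild", "cultivated", "partly_cultivated")))
  redlist <- if ("redlist" %in% names(tab)) toupper(trimws(tab$redlist)) else
    rep("NOT_LISTED", nrow(tab))
  redlist[!nzchar(redlist) | is.na(redlist)] <- "NOT_LISTED"
  stopifnot(all(redlist %in% c("EN", "NT", "LC", "DD", "NOT_LISTED")))
  genus <- if ("genus" %in% names(tab)) trimws(tab$genus) else
    vapply(strsplit(canon, " "), `[`, character(1), 1)
  note <- if ("note" %in% names(tab)) trimws(tab$note) else rep("ok", nrow(tab))
  note[!nzchar(note) | is.na(note)] <- "ok"
  stopifnot(all(note %in% c("ok", "outside_study_area",
                            "insufficient_records", "cultivated")))

  unresolved <- character(0)
  native <- lapply(split_multi(if ("native_countries" %in% names(tab))
    tab$native_countries else rep("", nrow(tab))), function(v) {
      codes <- country_to_alpha3(v)
      unresolved <<- c(unresolved, v[is.na(codes)])
      sort(unique(codes[!is.na(codes)]))
    })
  names(native) <- canon
  if (length(unresolved)) {
    warning("unresolved country name(s): ",
            paste(unique(unresolved), collapse = ", "), call. = FALSE)
  }

  synonyms <- split_multi(if ("synonyms" %in% names(tab)) tab$synonyms else
    rep("", nrow(tab)))
  synonyms <- lapply(synonyms, squeeze_ws)
  names(synonyms) <- canon
  for (i in seq_along(synonyms)) {
    synonyms[[i]] <- setdiff(synonyms[[i]], canon[i])
  }

  idx_names <- c(canon, unlist(synonyms, use.names = FALSE))
  idx_target <- c(canon, rep(canon, lengths(synonyms)))
  coll <- tapply(idx_target, idx_names, function(v) length(unique(v)))
  if (any(coll > 1)) {
    stop("name(s) mapping to more than one canonical name: ",
         paste(names(coll)[coll > 1], collapse = ", "), call. = FALSE)
  }
  keep <- !duplicated(idx_names)
  name_index <- stats::setNames(idx_target[keep], idx_names[keep])

  taxa <- data.frame(canonical_name = canon, genus = genus, tier = tier,
                     cultivation = cultivation, redlist = redlist,
                     modellable_note = note, stringsAsFactors = FALSE)
  for (extra in intersect(c("accessions", "native_collected"), names(tab))) {
    taxa[[extra]] <- as.numeric(gsub(",", "", tab[[extra]]))
  }
  reg <- list(taxa = taxa, native = native, synonyms = synonyms,
              name_index = name_index)
  class(reg) <- "cwr_registry"
  attr(reg, "unresolved_countries") <- unique(unresolved)
  reg
}

#' @export
print.cwr_registry <- function(x, ...) {
  cat(sprintf("cwr_registry: %d taxa in %d genera\n",
              nrow(x$taxa), length(unique(x$taxa$genus))))
  print(table(tier = x$taxa$tier))
  invisible(x)
}

#' Write a registry back to delimited text
#'
#' Inverse of [load_registry()]: reloading the written file yields an equal
#' registry (alpha-3 codes are written, so name-form differences are
#' normalised away).
#'
#' @param registry a `cwr_registry`.
#' @param path output file; tab-delimited.
#' @export
write_registry <- function(registry, path) {
  tab <- registry$taxa
  names(tab)[names(tab) == "canonical_name"] <- "taxon"
  names(tab)[names(tab) == "modellable_note"] <- "note"
  tab$native_countries <- vapply(registry$native[tab$taxon], paste,
                                 character(1), collapse = "|")
  tab$synonyms <- vapply(registry$synonyms[tab$taxon], paste,
                         character(1), collapse = "|")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Resolve a taxon name against the registry
#'
#' Exact match (after whitespace normalisation) on canonical names and
#' synonyms; if that fails and `fallback = TRUE`, an authority-stripped
#' match is attempted and flagged via the `"matched_by"` attribute.
#'
#' @param name a single taxon name.
#' @param registry a `cwr_registry`.
#' @param fallback allow the authority-stripped fallback (default TRUE).
#' @return The canonical name, or `NA_character_` if unmatched. The
#'   attribute `matched_by` is one of `"exact"`, `"stripped"`, `"none"`.
#' @examples
#' reg <- load_registry(system.file("extdata", "gene_pool_inventory.tsv",
#'                                  package = "cwrgap"))
#' resolve_name("Sinapis incana L.", reg)
#' @export
resolve_name <- function(name, registry, fallback = TRUE) {
  stopifnot(inherits(registry, "cwr_registry"), length(name) == 1)
  n <- squeeze_ws(name)
  hit <- registry$name_index[n]
  if (!is.na(hit)) return(structure(unname(hit), matched_by = "exact"))
  if (fallback) {
    sidx <- stripped_index(registry)
    hit <- sidx[tolower(strip_authority(n))]
    if (!is.na(hit)) return(structure(unname(hit), matched_by = "stripped"))
  }
  structure(NA_character_, matched_by = "none")
}

# authority-stripped index; ambiguous stripped forms are omitted so they
# can never silently resolve to the wrong taxon
stripped_index <- function(registry) {
  nm <- names(registry$name_index)
  stripped <- tolower(strip_authority(nm))
  tgt <- unname(registry$name_index)
  amb <- tapply(tgt, stripped, function(v) length(unique(v)))
  ok <- stripped %in% names(amb)[amb == 1]
  keep <- ok & !duplicated(stripped)
  stats::setNames(tgt[keep], stripped[keep])
}

#' Native-range countries of a taxon
#'
#' @param name canonical name or synonym.
#' @param registry a `cwr_registry`.
#' @return Character vector of alpha-3 codes (empty for cultivated-only
#'   taxa). Unresolved names are an error.
#' @export
native_countries <- function(name, registry) {
  canon <- resolve_name(name, registry)
  if (is.na(canon)) stop("name not in registry: ", name, call. = FALSE)
  registry$native[[canon]]
}
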