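write_mcpd <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("MCPD parsing keeps rows, flags bad origins, rejects bad files", {
  p <- write_mcpd(c("ACCENUMB\tINSTCODE\tGENUS\tSPECIES\tORIGCTY",
                    "A1\tI1\tBrassica\tcretica\tGRC",
                    "A2\tI1\tBrassica\tcretica\t"))
  rec <- parse_passport(p)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$origcty, c("GRC", NA))

  bad <- write_mcpd(c("ACCENUMB\tORIGCTY", "A1\tNowhere"))
  expect_warning(rec2 <- parse_passport(bad), "unparseable ORIGCTY")
  expect_true(is.na(rec2$origcty))

  noacc <- write_mcpd(c("INSTCODE\tGENUS", "I1\tBrassica"))
  expect_error(parse_passport(noacc), "ACCENUMB")

  dup <- write_mcpd(c("ACCENUMB\tINSTCODE", "A1\tI1", "A1\tI1"))
  expect_error(parse_passport(dup), "duplicate accession")
})

test_that("synthetic passport files are recovered exactly", {
  reg <- tiny_registry()
  # per-taxon / per-country / per-status ground truth
  spec <- data.frame(
    taxon = c("Brassica cretica Lam.", "Brassica cretica Lam.",
              "Brassica cretica Lam.", "Sinapis incana L.",
              "Hirschfeldia incana (L.) Lagr.-Foss.", "Synthetica culta"),
    origcty = c("GRC", "TUR", "DEU", "FRA", "ESP", NA),
    collected = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    n = c(5, 3, 2, 4, 1, 7), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  make_passport_file(spec, path, seed = 42)
  rec <- parse_passport(path)
  expect_equal(nrow(rec), sum(spec$n))

  counts <- accession_counts(rec, reg)
  expect_equal(unname(counts["Brassica cretica Lam."]), 10L)
  # synonym-labelled rows fold into the canonical taxon
  expect_equal(unname(counts["Hirschfeldia incana (L.) Lagr.-Foss."]), 5L)
  expect_equal(unname(counts["Synthetica culta"]), 7L)
  expect_equal(nrow(attr(counts, "unmatched")), 0)

  stats <- native_collected_counts(rec, reg)
  cre <- stats[stats$canonical_name == "Brassica cretica Lam.", ]
  # GRC collected (5) counts; TUR native but not collected; DEU collected
  # but outside the native range
  expect_equal(cre$total_accessions, 10L)
  expect_equal(cre$native_collected, 5L)
  pc <- attr(stats, "per_country")[["Brassica cretica Lam."]]
  expect_equal(pc[["GRC"]], 5L)
  expect_equal(pc[["TUR"]], 0L)
  hir <- stats[stats$canonical_name ==
                 "Hirschfeldia incana (L.) Lagr.-Foss.", ]
  expect_equal(hir$native_collected, 4L)  # ESP row is not collected status
})

test_that("collected-material status uses COLLSRC then SAMPSTAT", {
  rec <- data.frame(collsrc = c(10L, 19L, 40L, NA, NA, NA),
                    sampstat = c(300L, NA, 100L, 150L, 300L, NA))
  expect_equal(is_collected(rec), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  # configurable code sets
  expect_equal(is_collected(rec, collsrc_codes = 40L),
               c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("country gaps are native countries without collected material", {
  reg <- gene_pool_registry()
  gap_count <- function(taxon, collected_in) {
    nat <- native_countries(taxon, reg)
    per <- stats::setNames(integer(length(nat)), nat)
    per[collected_in] <- 1L
    length(country_gaps(per, reg, taxon))
  }
  # collections in 3 of 17 native countries leave 14 gap countries
  expect_equal(gap_count("Brassica elongata Ehrh.",
                         c("ESP", "TUR", "UKR")), 14)
  # collections in 6 of 38 native countries leave 32
  expect_equal(gap_count("Descurainia sophia (L.) Webb ex Prantl",
                         c("ESP", "ITA", "GRC", "TUR", "FRA", "PRT")), 32)
  # zero collections: the gap set is the full native set
  expect_equal(gap_count("Brassica elongata Ehrh.", character(0)), 17)
})

test_that("gene-pool summary aggregates and handles degenerate input", {
  reg <- gene_pool_registry()
  s <- summarize_gene_pool(fixture_stats(), reg)
  expect_equal(s$grand_total, sum(s$per_taxon$total_accessions))
  expect_equal(s$grand_total, sum(s$totals_by_tier))
  expect_true(all(s$per_taxon$native_collected <=
                    s$per_taxon$total_accessions))

  zero <- data.frame(canonical_name = reg$taxa$canonical_name,
                     total_accessions = 0, native_collected = 0)
  sz <- summarize_gene_pool(zero, reg)
  expect_equal(sz$grand_total, 0)
  expect_equal(unname(sz$tertiary_fraction_below), c(100, 100))
})
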