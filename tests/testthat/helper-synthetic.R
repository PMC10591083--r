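# small in-code builders shared across test files

tiny_registry <- function() {
  load_registry(data.frame(
    taxon = c("Brassica cretica Lam.", "Hirschfeldia incana (L.) Lagr.-Foss.",
              "Synthetica culta"),
    tier = c("secondary", "tertiary", "primary"),
    cultivation = c("wild", "wild", "cultivated"),
    redlist = c("LC", "", "NOT_LISTED"),
    native_countries = c("Greece|Turkey", "FRA|ESP|ITA", ""),
    synonyms = c("", "Sinapis incana L.", ""),
    stringsAsFactors = FALSE))
}

tiny_grid <- function(n_rows = 20, n_cols = 20, res_arcmin = 30) {
  grid_spec(lon_min = 0, lat_max = 10, res_arcmin = res_arcmin,
            n_rows = n_rows, n_cols = n_cols)
}

# landscape with one west-east temperature gradient and one north-south
# precipitation gradient; values constant within a column / row
gradient_env <- function(n_rows = 40, n_cols = 40,
                         temp_range = c(0, 30), prec_range = c(0, 2000)) {
  g <- grid_spec(lon_min = 0, lat_max = n_rows * 2.5 / 60,
                 res_arcmin = 2.5, n_rows = n_rows, n_cols = n_cols)
  make_env_stack(g, layers = list(
    temp = list(kind = "lon_gradient", range = temp_range),
    prec = list(kind = "lat_gradient", range = prec_range)))$current
}

# independent brute-force oracles for the range metrics (plain loops,
# no package set machinery)
brute_change_mig <- function(current, future) {
  round(100 * (nrow(future) - nrow(current)) / nrow(current) +
          sign(nrow(future) - nrow(current)) * 0, 10) # exact ratio
}
brute_intersection_size <- function(current, future) {
  n <- 0
  for (i in seq_len(nrow(current))) {
    for (j in seq_len(nrow(future))) {
      if (current[i, 1] == future[j, 1] && current[i, 2] == future[j, 2]) {
        n <- n + 1
        break
      }
    }
  }
  n
}

expect_cells_equal <- function(a, b) {
  expect_equal(unclass(cell_set(a)), unclass(cell_set(b)),
               ignore_attr = TRUE)
}

fixture_stats <- function() {
  inv <- gene_pool_inventory()
  data.frame(canonical_name = inv$taxon, total_accessions = inv$accessions,
             native_collected = inv$native_collected,
             stringsAsFactors = FALSE)
}
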