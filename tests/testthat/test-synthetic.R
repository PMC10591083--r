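test_that("stack generation is seeded and shifts are exactly additive", {
  g <- tiny_grid()
  spec <- list(temp = list(kind = "lon_gradient", range = c(0, 30),
                           noise_sd = 0.5),
               prec = list(kind = "lat_gradient", range = c(0, 1000)))
  a <- make_env_stack(g, spec, seed = 3)
  b <- make_env_stack(g, spec, seed = 3)
  expect_identical(a$current$layers, b$current$layers)
  # zero shift: future identical to current
  z <- make_env_stack(g, spec, shift = c(temp = 0), seed = 3)
  expect_identical(z$future$layers, z$current$layers)
  # +delta on one layer changes that layer by exactly delta everywhere
  s <- make_env_stack(g, spec, shift = c(temp = 2.5), seed = 3)
  expect_equal(s$future$layers$temp, s$current$layers$temp + 2.5)
  expect_identical(s$future$layers$prec, s$current$layers$prec)
})

test_that("simulated occurrences stay inside the niche support", {
  env <- gradient_env(30, 30)
  niche <- niche_spec(bounds = list(temp = c(10, 20), prec = c(500, 1500)))
  occ <- simulate_occurrences(niche, env, n_draws = 100, seed = 12)
  truth <- attr(occ, "true_cells")
  sampled <- attr(occ, "sampled_cells")
  # every sampled cell is truly suitable: no records where suitability is 0
  expect_equal(nrow(cells_diff(sampled, truth)), 0)
  vals <- env_values(env, sampled)
  expect_true(all(vals[, "temp"] >= 10 & vals[, "temp"] <= 20))
  # determinism
  occ2 <- simulate_occurrences(niche, env, n_draws = 100, seed = 12)
  expect_identical(occ, occ2)
})

test_that("a noiseless envelope niche is recovered exactly", {
  env <- gradient_env(40, 40)
  niche <- niche_spec(bounds = list(temp = c(8, 22), prec = c(300, 1700)))
  truth <- true_suitable_cells(niche, env)
  # sample densely enough to hit the extreme rows/columns
  occ <- simulate_occurrences(niche, env, n_draws = nrow(truth), seed = 2)
  X <- env_values(env, attr(occ, "sampled_cells"))
  m <- fit_envelope(X, q = 0)
  expect_equal(m$lower, apply(env_values(env, truth), 2, min))
  expect_equal(m$upper, apply(env_values(env, truth), 2, max))
})

test_that("the analytic range-change oracle does plain set arithmetic", {
  env <- gradient_env(30, 60, temp_range = c(0, 29.5), prec_range = c(0, 100))
  # column c carries temp value 0.5*c: bounds [5, 9.75] cover columns 10..19
  niche <- niche_spec(bounds = list(temp = c(5, 9.75), prec = c(-1, 101)))
  # zero shift: no change under either assumption
  z <- expected_range_change(niche, env, c(temp = 0))
  expect_equal(z$change_mig, 0)
  expect_equal(z$change_nomig, 0)
  # shifting by one column width (+0.5) loses exactly 1 of 10 columns
  one <- expected_range_change(niche, env, c(temp = 0.5))
  expect_equal(one$change_nomig, -10.0)
  expect_equal(one$change_mig, 0)   # window slides, same width
  # shift beyond the upper bound empties the range
  gone <- expected_range_change(niche, env, c(temp = 100))
  expect_equal(gone$change_mig, -100)
  expect_equal(gone$change_nomig, -100)
})

test_that("passport generation honours its ground-truth spec", {
  reg <- tiny_registry()
  empty <- data.frame(taxon = character(0), origcty = character(0),
                      collected = logical(0), n = integer(0))
  p0 <- withr::local_tempfile(fileext = ".tsv")
  make_passport_file(empty, p0)
  expect_equal(nrow(parse_passport(p0)), 0)

  # 5 native-collected plus 3 non-native rows -> stats (5 of 8)
  spec <- data.frame(taxon = "Brassica cretica Lam.",
                     origcty = c("GRC", "DEU"), collected = c(TRUE, TRUE),
                     n = c(5, 3), stringsAsFactors = FALSE)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  make_passport_file(spec, p1, seed = 7)
  stats <- native_collected_counts(parse_passport(p1), reg)
  cre <- stats[stats$canonical_name == "Brassica cretica Lam.", ]
  expect_equal(cre$total_accessions, 8L)
  expect_equal(cre$native_collected, 5L)
  # the ground truth is saved beside the file
  expect_true(file.exists(paste0(p1, ".truth.tsv")))
})

test_that("ASCII grid rasters round-trip with their mask", {
  g <- tiny_grid(10, 12)
  m <- matrix(stats::runif(120), 10, 12)
  m[3, 4] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m, g, path)
  back <- read_ascii_grid(path)
  expect_equal(back$values, m, tolerance = 1e-6)
  expect_equal(back$grid$n_rows, g$n_rows)
  expect_equal(back$grid$lon_min, g$lon_min)
  expect_equal(back$grid$res_arcmin, g$res_arcmin)
  # stack reading harmonises masks across layers
  g2 <- tiny_grid(10, 12)
  m2 <- matrix(1, 10, 12)
  p2 <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m2, g2, p2)
  stack <- read_env_stack(c(path, p2))
  expect_equal(sum(!stack$mask), 1)
  expect_true(is.na(stack$layers[[2]][3, 4]))
})
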