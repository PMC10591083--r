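test_that("cleaning drops missing, invalid and out-of-region records", {
  rec <- data.frame(taxon_name = "t",
                    lon = c("5", "", "5", "200", "50"),
                    lat = c("45", "45", "95", "45", "45"),
                    stringsAsFactors = FALSE)
  out <- clean_occurrences(rec, c(0, 10, 40, 50))
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$lon, 5)
  expect_equal(sort(out$rejected$reason),
               c("invalid", "invalid", "missing", "outside_region"))
})

test_that("grid indexing follows the floor convention with boundary clamp", {
  g <- grid_spec(lon_min = 0, lat_max = 10, res_arcmin = 2.5,
                 n_rows = 24, n_cols = 24)
  # upper-left origin
  expect_equal(unname(grid_index(0, 10, g)[1, ]), c(0L, 0L))
  # 0.05 deg east = 1.2 cell widths -> column 1; 0.01 south -> row 0
  expect_equal(unname(grid_index(0.05, 9.99, g)[1, ]), c(0L, 1L))
  # exact east/south boundary clamps into the last cell
  east <- g$lon_min + g$n_cols * g$res_deg
  south <- g$lat_max - g$n_rows * g$res_deg
  expect_equal(unname(grid_index(east, south, g)[1, ]),
               c(g$n_rows - 1L, g$n_cols - 1L))
  expect_error(grid_index(-1, 5, g), "outside grid extent")
})

test_that("per-cell deduplication is order-invariant and exact", {
  g <- tiny_grid()
  rec <- data.frame(lon = c(0.1, 0.15, 0.2, 3.1),
                    lat = c(9.9, 9.95, 9.9, 8.0))
  cells <- dedupe_cells(rec, g)
  expect_equal(nrow(cells), 2)
  shuffled <- rec[c(4, 2, 1, 3), ]
  expect_cells_equal(dedupe_cells(shuffled, g), cells)
  # synthetic scatter with known occupancy
  set.seed(11)
  pts <- cell_centers(cell_set(cbind(row = c(0, 5, 7), col = c(0, 5, 9))), g)
  many <- data.frame(lon = rep(pts$lon, 3), lat = rep(pts$lat, 3))
  expect_cells_equal(dedupe_cells(many, g),
                     cbind(row = c(0, 5, 7), col = c(0, 5, 9)))
})

test_that("thinning keeps cells separated by at least one empty cell", {
  expect_cells_equal(thin_cells(cbind(row = c(0, 0), col = c(0, 1))),
                     cbind(row = 0, col = 0))
  # distance exactly 2 (one empty cell between): both kept
  kept <- thin_cells(cbind(row = c(0, 2), col = c(0, 2)))
  expect_equal(nrow(kept), 2)
  # diagonal neighbours conflict under the default Chebyshev rule...
  expect_equal(nrow(thin_cells(cbind(row = c(0, 1), col = c(0, 1)))), 1)
  # ...but not under rook separation
  expect_equal(nrow(thin_cells(cbind(row = c(0, 1), col = c(0, 1)),
                               mode = "rook")), 2)
  # full 5x5 block reduces to the 9 cells on even rows/columns
  block <- as.matrix(expand.grid(row = 0:4, col = 0:4))
  expect_cells_equal(thin_cells(block),
                     as.matrix(expand.grid(row = c(0, 2, 4),
                                           col = c(0, 2, 4))))
})

test_that("thinning is idempotent, conflict-free and maximal on random sets", {
  set.seed(202)
  chebyshev_ok <- function(cells) {
    n <- nrow(cells)
    if (n < 2) return(TRUE)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (max(abs(cells[i, 1] - cells[j, 1]),
              abs(cells[i, 2] - cells[j, 2])) < 2) return(FALSE)
    }
    TRUE
  }
  for (rep in 1:60) {
    side <- sample(2:8, 1)
    n <- sample.int(side^2, 1)
    cells <- cell_set(cbind(row = sample.int(side, n, TRUE) - 1,
                            col = sample.int(side, n, TRUE) - 1))
    thinned <- thin_cells(cells)
    # subset of the input
    expect_true(all(paste(thinned[, 1], thinned[, 2]) %in%
                      paste(cells[, 1], cells[, 2])))
    # pairwise separation holds (brute force over all pairs)
    expect_true(chebyshev_ok(thinned))
    # maximal: every rejected cell conflicts with some kept cell
    rejected <- cells[!(paste(cells[, 1], cells[, 2]) %in%
                          paste(thinned[, 1], thinned[, 2])), , drop = FALSE]
    for (k in seq_len(nrow(rejected))) {
      conflicts <- any(pmax(abs(thinned[, 1] - rejected[k, 1]),
                            abs(thinned[, 2] - rejected[k, 2])) < 2)
      expect_true(conflicts)
    }
    # idempotent
    expect_cells_equal(thin_cells(thinned), thinned)
  }
})

test_that("modellability is a simple thinned-cell-count threshold", {
  two <- cell_set(cbind(row = c(0, 5), col = c(0, 5)))
  expect_false(is_modellable(two, 10))
  ten <- cell_set(cbind(row = 2 * (0:9), col = 2 * (0:9)))
  expect_true(is_modellable(ten, 10))
  expect_false(is_modellable(cell_set(NULL), 1))
})

test_that("occurrence tables in the GBIF dialect are read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gbifID,species,decimalLatitude,decimalLongitude,basisOfRecord",
               "1,Aus bus,45.0,5.0,HUMAN_OBSERVATION",
               "2,Aus bus,46.0,6.0,PRESERVED_SPECIMEN"), path)
  occ <- read_occurrences(path)
  expect_equal(nrow(occ), 2)
  expect_equal(occ$taxon_name, rep("Aus bus", 2))
  expect_equal(occ$source_id, c("1", "2"))
})
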