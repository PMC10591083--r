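#' Specify a true climate niche
#'
#' Ground-truth species-climate relationship for simulations. Two truth
#' modes: hard per-layer bounds (an envelope niche, giving exact oracles
#' for recovery tests) or Gaussian suitability per layer (optimum and
#' tolerance, exercising realistic model misspecification).
#'
#' @param bounds named list of `c(lower, upper)` per layer (envelope
#'   truth), or NULL.
#' @param optimum,tolerance named numeric vectors per layer (Gaussian
#'   truth), or NULL. Tolerances must be positive.
#' @param max_prevalence presence probability at the niche optimum for
#'   Bernoulli sampling (default 1).
#' @return Object of class `niche_spec`.
#' @export
niche_spec <- function(bounds = NULL, optimum = NULL, tolerance = NULL,
                       max_prevalence = 1) {
  if (!is.null(bounds)) {
    stopifnot(is.list(bounds), !is.null(names(bounds)),
              all(vapply(bounds, function(b) length(b) == 2 && b[1] <= b[2],
                         logical(1))))
    mode <- "envelope"
  } else {
    stopifnot(!is.null(optimum), !is.null(tolerance),
              identical(names(optimum), names(tolerance)),
              all(tolerance > 0))
    mode <- "gaussian"
  }
  stopifnot(max_prevalence > 0, max_prevalence <= 1)
  structure(list(mode = mode, bounds = bounds, optimum = optimum,
                 tolerance = tolerance, max_prevalence = max_prevalence),
            class = "niche_spec")
}

#' True suitability of every cell
#'
#' Envelope truth: 1 where all niche layers are within bounds, 0 outside.
#' Gaussian truth: product over layers of
#' `exp(-((v - optimum) / tolerance)^2 / 2)`, scaled by `max_prevalence`.
#'
#' @param niche a [niche_spec()].
#' @param env an [env_stack()] containing every niche layer.
#' @return Matrix of suitabilities (`NA` off-mask).
#' @export
niche_suitability <- function(niche, env) {
  layers <- if (niche$mode == "envelope") names(niche$bounds) else
    names(niche$optimum)
  miss <- setdiff(layers, names(env$layers))
  if (length(miss)) stop("niche layer(s) absent from stack: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (niche$mode == "envelope") {
    s <- matrix(1, env$grid$n_rows, env$grid$n_cols)
    for (nm in layers) {
      b <- niche$bounds[[nm]]
      l <- env$layers[[nm]]
      s <- s * (l >= b[1] & l <= b[2])
    }
  } else {
    s <- matrix(niche$max_prevalence, env$grid$n_rows, env$grid$n_cols)
    for (nm in layers) {
      z <- (env$layers[[nm]] - niche$optimum[[nm]]) / niche$tolerance[[nm]]
      s <- s * exp(-z^2 / 2)
    }
  }
  s[!env$mask] <- NA_real_
  s
}

true_suitable_cells <- function(niche, env, cutoff = 0.5) {
  s <- niche_suitability(niche, env)
  if (niche$mode == "envelope") cutoff <- 1
  idx <- which(!is.na(s) & s >= cutoff, arr.ind = TRUE)
  cell_set(cbind(row = idx[, 1] - 1L, col = idx[, 2] - 1L))
}

#' Generate a synthetic environmental stack (and a shifted future twin)
#'
#' Layers are deterministic spatial gradients plus optional Gaussian noise,
#' a minimal stand-in for bioclimatic surfaces. Supported layer
#' descriptors: `list(kind = "lon_gradient", range = c(lo, hi), noise_sd =
#' 0)` (value increases west to east, constant within a column),
#' `"lat_gradient"` (increases north to south, constant within a row), and
#' `"constant"` (`value =`). The future twin adds the per-layer `shift`
#' cell-wise to the current stack, emulating a prescribed warming. Pure
#' function of `(grid, layers, shift, seed)`.
#'
#' @param grid a [grid_spec()].
#' @param layers named list of layer descriptors.
#' @param shift optional named numeric vector of per-layer additive deltas.
#' @param seed integer seed (used only when any `noise_sd > 0`).
#' @return List with `current` (an [env_stack()]) and `future` (shifted
#'   twin, or NULL when `shift` is NULL).
#' @export
make_env_stack <- function(grid, layers, shift = NULL, seed = 1) {
  stopifnot(is.list(layers), !is.null(names(layers)))
  set.seed(seed)
  mats <- lapply(layers, function(sp) {
    kind <- sp$kind
    base <- switch(kind,
      lon_gradient = {
        v <- seq(sp$range[1], sp$range[2], length.out = grid$n_cols)
        matrix(rep(v, each = grid$n_rows), grid$n_rows, grid$n_cols)
      },
      lat_gradient = {
        v <- seq(sp$range[1], sp$range[2], length.out = grid$n_rows)
        matrix(rep(v, times = grid$n_cols), grid$n_rows, grid$n_cols)
      },
      constant = matrix(sp$value, grid$n_rows, grid$n_cols),
      stop("unknown layer kind: ", kind, call. = FALSE))
    ns <- if (is.null(sp$noise_sd)) 0 else sp$noise_sd
    if (ns > 0) base <- base + matrix(stats::rnorm(length(base), 0, ns),
                                      nrow(base), ncol(base))
    base
  })
  current <- env_stack(grid, mats)
  future <- NULL
  if (!is.null(shift)) {
    stopifnot(all(is.finite(shift)), all(names(shift) %in% names(mats)))
    fmats <- mats
    for (nm in names(shift)) fmats[[nm]] <- fmats[[nm]] + shift[[nm]]
    future <- env_stack(grid, fmats)
  }
  list(current = current, future = future)
}

#' Simulate occurrence records from a known niche
#'
#' Draws presence records over the landscape with probability proportional
#' to the true suitability. `mode = "fixed_n"` samples `n_draws` cells
#' without replacement (suitability-weighted; for an envelope niche this is
#' a uniform draw from the truly suitable cells -- "noiseless" sampling, no
#' presence ever falls outside the true niche). `mode = "bernoulli"` visits
#' every cell once and records a presence with probability `suitability *
#' max_prevalence`. Records are placed at cell centres.
#'
#' @param niche a [niche_spec()].
#' @param env an [env_stack()].
#' @param n_draws number of records (`fixed_n` mode).
#' @param seed integer seed.
#' @param mode `"fixed_n"` (default) or `"bernoulli"`.
#' @param taxon_name label written on the records.
#' @return Data frame (`taxon_name`, `lon`, `lat`) with attributes
#'   `true_cells` (truly suitable [cell_set()]) and `sampled_cells`.
#' @export
simulate_occurrences <- function(niche, env, n_draws = 100, seed = 1,
                                 mode = c("fixed_n", "bernoulli"),
                                 taxon_name = "Synthetica exempli") {
  mode <- match.arg(mode)
  s <- niche_suitability(niche, env)
  ok <- which(!is.na(s) & s > 0, arr.ind = TRUE)
  cells <- cbind(row = ok[, 1] - 1L, col = ok[, 2] - 1L)
  p <- s[ok]
  set.seed(seed)
  if (mode == "fixed_n") {
    if (!nrow(cells)) {
      take <- integer(0)
    } else {
      n <- min(n_draws, nrow(cells))
      take <- sample.int(nrow(cells), n, prob = p)
    }
  } else {
    take <- which(stats::runif(length(p)) < p)
  }
  sampled <- cell_set(cells[take, , drop = FALSE])
  ctr <- cell_centers(sampled, env$grid)
  out <- data.frame(taxon_name = rep(taxon_name, nrow(ctr)),
                    lon = ctr$lon, lat = ctr$lat, stringsAsFactors = FALSE)
  attr(out, "true_cells") <- true_suitable_cells(niche, env)
  attr(out, "sampled_cells") <- sampled
  out
}

#' Analytic range change under a prescribed climate shift
#'
#' For an envelope-truth niche the truly suitable cell sets under the
#' current and the shifted stack are computable by direct evaluation; this
#' yields exact expected values for both migration assumptions and serves
#' as the oracle for end-to-end pipeline tests.
#'
#' @param niche a [niche_spec()] with hard bounds.
#' @param env the current [env_stack()].
#' @param shift named numeric vector of per-layer deltas.
#' @return List with `change_mig`, `change_nomig`, `current_cells`,
#'   `future_cells`.
#' @export
expected_range_change <- function(niche, env, shift) {
  stopifnot(niche$mode == "envelope")
  cur <- true_suitable_cells(niche, env)
  fmats <- env$layers
  for (nm in names(shift)) fmats[[nm]] <- fmats[[nm]] + shift[[nm]]
  fut_env <- env_stack(env$grid, fmats)
  fut <- true_suitable_cells(niche, fut_env)
  list(change_mig = change_with_migration(cur, fut),
       change_nomig = change_no_migration(cur, fut),
       current_cells = cur, future_cells = fut)
}

split_taxon_label <- function(label) {
  label <- squeeze_ws(label)
  sub <- ""
  m <- regexpr(" (subsp\\.|ssp\\.|var\\.) ", label)
  if (m > 0) {
    sub <- trimws(substring(label, m + 1))
    label <- trimws(substring(label, 1, m - 1))
  }
  toks <- strsplit(label, " ", fixed = TRUE)[[1]]
  list(genus = toks[1],
       species = if (length(toks) >= 2) toks[2] else "",
       spauthor = if (length(toks) >= 3)
         paste(toks[-(1:2)], collapse = " ") else "",
       subtaxa = sub)
}

#' Write a synthetic MCPD passport file with known tallies
#'
#' Expands per-taxon / per-country / per-status counts into accession rows
#' in the MCPD column dialect that [parse_passport()] consumes, so that
#' [accession_counts()] and [native_collected_counts()] must reproduce the
#' requested tallies exactly. Collected rows draw `COLLSRC` uniformly from
#' the wild codes 10-19; non-collected rows get `COLLSRC 40` (genebank) and
#' `SAMPSTAT 300`. The request is saved beside the file as a ground-truth
#' sidecar (`<file>.truth.tsv`).
#'
#' @param spec data frame with columns `taxon` (name as it should appear,
#'   possibly a synonym), `origcty` (alpha-3 or NA for unknown origin),
#'   `collected` (logical), `n` (row count to emit).
#' @param file output path.
#' @param seed integer seed (row shuffling and COLLSRC draws).
#' @return `file`, invisibly.
#' @export
make_passport_file <- function(spec, file, seed = 1) {
  cols <- c("ACCENUMB", "INSTCODE", "GENUS", "SPECIES", "SPAUTHOR",
            "SUBTAXA", "ORIGCTY", "COLLSRC", "SAMPSTAT")
  if (!nrow(spec)) {
    writeLines(paste(cols, collapse = "\t"), file)
    utils::write.table(spec, paste0(file, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(file))
  }
  stopifnot(all(c("taxon", "origcty", "collected", "n") %in% names(spec)),
            all(spec$n >= 0))
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    n <- spec$n[i]
    if (!n) return(NULL)
    parts <- split_taxon_label(spec$taxon[i])
    data.frame(GENUS = parts$genus, SPECIES = parts$species,
               SPAUTHOR = parts$spauthor, SUBTAXA = parts$subtaxa,
               ORIGCTY = ifelse(is.na(spec$origcty[i]), "",
                                spec$origcty[i]),
               COLLSRC = if (spec$collected[i])
                 sample(10:19, n, replace = TRUE) else rep(40L, n),
               SAMPSTAT = if (spec$collected[i]) rep(100L, n) else
                 rep(300L, n),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
  rows <- cbind(ACCENUMB = sprintf("ACC%06d", seq_len(nrow(rows))),
                INSTCODE = "SYN001", rows)
  utils::write.table(rows[, cols], file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(spec, paste0(file, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
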