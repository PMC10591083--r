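#' Sample pseudo-absence sets
#'
#' Presence-only niche modelling needs background ("pseudo-absence") cells
#' to contrast with presences. Draws `n_sets` independent uniform samples,
#' without replacement, from the valid (unmasked) cells that are not
#' presences. Reproducible for a fixed seed.
#'
#' @param presences a [cell_set()] of presence cells.
#' @param env an [env_stack()].
#' @param n_sets number of pseudo-absence sets (default 3).
#' @param n_per_set cells per set (default: the presence count).
#' @param seed integer RNG seed.
#' @return Object of class `pa_set`: list with `presences`, `absence_sets`
#'   (list of cell sets, each disjoint from the presences), `seed`.
#' @export
sample_pseudo_absences <- function(presences, env, n_sets = 3,
                                   n_per_set = NULL, seed = 1) {
  presences <- cell_set(presences, env$grid)
  if (is.null(n_per_set)) n_per_set <- nrow(presences)
  cand <- cells_diff(valid_cells(env), presences)
  if (n_per_set > nrow(cand)) {
    stop("not enough candidate cells for pseudo-absences (", nrow(cand),
         " available, ", n_per_set, " requested)", call. = FALSE)
  }
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) {
    cell_set(cand[sample.int(nrow(cand), n_per_set), , drop = FALSE])
  })
  structure(list(presences = presences, absence_sets = sets, seed = seed),
            class = "pa_set")
}

#' Fit a climate-envelope (surface range envelope) member
#'
#' The rectilinear "bioclim" model: per layer, bounds are taken at the
#' `q`-th and `(100 - q)`-th percentiles of the presence values. The
#' suitability of a cell is the fraction of layers whose value falls within
#' its bounds, so `q = 0` gives an envelope that contains every presence
#' with suitability 1.
#'
#' @param presence_env numeric matrix of layer values at presence cells
#'   (rows = cells, columns = layers; see [env_values()]).
#' @param q tail percentile trimmed at each end, `0 <= q < 50`.
#' @return Object of class `sdm_member`, kind `"envelope"`, with `lower`
#'   and `upper` bound vectors. Skill (`tss`, `auc`) and `threshold` are
#'   filled in by [evaluate_scores()]/[fit_sdm_ensemble()].
#' @export
fit_envelope <- function(presence_env, q = 2.5) {
  stopifnot(is.matrix(presence_env), nrow(presence_env) >= 1,
            q >= 0, q < 50)
  if (nrow(presence_env) < 2) stop("need >= 2 presence cells", call. = FALSE)
  pr <- c(q, 100 - q) / 100
  bounds <- apply(presence_env, 2, stats::quantile, probs = pr, names = FALSE)
  structure(list(kind = "envelope",
                 lower = bounds[1, ], upper = bounds[2, ],
                 layer_names = colnames(presence_env),
                 q = q, tss = NA_real_, auc = NA_real_,
                 threshold = NA_real_),
            class = "sdm_member")
}

#' Fit a logistic-regression member
#'
#' Binomial GLM of presence against the environmental layers, fitted with
#' `stats::glm`. Layers are standardised to zero mean and unit variance
#' over the training cells; by default each standardised layer also enters
#' squared (the usual regression-based SDM response shape, allowing
#' unimodal suitability). Constant layers are dropped with a warning.
#' Under complete separation coefficients diverge; their magnitude is
#' capped (rescaled to `max_abs_coef`) and the model flagged.
#'
#' @param X numeric matrix of layer values at training cells.
#' @param y 0/1 vector (1 = presence).
#' @param quadratic add squared terms (default TRUE).
#' @param max_abs_coef magnitude cap applied on the standardised scale.
#' @return Object of class `sdm_member`, kind `"logistic"`, holding the
#'   standardisation constants and coefficient vector.
#' @export
fit_logistic <- function(X, y, quadratic = TRUE, max_abs_coef = 15) {
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% 0:1))
  if (!any(y == 1) || !any(y == 0)) {
    stop("both classes must be nonempty", call. = FALSE)
  }
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  keep <- scale > 0
  if (!any(keep)) {
    # intercept-only: suitability = presence prevalence
    warning("all layers constant; intercept-only model", call. = FALSE)
    return(structure(list(kind = "logistic", center = center, scale = scale,
                          keep = keep, quadratic = quadratic,
                          coef = stats::qlogis(mean(y)), separation = FALSE,
                          layer_names = colnames(X), tss = NA_real_,
                          auc = NA_real_, threshold = NA_real_),
                     class = "sdm_member"))
  }
  if (any(!keep)) {
    warning("dropping constant layer(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
  }
  Z <- scale(X[, keep, drop = FALSE], center = center[keep],
             scale = scale[keep])
  F <- if (quadratic) cbind(Z, Z^2) else Z
  fit <- suppressWarnings(stats::glm.fit(cbind(1, F), y,
                                         family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  separation <- max(abs(beta[-1])) > max_abs_coef
  if (separation) {
    beta <- beta * max_abs_coef / max(abs(beta[-1]))
  }
  structure(list(kind = "logistic", center = center, scale = scale,
                 keep = keep, quadratic = quadratic, coef = beta,
                 separation = separation, layer_names = colnames(X),
                 tss = NA_real_, auc = NA_real_, threshold = NA_real_),
            class = "sdm_member")
}

#' Predict member suitability
#'
#' @param object an `sdm_member`.
#' @param newdata numeric matrix of layer values (columns in training
#'   order).
#' @param ... unused.
#' @return Suitability vector in `[0, 1]`.
#' @export
predict.sdm_member <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (object$kind == "envelope") {
    inside <- sweep(newdata, 2, object$lower, `>=`) &
      sweep(newdata, 2, object$upper, `<=`)
    return(rowMeans(inside))
  }
  keep <- object$keep
  if (!any(keep)) {
    return(rep(stats::plogis(object$coef[1]), nrow(newdata)))
  }
  Z <- scale(newdata[, keep, drop = FALSE], center = object$center[keep],
             scale = object$scale[keep])
  F <- if (object$quadratic) cbind(Z, Z^2) else Z
  as.numeric(stats::plogis(cbind(1, F) %*% object$coef))
}

#' @export
print.sdm_member <- function(x, ...) {
  cat(sprintf("sdm_member [%s]  TSS=%.3f  AUC=%.3f  threshold=%.3f\n",
              x$kind, x$tss, x$auc, x$threshold))
  invisible(x)
}

tss_at_thresholds <- function(scores, labels) {
  u <- sort(unique(scores))
  thr <- c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1)
  pos <- labels == 1
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  data.frame(threshold = thr, tss = sens + spec - 1)
}

auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated TSS, AUC and binarisation threshold
#'
#' Repeatedly draws random evaluation subsets (a holdout of `split` of the
#' items), and on each computes (a) the maximum of the true skill statistic
#' TSS = sensitivity + specificity - 1 over candidate thresholds -- the
#' midpoints of sorted unique scores plus 0 and 1, ties resolved toward the
#' lower threshold -- and (b) AUC by the rank statistic. Reported TSS/AUC
#' are rep means; the reported threshold is the mean of the per-rep TSS
#' maximisers. Splits with a single class are redrawn (bounded retries).
#'
#' @param scores suitability scores in `[0, 1]`.
#' @param labels 0/1 vector of the same length.
#' @param split holdout fraction (default 0.3, the 70/30 convention);
#'   `split = 1` evaluates on the full item set.
#' @param reps number of random splits (default 5).
#' @param seed integer RNG seed.
#' @return List with `tss`, `auc`, `threshold`.
#' @export
evaluate_scores <- function(scores, labels, split = 0.3, reps = 5, seed = 1) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1),
            any(labels == 1), any(labels == 0), split > 0, split <= 1)
  set.seed(seed)
  n <- length(scores)
  m <- min(n, max(2L, floor(split * n)))
  tss <- auc <- thr <- numeric(reps)
  for (r in seq_len(reps)) {
    for (try in 1:100) {
      idx <- sample.int(n, m)
      if (any(labels[idx] == 1) && any(labels[idx] == 0)) break
      if (try == 100) stop("could not draw a two-class evaluation split",
                           call. = FALSE)
    }
    s <- scores[idx]; l <- labels[idx]
    curve <- tss_at_thresholds(s, l)
    best <- which.max(curve$tss)   # which.max takes the first (lowest) tie
    tss[r] <- curve$tss[best]
    thr[r] <- curve$threshold[best]
    auc[r] <- auc_rank(s, l)
  }
  list(tss = mean(tss), auc = mean(auc), threshold = mean(thr))
}

#' Fit the ensemble niche model
#'
#' The packaged ensemble has two member kinds: a climate envelope fitted to
#' the presences, and one logistic regression per pseudo-absence set. Every
#' member is scored with [evaluate_scores()] on the presences plus the
#' first pseudo-absence set (a common evaluation pool, so member skills are
#' comparable); members reaching `tss_cutoff` are admitted and weighted by
#' their TSS (normalised to sum 1).
#'
#' @param presences a [cell_set()] of presence cells (cleaned, deduplicated
#'   and thinned upstream).
#' @param env an [env_stack()] of current-climate layers.
#' @param n_pa_sets pseudo-absence sets, and hence logistic members
#'   (default 3).
#' @param q envelope tail percentile (default 2.5).
#' @param quadratic quadratic terms in the logistic members (default TRUE).
#' @param tss_cutoff minimum member TSS for admission (default 0.7).
#' @param split,reps evaluation settings, see [evaluate_scores()].
#' @param seed integer seed governing pseudo-absences and evaluation splits.
#' @return Object of class `sdm_ensemble` with `members` (all fitted
#'   members, scored), `admitted` (indices), `weights`, `tss_cutoff`,
#'   `config`. Errors if no member reaches the cutoff, naming the best
#'   member score.
#' @examples
#' g <- grid_spec(0, 10, res_arcmin = 30, n_rows = 20, n_cols = 20)
#' layer <- matrix(rep(seq(0, 30, length.out = 20), each = 20), 20, 20)
#' env <- env_stack(g, list(temp = layer))
#' pres <- cell_set(expand.grid(row = 4:9, col = 4:9))
#' fit <- fit_sdm_ensemble(pres, env, seed = 7, tss_cutoff = 0.3)
#' summary(fit)
#' @export
fit_sdm_ensemble <- function(presences, env, n_pa_sets = 3, q = 2.5,
                             quadratic = TRUE, tss_cutoff = 0.7,
                             split = 0.3, reps = 5, seed = 1) {
  presences <- cell_set(presences, env$grid)
  pa <- sample_pseudo_absences(presences, env, n_sets = n_pa_sets,
                               seed = seed)
  Xp <- env_values(env, presences)
  eval_cells <- rbind(presences, pa$absence_sets[[1]])
  eval_X <- env_values(env, eval_cells)
  eval_y <- c(rep(1, nrow(presences)), rep(0, nrow(pa$absence_sets[[1]])))

  members <- list(fit_envelope(Xp, q = q))
  for (s in pa$absence_sets) {
    Xa <- env_values(env, s)
    members <- c(members, list(
      fit_logistic(rbind(Xp, Xa), c(rep(1, nrow(Xp)), rep(0, nrow(Xa))),
                   quadratic = quadratic)))
  }
  for (i in seq_along(members)) {
    sc <- predict(members[[i]], eval_X)
    ev <- evaluate_scores(sc, eval_y, split = split, reps = reps,
                          seed = seed + i)
    members[[i]]$tss <- ev$tss
    members[[i]]$auc <- ev$auc
    members[[i]]$threshold <- ev$threshold
  }
  tss <- vapply(members, `[[`, numeric(1), "tss")
  admitted <- which(tss >= tss_cutoff)
  if (!length(admitted)) {
    stop(sprintf("no ensemble member reached the TSS cutoff %.2f (best: %.3f)",
                 tss_cutoff, max(tss)), call. = FALSE)
  }
  w <- tss[admitted] / sum(tss[admitted])
  structure(list(members = members, admitted = admitted, weights = w,
                 tss_cutoff = tss_cutoff, presences = presences,
                 pa = pa,
                 config = list(n_pa_sets = n_pa_sets, q = q,
                               quadratic = quadratic, split = split,
                               reps = reps, seed = seed)),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("sdm_ensemble: %d member(s), %d admitted at TSS >= %.2f\n",
              length(x$members), length(x$admitted), x$tss_cutoff))
  invisible(x)
}

#' @export
summary.sdm_ensemble <- function(object, ...) {
  kinds <- vapply(object$members, `[[`, character(1), "kind")
  df <- data.frame(member = seq_along(object$members), kind = kinds,
                   tss = vapply(object$members, `[[`, numeric(1), "tss"),
                   auc = vapply(object$members, `[[`, numeric(1), "auc"),
                   threshold = vapply(object$members, `[[`, numeric(1),
                                      "threshold"),
                   admitted = seq_along(object$members) %in% object$admitted,
                   weight = 0)
  df$weight[object$admitted] <- object$weights
  print(df, row.names = FALSE, digits = 3)
  invisible(df)
}

#' Consensus projection of fitted members
#'
#' Projects a set of scored members onto an environmental stack. Members
#' with `tss >= tss_cutoff` are admitted and weighted by TSS (normalised).
#' The consensus suitability of a valid cell is the weighted mean of member
#' suitabilities; the binary prediction applies each member's own threshold
#' and takes the TSS-weighted majority (weight >= 0.5). Masked cells are
#' never predicted.
#'
#' @param models list of scored `sdm_member` objects (or an `sdm_ensemble`,
#'   whose members and cutoff are used).
#' @param env an [env_stack()] (current or future climate).
#' @param tss_cutoff minimum member TSS.
#' @return List with `suitability` (matrix, `NA` off-mask) and `cells`
#'   (binary-presence [cell_set()]).
#' @export
ensemble_project <- function(models, env, tss_cutoff = 0.7) {
  if (inherits(models, "sdm_ensemble")) {
    if (missing(tss_cutoff)) tss_cutoff <- models$tss_cutoff
    models <- models$members
  }
  tss <- vapply(models, `[[`, numeric(1), "tss")
  adm <- which(tss >= tss_cutoff)
  if (!length(adm)) {
    stop(sprintf("no member reaches TSS cutoff %.2f (best: %.3f)",
                 tss_cutoff, max(tss)), call. = FALSE)
  }
  w <- tss[adm] / sum(tss[adm])
  cells <- valid_cells(env)
  X <- env_values(env, cells)
  consensus <- numeric(nrow(cells))
  vote <- numeric(nrow(cells))
  for (k in seq_along(adm)) {
    m <- models[[adm[k]]]
    s <- predict(m, X)
    consensus <- consensus + w[k] * s
    vote <- vote + w[k] * (s >= m$threshold)
  }
  suit <- matrix(NA_real_, env$grid$n_rows, env$grid$n_cols)
  suit[cells[, 1] + 1L + cells[, 2] * env$grid$n_rows] <- consensus
  list(suitability = suit,
       cells = cell_set(cells[vote >= 0.5, , drop = FALSE]))
}

#' Project an ensemble onto a climate stack
#'
#' @param object an `sdm_ensemble`.
#' @param env an [env_stack()]; layer names must match the fit.
#' @param ... unused.
#' @return See [ensemble_project()].
#' @export
predict.sdm_ensemble <- function(object, env, ...) {
  ensemble_project(object$members, env, tss_cutoff = object$tss_cutoff)
}

#' Dump a fitted ensemble as a structured text document
#'
#' Key-value (YAML) dump of member kinds, parameters, skill scores,
#' thresholds and the run seed, sufficient to audit or re-apply a fit.
#'
#' @param object an `sdm_ensemble`.
#' @param file output path.
#' @export
write_sdm_model <- function(object, file) {
  mem <- lapply(object$members, function(m) {
    out <- list(kind = m$kind, tss = m$tss, auc = m$auc,
                threshold = m$threshold)
    if (m$kind == "envelope") {
      out$lower <- as.list(stats::setNames(m$lower, m$layer_names))
      out$upper <- as.list(stats::setNames(m$upper, m$layer_names))
      out$q <- m$q
    } else {
      out$center <- as.list(stats::setNames(m$center, m$layer_names))
      out$scale <- as.list(stats::setNames(m$scale, m$layer_names))
      out$coef <- as.numeric(m$coef)
      out$quadratic <- m$quadratic
      out$separation <- m$separation
    }
    out
  })
  yaml::write_yaml(list(members = mem, admitted = object$admitted,
                        weights = as.numeric(object$weights),
                        tss_cutoff = object$tss_cutoff,
                        config = object$config), file)
  invisible(file)
}
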