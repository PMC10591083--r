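test_that("pseudo-absence sampling is disjoint, sized and seeded", {
  env <- gradient_env(20, 20)
  pres <- cell_set(as.matrix(expand.grid(row = 3:8, col = 3:8)))
  pa <- sample_pseudo_absences(pres, env, n_sets = 3, seed = 9)
  for (s in pa$absence_sets) {
    expect_equal(nrow(s), nrow(pres))
    expect_equal(nrow(cells_intersect(s, pres)), 0)
  }
  pa2 <- sample_pseudo_absences(pres, env, n_sets = 3, seed = 9)
  expect_identical(pa$absence_sets, pa2$absence_sets)
  pa3 <- sample_pseudo_absences(pres, env, n_sets = 3, seed = 10)
  expect_false(identical(pa$absence_sets, pa3$absence_sets))
  expect_error(sample_pseudo_absences(pres, env, n_per_set = 1e6),
               "not enough candidate cells")
})

test_that("the climate envelope contains its support and rejects outsiders", {
  X <- cbind(temp = c(10, 12, 15, 20), prec = c(500, 600, 700, 800))
  m <- fit_envelope(X, q = 0)
  expect_equal(predict(m, X), rep(1, 4))
  # one of two layers outside -> suitability 0.5; both outside -> 0
  expect_equal(predict(m, cbind(temp = 25, prec = 600)), 0.5)
  expect_equal(predict(m, cbind(temp = 25, prec = 100)), 0)
  expect_error(fit_envelope(X[1, , drop = FALSE]), ">= 2 presence")
  # percentile bounds on a uniform sample
  set.seed(5)
  U <- cbind(u = stats::runif(20000))
  m5 <- fit_envelope(U, q = 5)
  expect_equal(unname(m5$lower), 0.05, tolerance = 0.01)
  expect_equal(unname(m5$upper), 0.95, tolerance = 0.01)
})

test_that("logistic member separates separable data and stays null on noise", {
  set.seed(31)
  x <- c(stats::rnorm(60, 0, 0.3), stats::rnorm(60, 5, 0.3))
  y <- rep(c(0, 1), each = 60)
  m <- fit_logistic(cbind(x = x), y, quadratic = FALSE)
  sc <- predict(m, cbind(x = x))
  ev <- evaluate_scores(sc, y, seed = 2)
  expect_equal(ev$tss, 1)
  expect_equal(ev$auc, 1)
  # permuted labels: no signal, weights near zero, TSS near zero on average
  yp <- sample(y)
  mp <- fit_logistic(cbind(x = x), yp, quadratic = FALSE)
  expect_lt(max(abs(mp$coef[-1])), 1)
  evp <- evaluate_scores(predict(mp, cbind(x = x)), yp, seed = 2)
  expect_lt(abs(evp$tss), 0.35)
  # constant layer: intercept-only model predicting the prevalence
  expect_warning(mc <- fit_logistic(cbind(k = rep(1, 10)),
                                    rep(c(0, 1), 5)), "constant")
  expect_equal(predict(mc, cbind(k = rep(1, 3))), rep(0.5, 3))
})

test_that("TSS/AUC evaluation matches hand-enumerated cases", {
  # worked 4-point set: threshold 0.5 separates perfectly
  ev <- evaluate_scores(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1),
                        split = 1, reps = 3, seed = 1)
  expect_equal(ev$tss, 1)
  expect_equal(ev$threshold, 0.5)
  # uninformative constant scores
  ev0 <- evaluate_scores(rep(0.4, 40), rep(c(0, 1), 20), seed = 3)
  expect_equal(ev0$tss, 0)
  expect_equal(ev0$auc, 0.5)
})

test_that("TSS/AUC are permutation-invariant and AUC flips with labels", {
  set.seed(77)
  for (i in 1:10) {
    n <- 40
    sc <- stats::runif(n)
    lb <- c(1, 0, stats::rbinom(n - 2, 1, 0.5))
    perm <- sample.int(n)
    e1 <- evaluate_scores(sc, lb, split = 1, reps = 1, seed = 5)
    e2 <- evaluate_scores(sc[perm], lb[perm], split = 1, reps = 1,
                          seed = 5)
    expect_equal(e1$tss, e2$tss)
    expect_equal(e1$auc, e2$auc)
    a <- evaluate_scores(sc, lb, split = 1, reps = 1, seed = 5)$auc
    b <- evaluate_scores(sc, 1 - lb, split = 1, reps = 1, seed = 5)$auc
    expect_equal(a, 1 - b)
  }
})

test_that("ensemble consensus respects weights, cutoff and the mask", {
  env <- gradient_env(30, 30)
  # mask a corner block
  masked <- env$layers
  masked$temp[1:5, 1:5] <- NA
  env <- env_stack(env$grid, masked)
  niche <- niche_spec(bounds = list(temp = c(8, 22), prec = c(400, 1500)))
  occ <- simulate_occurrences(niche, env, n_draws = 120, seed = 4)
  pres <- attr(occ, "sampled_cells")
  fit <- fit_sdm_ensemble(pres, env, seed = 4, q = 0, tss_cutoff = 0.3)
  proj <- predict(fit, env)
  # suitabilities in [0,1]; masked cells never predicted
  expect_true(all(proj$suitability[env$mask] >= 0 &
                    proj$suitability[env$mask] <= 1))
  expect_true(all(is.na(proj$suitability[!env$mask])))
  expect_equal(nrow(cells_intersect(proj$cells,
                                    cells_diff(valid_cells(env),
                                               valid_cells(env)))), 0)
  expect_true(all((proj$cells[, 1] + 1 + proj$cells[, 2] *
                     env$grid$n_rows) %in% which(env$mask)))

  # single admitted member: consensus equals that member's prediction
  m1 <- fit$members[[1]]
  solo <- ensemble_project(list(m1), env, tss_cutoff = 0)
  vc <- valid_cells(env)
  lin <- vc[, 1] + 1 + vc[, 2] * env$grid$n_rows
  expect_equal(solo$suitability[lin],
               as.numeric(predict(m1, env_values(env, vc))))
  # two identical members: consensus equals either
  twin <- ensemble_project(list(m1, m1), env, tss_cutoff = 0)
  expect_equal(twin$suitability, solo$suitability)
  expect_cells_equal(twin$cells, solo$cells)
  # no member passing the cutoff is an error naming the best score
  expect_error(ensemble_project(list(m1), env, tss_cutoff = 1.5), "best")
})

test_that("projection onto an identical future equals the current one", {
  env <- gradient_env(25, 25)
  niche <- niche_spec(bounds = list(temp = c(10, 20), prec = c(500, 1500)))
  occ <- simulate_occurrences(niche, env, n_draws = 80, seed = 6)
  fit <- fit_sdm_ensemble(attr(occ, "sampled_cells"), env, seed = 6,
                          q = 0, tss_cutoff = 0.3)
  cur <- predict(fit, env)
  fut <- predict(fit, env_stack(env$grid, env$layers))
  expect_equal(cur$suitability, fut$suitability)
  expect_cells_equal(cur$cells, fut$cells)
})

test_that("a fitted ensemble round-trips through its text dump", {
  env <- gradient_env(20, 20)
  niche <- niche_spec(bounds = list(temp = c(8, 20), prec = c(300, 1500)))
  occ <- simulate_occurrences(niche, env, n_draws = 60, seed = 8)
  fit <- fit_sdm_ensemble(attr(occ, "sampled_cells"), env, seed = 8,
                          q = 0, tss_cutoff = 0.3)
  path <- withr::local_tempfile(fileext = ".yml")
  write_sdm_model(fit, path)
  dump <- yaml::read_yaml(path)
  expect_length(dump$members, length(fit$members))
  expect_equal(dump$members[[1]]$kind, "envelope")
  expect_equal(unlist(dump$members[[1]]$lower),
               stats::setNames(fit$members[[1]]$lower, c("temp", "prec")))
  expect_equal(dump$tss_cutoff, fit$tss_cutoff)
})
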