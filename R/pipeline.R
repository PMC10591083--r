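stop_classed <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}
stop_config <- function(msg) stop_classed("cwrgap_config_error", msg)
stop_data <- function(msg) stop_classed("cwrgap_data_error", msg)
stop_dependency <- function(msg) stop_classed("cwrgap_dependency_error", msg)

#' Read and validate a pipeline run configuration
#'
#' The run configuration is a single YAML document. Recognised keys:
#' `out_dir` (required); `paths` (`registry`, `passport`, `occurrences`,
#' `env_current` -- vector of ASCII-grid files --, `env_future` -- a map
#' scenario name to file vector); `region` (`[lon_min, lon_max, lat_min,
#' lat_max]`, default the European/Mediterranean window 32W-62E, 20-72N);
#' `sdm` (settings for [fit_sdm_ensemble()] plus `min_cells`); `rules`
#' (arguments of [rule_config()], `exclusions` as a list); `seed`.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return Validated config list (class `run_config`). Referenced paths
#'   that do not exist raise a config error naming the field.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop_config(paste0("config file not found: ",
                                                 config))
    yaml::read_yaml(config)
  } else config
  if (is.null(cfg$out_dir)) stop_config("config field missing: out_dir")
  if (is.null(cfg$seed)) cfg$seed <- 1
  if (is.null(cfg$region)) cfg$region <- c(-32, 62, 20, 72)
  if (length(cfg$region) != 4) stop_config("config field invalid: region")
  sdm_defaults <- list(n_pa_sets = 3, q = 2.5, quadratic = TRUE,
                       tss_cutoff = 0.7, split = 0.3, reps = 5,
                       min_cells = 10)
  cfg$sdm <- utils::modifyList(sdm_defaults, cfg$sdm %||% list())
  check_path <- function(p, field) {
    for (f in p) if (!file.exists(f)) {
      stop_config(paste0("config path does not exist (", field, "): ", f))
    }
  }
  for (field in c("registry", "passport", "occurrences")) {
    if (!is.null(cfg$paths[[field]])) check_path(cfg$paths[[field]], field)
  }
  if (!is.null(cfg$paths$env_current)) {
    check_path(cfg$paths$env_current, "env_current")
  }
  for (sc in names(cfg$paths$env_future)) {
    check_path(cfg$paths$env_future[[sc]], paste0("env_future/", sc))
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_line <- function(state, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  cat(line, file = state$log, sep = "\n", append = TRUE)
  message(line)
}

write_manifest <- function(cfg) {
  inputs <- unlist(cfg$paths, use.names = TRUE)
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  yaml::write_yaml(list(
    package = "cwrgap",
    version = as.character(utils::packageVersion("cwrgap")),
    seed = cfg$seed,
    config = unclass(cfg),
    input_md5 = sums
  ), file.path(cfg$out_dir, "run_manifest.yml"))
}

stage_gap_report <- function(cfg, state) {
  if (is.null(cfg$paths$registry) || is.null(cfg$paths$passport)) {
    stop_config("gap-report needs paths: registry and passport")
  }
  reg <- load_registry(cfg$paths$registry)
  rec <- parse_passport(cfg$paths$passport)
  log_line(state, "gap-report", sprintf("%d passport records, %d taxa",
                                        nrow(rec), nrow(reg$taxa)))
  stats <- native_collected_counts(rec, reg)
  un <- attr(stats, "unmatched")
  if (nrow(un)) log_line(state, "gap-report",
                         sprintf("%d unmatched label(s) dropped", sum(un$n)))
  summ <- summarize_gene_pool(stats, reg)
  paths <- write_gap_report(summ, file.path(cfg$out_dir, "gap"))
  utils::write.table(stats, file.path(cfg$out_dir, "gap", "stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line(state, "gap-report", paste("wrote", paste(basename(paths),
                                                     collapse = ", ")))
}

stage_sdm <- function(cfg, state) {
  p <- cfg$paths
  if (is.null(p$occurrences) || is.null(p$env_current) ||
      is.null(p$env_future)) {
    stop_config("sdm needs paths: occurrences, env_current, env_future")
  }
  env_cur <- read_env_stack(p$env_current)
  occ <- read_occurrences(p$occurrences)
  sdm_dir <- file.path(cfg$out_dir, "sdm")
  dir.create(sdm_dir, showWarnings = FALSE, recursive = TRUE)
  proj_rows <- list()
  reason_rows <- list()
  for (tx in unique(occ$taxon_name)) {
    sub <- occ[occ$taxon_name == tx, , drop = FALSE]
    cl <- clean_occurrences(sub, cfg$region)
    log_line(state, "sdm", sprintf("%s: %d records, %d rejected", tx,
                                   nrow(sub), nrow(cl$rejected)))
    cells <- thin_cells(dedupe_cells(cl$records, env_cur$grid))
    log_line(state, "sdm", sprintf("%s: %d cells after dedupe+thin", tx,
                                   nrow(cells)))
    if (!is_modellable(cells, cfg$sdm$min_cells)) {
      reason_rows[[tx]] <- data.frame(taxon = tx,
                                      reason = "insufficient_records")
      next
    }
    fit <- fit_sdm_ensemble(cells, env_cur, n_pa_sets = cfg$sdm$n_pa_sets,
                            q = cfg$sdm$q, quadratic = cfg$sdm$quadratic,
                            tss_cutoff = cfg$sdm$tss_cutoff,
                            split = cfg$sdm$split, reps = cfg$sdm$reps,
                            seed = cfg$seed)
    log_line(state, "sdm", sprintf("%s: %d/%d members admitted", tx,
                                   length(fit$admitted),
                                   length(fit$members)))
    write_sdm_model(fit, file.path(sdm_dir, paste0(
      gsub("[^A-Za-z0-9]+", "_", tx), "_model.yml")))
    add <- function(scenario, cells) {
      if (!nrow(cells)) return()
      proj_rows[[length(proj_rows) + 1]] <<-
        data.frame(taxon = tx, scenario = scenario,
                   row = cells[, 1], col = cells[, 2])
    }
    add("current", predict(fit, env_cur)$cells)
    for (sc in names(p$env_future)) {
      env_fut <- read_env_stack(p$env_future[[sc]])
      add(sc, predict(fit, env_fut)$cells)
    }
  }
  proj <- do.call(rbind, c(proj_rows, list(
    data.frame(taxon = character(0), scenario = character(0),
               row = integer(0), col = integer(0)))))
  utils::write.table(proj, file.path(sdm_dir, "projections.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  reasons <- do.call(rbind, c(reason_rows, list(
    data.frame(taxon = character(0), reason = character(0)))))
  utils::write.table(reasons, file.path(sdm_dir, "unmodelled.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line(state, "sdm", "wrote projections.tsv, unmodelled.tsv")
}

stage_range_change <- function(cfg, state) {
  sdm_dir <- file.path(cfg$out_dir, "sdm")
  pf <- file.path(sdm_dir, "projections.tsv")
  if (!file.exists(pf)) {
    stop_dependency("range-change needs the sdm stage artifact (projections.tsv); run `sdm` first")
  }
  proj <- utils::read.delim(pf, stringsAsFactors = FALSE)
  reasons <- utils::read.delim(file.path(sdm_dir, "unmodelled.tsv"),
                               stringsAsFactors = FALSE)
  scenarios <- setdiff(unique(proj$scenario), "current")
  projections <- list()
  for (tx in unique(proj$taxon)) {
    sub <- proj[proj$taxon == tx, , drop = FALSE]
    cur <- cell_set(sub[sub$scenario == "current", c("row", "col")])
    fut <- lapply(stats::setNames(scenarios, scenarios), function(sc) {
      cell_set(sub[sub$scenario == sc, c("row", "col")])
    })
    projections[[tx]] <- list(current = cur, future = fut)
  }
  for (i in seq_len(nrow(reasons))) {
    projections[[reasons$taxon[i]]] <- list(reason = reasons$reason[i])
  }
  tab <- build_range_table(projections, scenarios = scenarios)
  utils::write.table(tab, file.path(cfg$out_dir, "range_change.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line(state, "range-change", sprintf("wrote range_change.tsv (%d taxa)",
                                          nrow(tab)))
}

stage_priority <- function(cfg, state) {
  if (is.null(cfg$paths$registry)) stop_config("priority needs paths: registry")
  stats_f <- file.path(cfg$out_dir, "gap", "stats.tsv")
  if (!file.exists(stats_f)) {
    stop_dependency("priority needs the gap-report stage artifact (gap/stats.tsv); run `gap-report` first")
  }
  range_f <- file.path(cfg$out_dir, "range_change.tsv")
  if (!file.exists(range_f)) {
    stop_dependency("priority needs the range-change stage artifact (range_change.tsv); run `range-change` first")
  }
  reg <- load_registry(cfg$paths$registry)
  stats <- utils::read.delim(stats_f, stringsAsFactors = FALSE)
  rng <- utils::read.delim(range_f, stringsAsFactors = FALSE)
  rules <- do.call(rule_config, cfg$rules %||% list())
  tab <- build_priority_table(reg, stats, rng, rules)
  utils::write.table(tab, file.path(cfg$out_dir, "priority.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(rules), file.path(cfg$out_dir, "priority_rules.yml"))
  cts <- attr(tab, "counts")
  log_line(state, "priority", paste(names(cts), as.integer(cts),
                                    sep = "=", collapse = " "))
}

stage_simulate <- function(cfg, state) {
  dir <- file.path(cfg$out_dir, "simulated")
  made <- make_demo_inputs(dir, seed = cfg$seed)
  log_line(state, "simulate", paste("wrote synthetic inputs under", dir))
  made
}

#' Run the gap-analysis pipeline
#'
#' Orchestrates the stages over on-disk artifacts so they can be run
#' individually and chained: `gap-report` (passport statistics),
#' `sdm` (ensemble fitting and projection per taxon), `range-change`
#' (range metrics from projections), `priority` (collecting priorities),
#' `simulate` (synthetic demo inputs), or `all`. A run manifest (config
#' echo, seed, package version, input checksums) and a log are written to
#' `out_dir`; identical config and seed give identical artifacts.
#'
#' @param config a config list or YAML path, see [read_run_config()].
#' @param command one of `"gap-report"`, `"sdm"`, `"range-change"`,
#'   `"priority"`, `"simulate"`, `"all"`.
#' @return `out_dir`, invisibly. Errors are classed:
#'   `cwrgap_config_error`, `cwrgap_data_error`, `cwrgap_dependency_error`.
#' @export
run_pipeline <- function(config, command = "all") {
  command <- match.arg(command, c("all", "gap-report", "sdm", "range-change",
                                  "priority", "simulate"))
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(log = file.path(cfg$out_dir, "run.log"))
  write_manifest(cfg)
  stages <- if (command == "all") {
    c("gap-report", "sdm", "range-change", "priority")
  } else command
  for (st in stages) {
    switch(st,
           "gap-report" = stage_gap_report(cfg, state),
           "sdm" = stage_sdm(cfg, state),
           "range-change" = stage_range_change(cfg, state),
           "priority" = stage_priority(cfg, state),
           "simulate" = stage_simulate(cfg, state))
  }
  invisible(cfg$out_dir)
}

#' Generate a self-contained synthetic demo dataset and config
#'
#' Builds a small landscape (two gradient layers), an envelope-niche taxon
#' with simulated occurrences, a prescribed warming shift as the future
#' scenario, a three-taxon registry and a synthetic passport file, and a
#' ready-to-run YAML config pointing at them. Everything is a pure
#' function of the seed.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return Path of the written config file.
#' @export
make_demo_inputs <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- grid_spec(lon_min = 0, lat_max = 45, res_arcmin = 15,
                 n_rows = 60, n_cols = 80)
  stacks <- make_env_stack(g, layers = list(
    temp = list(kind = "lon_gradient", range = c(0, 30)),
    prec = list(kind = "lat_gradient", range = c(200, 1200))
  ), shift = c(temp = 3), seed = seed)
  cur_dir <- file.path(dir, "env_current")
  fut_dir <- file.path(dir, "env_rcp85")
  write_env_stack(stacks$current, cur_dir)
  write_env_stack(stacks$future, fut_dir)
  niche <- niche_spec(bounds = list(temp = c(8, 10 + 11.4),
                                    prec = c(400, 900)))
  occ <- simulate_occurrences(niche, stacks$current, n_draws = 400,
                              seed = seed, taxon_name = "Synthetica exempli")
  utils::write.table(
    data.frame(species = occ$taxon_name, decimalLongitude = occ$lon,
               decimalLatitude = occ$lat),
    file.path(dir, "occurrences.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  reg_tab <- data.frame(
    taxon = c("Synthetica exempli", "Synthetica culta",
              "Synthetica rara"),
    tier = c("tertiary", "primary", "tertiary"),
    cultivation = c("wild", "cultivated", "wild"),
    redlist = c("LC", "NOT_LISTED", "EN"),
    native_countries = c("ESP|FRA|ITA", "", "GRC"),
    synonyms = c("Synthetica exempli Auct.", "", ""),
    note = c("ok", "cultivated", "insufficient_records"))
  utils::write.table(reg_tab, file.path(dir, "registry.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pass_spec <- data.frame(
    taxon = c("Synthetica exempli", "Synthetica exempli",
              "Synthetica exempli Auct.", "Synthetica culta",
              "Synthetica rara"),
    origcty = c("ESP", "DEU", "FRA", NA, "GRC"),
    collected = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    n = c(12, 5, 3, 20, 2))
  make_passport_file(pass_spec, file.path(dir, "passport.tsv"), seed = seed)
  cfg <- list(out_dir = file.path(dir, "out"),
              seed = seed,
              region = c(0, 20, 30, 45),
              paths = list(
                registry = file.path(dir, "registry.tsv"),
                passport = file.path(dir, "passport.tsv"),
                occurrences = file.path(dir, "occurrences.tsv"),
                env_current = as.list(sort(list.files(cur_dir,
                                                      full.names = TRUE))),
                env_future = list("RCP8.5" = as.list(sort(list.files(
                  fut_dir, full.names = TRUE))))),
              sdm = list(tss_cutoff = 0.5, min_cells = 10))
  cfg_path <- file.path(dir, "config.yml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
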