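#' Assemble (or load) a run configuration
#'
#' A run configuration drives the five pipeline stages. It can be given as a
#' YAML file or a list; missing fields take the defaults below, which mirror
#' the study conditions (42 subjects, default task).
#'
#' @param x path to a YAML file, or a named list of overrides.
#' @return a validated list of class `cm_run_config` with fields `task`
#'   (arguments to [task_config()]), `cohort_size`, `specs`, `n_starts`,
#'   `n_boot`, `n_sims`, `glrt_subs`, `sweep_families`, `master_seed`,
#'   `out_dir`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  cfg <- list(task = list(), cohort_size = 42L, specs = MODEL_NAMES,
              n_starts = 5L, n_boot = 1000L, n_sims = 2000L,
              glrt_subs = character(), sweep_families = "mf_ratio",
              master_seed = 1L, out_dir = "creditmap_run")
  for (nm in names(x)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    cfg[[nm]] <- x[[nm]]
  }
  bad <- setdiff(cfg$specs, MODEL_NAMES)
  if (length(bad)) stop("unknown model spec(s) in config: ",
                        paste(bad, collapse = ", "))
  cfg$task <- do.call(task_config, cfg$task)  # validates task fields
  cfg$master_seed <- as.integer(cfg$master_seed)
  structure(cfg, class = "cm_run_config")
}

as_run_config <- function(x) {
  if (inherits(x, "cm_run_config")) x else run_config(x)
}

stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 11L, fit = 23L, compare = 37L, signatures = 53L,
               sweep = 71L)
  as.integer((as.numeric(cfg$master_seed) * 101 + offsets[[stage]]) %%
               (2^31 - 1))
}

sessions_dir <- function(cfg) file.path(cfg$out_dir, "sessions")

load_sessions <- function(cfg) {
  dir <- sessions_dir(cfg)
  files <- sort(list.files(dir, pattern = "^session_.*\\.csv$",
                           full.names = TRUE))
  if (!length(files))
    stop("no session files found at '", dir, "'; run run_simulate() first")
  lapply(files, read_session)
}

#' Pipeline stages
#'
#' `run_simulate()` simulates a synthetic cohort from the full model at
#' heterogeneous generating parameters and writes one CSV (plus JSON
#' sidecar) per subject. `run_fit()` fits the configured model specs to
#' every session and writes a tidy fit table and evidence matrix.
#' `run_compare()` runs random-effects Bayesian model selection on the
#' evidence (plus bootstrap GLRTs for any `glrt_subs`). `run_signatures()`
#' builds and fits both model-agnostic regressions. `run_sweep()` runs the
#' configured standardized-earnings sweeps. All stages are deterministic
#' given the configuration's `master_seed` and are idempotent.
#'
#' @param cfg a [run_config()] (or list/YAML path coercible to one).
#' @return each stage invisibly returns its main artifact.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(cfg = run_config()) {
  cfg <- as_run_config(cfg)
  set.seed(stage_seed(cfg, "simulate"))
  dir.create(sessions_dir(cfg), recursive = TRUE, showWarnings = FALSE)
  pars <- sample_cohort_params(cfg$cohort_size, "full")
  write.csv(data.frame(subject = seq_len(cfg$cohort_size), pars),
            file.path(cfg$out_dir, "generating_params.csv"),
            row.names = FALSE)
  seeds <- sample.int(.Machine$integer.max - 1L, cfg$cohort_size)
  sessions <- lapply(seq_len(cfg$cohort_size), function(i) {
    ses <- simulate_session(pars[i, ], "full",
                            structure = make_structure(seed = seeds[i]),
                            config = cfg$task, seed = seeds[i])
    write_session(ses, file.path(sessions_dir(cfg),
                                 sprintf("session_%02d.csv", i)))
    ses
  })
  invisible(sessions)
}

#' @rdname pipeline
#' @export
run_fit <- function(cfg = run_config()) {
  cfg <- as_run_config(cfg)
  sessions <- load_sessions(cfg)
  res <- fit_cohort(sessions, cfg$specs, n_starts = cfg$n_starts,
                    seed = stage_seed(cfg, "fit"))
  rows <- do.call(rbind, lapply(seq_along(res$fits), function(i) {
    do.call(rbind, lapply(res$fits[[i]], function(f)
      data.frame(subject = i, spec = f$spec, loglik = f$loglik, k = f$k,
                 n_trials = f$n_trials, converged = f$converged,
                 t(as.numeric(f$params)))))
  }))
  names(rows)[7:18] <- PARAM_NAMES
  write.csv(rows, file.path(cfg$out_dir, "fits.csv"), row.names = FALSE)
  write.csv(data.frame(subject = seq_len(nrow(res$evidence)), res$evidence),
            file.path(cfg$out_dir, "evidence.csv"), row.names = FALSE)
  invisible(res)
}

#' @rdname pipeline
#' @export
run_compare <- function(cfg = run_config()) {
  cfg <- as_run_config(cfg)
  epath <- file.path(cfg$out_dir, "evidence.csv")
  if (!file.exists(epath))
    stop("evidence matrix not found at '", epath, "'; run run_fit() first")
  E <- as.matrix(read.csv(epath)[, -1, drop = FALSE])
  bms <- bms_random_effects(E, seed = stage_seed(cfg, "compare"))
  jsonlite::write_json(
    list(alpha = as.list(bms$alpha), expected_prob = as.list(bms$expected_prob),
         xp = as.list(bms$xp), bor = bms$bor, pxp = as.list(bms$pxp)),
    file.path(cfg$out_dir, "bms.json"), auto_unbox = TRUE, digits = NA)
  glrt <- NULL
  if (length(cfg$glrt_subs)) {
    sessions <- load_sessions(cfg)
    glrt <- lapply(cfg$glrt_subs, function(sub)
      bootstrap_glrt(sessions, sub, n_boot = cfg$n_boot,
                     n_starts = cfg$n_starts,
                     seed = stage_seed(cfg, "compare")))
    names(glrt) <- cfg$glrt_subs
    gl <- do.call(rbind, lapply(names(glrt), function(nm)
      data.frame(sub_spec = nm, group_statistic = glrt[[nm]]$group_statistic,
                 group_p = glrt[[nm]]$group_p, n_boot = glrt[[nm]]$n_boot)))
    write.csv(gl, file.path(cfg$out_dir, "glrt.csv"), row.names = FALSE)
  }
  invisible(list(bms = bms, glrt = glrt))
}

#' @rdname pipeline
#' @export
run_signatures <- function(cfg = run_config()) {
  cfg <- as_run_config(cfg)
  sessions <- load_sessions(cfg)
  set.seed(stage_seed(cfg, "signatures"))
  rep_tab <- build_repetition_table(sessions)
  side_tab <- build_sidechoice_table(sessions)
  rep_fit <- fit_repetition_model(rep_tab)
  side_fit <- fit_sidechoice_model(side_tab)
  write.csv(rep_tab, file.path(cfg$out_dir, "repetition_table.csv"),
            row.names = FALSE)
  write.csv(side_tab, file.path(cfg$out_dir, "sidechoice_table.csv"),
            row.names = FALSE)
  write.csv(rep_fit, file.path(cfg$out_dir, "repetition_effects.csv"),
            row.names = FALSE)
  write.csv(side_fit, file.path(cfg$out_dir, "sidechoice_effects.csv"),
            row.names = FALSE)
  report <- signature_report(rep_fit, side_fit)
  jsonlite::write_json(report, file.path(cfg$out_dir, "signatures.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(list(rep_fit = rep_fit, side_fit = side_fit, report = report))
}

#' @rdname pipeline
#' @export
run_sweep <- function(cfg = run_config()) {
  cfg <- as_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  grids <- lapply(cfg$sweep_families, function(fam)
    sweep_regime(fam, config = cfg$task, n_sims = cfg$n_sims,
                 seed = stage_seed(cfg, "sweep")))
  names(grids) <- cfg$sweep_families
  for (fam in cfg$sweep_families) {
    write.csv(grids[[fam]]$cells,
              file.path(cfg$out_dir, paste0("earnings_", fam, ".csv")),
              row.names = FALSE)
  }
  invisible(grids)
}
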