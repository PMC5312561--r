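#' Derive a reproducible child seed
#'
#' Seeds form a hierarchy master -> scenario -> replicate, so that any
#' single replicate of any scenario can be regenerated in isolation and
#' results are independent of execution order or parallelism. The mixing
#' uses two rounds of a multiplicative congruential step modulo
#' \eqn{2^{31}-1}, keeping every derived seed a valid 32-bit integer.
#'
#' @param master_seed Integer master seed.
#' @param scenario_index 1-based position of the scenario in the grid.
#' @param rep_index 1-based replicate number.
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(master_seed, scenario_index, rep_index) {
  m <- 2147483647
  s <- (abs(as.numeric(master_seed)) %% m)
  s <- (s * 48271 + as.numeric(scenario_index)) %% m
  s <- (s * 48271 + as.numeric(rep_index)) %% m
  as.integer(s + 1)
}

#' Canonical integer key of a scenario
#'
#' A deterministic hash of the scenario's scientific content (sizes, truth,
#' variances, generation mode — not `n_reps` or `seed`), used to seed its
#' replicate stream. Keying on content rather than grid position makes
#' every result invariant to the order scenarios are listed or executed in.
#'
#' @param scenario A [scenario_config()].
#' @return An integer in \[1, 2^31 - 2\].
#' @export
scenario_key <- function(scenario) {
  m <- 2147483647
  vals <- c(scenario$n_studies, scenario$total_size,
            match(scenario$size_scheme, c("balanced", "imbalanced")),
            round(scenario$beta0 * 1e6), round(scenario$beta1 * 1e6),
            round(scenario$tau0_sq * 1e6), round(scenario$tau1_sq * 1e6),
            round(scenario$rho * 1e6),
            match(scenario$generation_mode,
                  c("random_intercept", "stratified_intercept")))
  s <- 0
  for (v in vals) s <- (s * 48271 + (v %% m + m) %% m) %% m
  as.integer(s + 1)
}

#' Bundle a full simulation experiment
#'
#' @param grid List of [scenario_config()] objects.
#' @param methods Character subset of `c("DL", "BIVREML", "PQL_M3",
#'   "PQL_M4", "AGHQ_M3", "AGHQ_M4")`.
#' @param master_seed Integer master seed.
#' @param output_dir Optional directory for checkpoints and result tables;
#'   `NULL` keeps everything in memory.
#' @return An object of class `"run_manifest"`.
#' @export
run_manifest <- function(grid, methods = c("DL", "PQL_M3"),
                         master_seed = 1L, output_dir = NULL) {
  stopifnot(length(grid) >= 1, length(methods) >= 1)
  methods <- match.arg(methods, c("DL", "BIVREML", "PQL_M3", "PQL_M4",
                                  "AGHQ_M3", "AGHQ_M4"),
                       several.ok = TRUE)
  for (sc in grid) stopifnot(inherits(sc, "scenario_config"))
  if (!is.null(output_dir)) {
    ok <- dir.exists(output_dir) ||
      dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || file.access(output_dir, 2) != 0)
      stop("output directory is not writable: ", output_dir, call. = FALSE)
  }
  structure(list(grid = grid, methods = methods,
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = "run_manifest")
}

failed_fit <- function(method, msg) {
  new_pooled_fit(method, converged = FALSE,
                 messages = paste0("estimator error: ", msg))
}

#' Generate and analyze one Monte-Carlo replicate
#'
#' Draws one dataset from the replicate's child seed and fits every
#' requested method to that same dataset (a paired design: all methods see
#' identical data). Estimator errors are caught and recorded as
#' non-converged fits; they never abort the run. The two-stage methods
#' share a single first-stage pass.
#'
#' @param scenario A [scenario_config()].
#' @param rep_index Replicate number (1-based).
#' @param methods Character vector of method labels; see [fit_method()].
#' @param master_seed Master seed of the experiment.
#' @param scenario_index Position of the scenario in the grid (seeds the
#'   replicate together with `master_seed` and `rep_index`).
#' @return Named list of `pooled_fit` objects, one per method, with the
#'   dataset attached as attribute `"dataset"`.
#' @export
run_replicate <- function(scenario, rep_index, methods,
                          master_seed = scenario$seed,
                          scenario_index = scenario_key(scenario)) {
  if (is.na(master_seed)) stop("no master seed available", call. = FALSE)
  set.seed(child_seed(master_seed, scenario_index, rep_index))
  dataset <- generate_dataset(scenario)
  first_stage <- NULL
  if (any(methods %in% c("DL", "BIVREML")))
    first_stage <- tryCatch(fit_all_studies(dataset),
                            error = function(e) e)
  fits <- lapply(methods, function(m) {
    if (m %in% c("DL", "BIVREML") && inherits(first_stage, "error"))
      return(failed_fit(m, conditionMessage(first_stage)))
    tryCatch(fit_method(dataset, m, first_stage = first_stage),
             error = function(e) failed_fit(m, conditionMessage(e)))
  })
  names(fits) <- methods
  attr(fits, "dataset") <- dataset
  fits
}

#' Run a full simulation experiment
#'
#' Iterates scenarios and replicates, fits all requested methods per
#' replicate, and aggregates per (scenario x method) performance summaries.
#' With an `output_dir`, each scenario's replicate-level fit table is
#' checkpointed as tab-separated text when completed, interrupted runs
#' resume from existing checkpoints, and the final summary table is written
#' alongside them. Results are bit-identical for a given master seed
#' regardless of scenario order.
#'
#' @param manifest A [run_manifest()].
#' @param progress Print per-scenario progress to stderr.
#' @return List with `summaries` (list of `performance_summary`) and
#'   `table` (the flattened [performance_table()]).
#' @export
run_experiment <- function(manifest, progress = FALSE) {
  stopifnot(inherits(manifest, "run_manifest"))
  grid <- manifest$grid
  summaries <- list()
  for (si in seq_along(grid)) {
    sc <- grid[[si]]
    ckpt <- NULL
    if (!is.null(manifest$output_dir))
      ckpt <- file.path(manifest$output_dir,
                        sprintf("scenario_%03d_fits.tsv", si))
    if (!is.null(ckpt) && file.exists(ckpt)) {
      fit_tab <- read.table(ckpt, header = TRUE, sep = "\t")
    } else {
      rows <- vector("list", sc$n_reps * length(manifest$methods))
      ri <- 0L
      for (r in seq_len(sc$n_reps)) {
        fits <- run_replicate(sc, r, manifest$methods,
                              master_seed = manifest$master_seed,
                              scenario_index = scenario_key(sc))
        tab <- pooled_fits_table(fits)
        tab$rep <- r
        for (m in seq_len(nrow(tab))) {
          ri <- ri + 1L
          rows[[ri]] <- tab[m, ]
        }
        if (progress && r %% 100 == 0)
          message(sprintf("scenario %d/%d: replicate %d/%d",
                          si, length(grid), r, sc$n_reps))
      }
      fit_tab <- do.call(rbind, rows)
      if (!is.null(ckpt))
        write.table(fit_tab, ckpt, sep = "\t", row.names = FALSE,
                    quote = FALSE)
    }
    for (m in manifest$methods) {
      sub <- fit_tab[fit_tab$method == m, ]
      fits <- lapply(seq_len(nrow(sub)), function(i) {
        new_pooled_fit(m, beta1_hat = sub$beta1_hat[i],
                       se_beta1 = sub$se_beta1[i],
                       tau1_sq_hat = sub$tau1_sq_hat[i],
                       se_tau1_sq = sub$se_tau1_sq[i],
                       converged = sub$converged[i])
      })
      summaries[[paste0("scenario", si, "_", m)]] <-
        summarize_fits(fits, sc)
    }
    if (progress)
      message(sprintf("scenario %d/%d done", si, length(grid)))
  }
  tab <- performance_table(summaries)
  if (!is.null(manifest$output_dir))
    write.table(tab, file.path(manifest$output_dir, "performance.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  list(summaries = summaries, table = tab)
}
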