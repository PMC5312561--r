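test_that("replicates are deterministic and paired across methods", {
  sc <- scenario_config(5, 250, "balanced", n_reps = 3)
  f1 <- run_replicate(sc, 2, c("DL", "BIVREML"), master_seed = 7,
                      scenario_index = 1)
  f2 <- run_replicate(sc, 2, c("DL", "BIVREML"), master_seed = 7,
                      scenario_index = 1)
  expect_identical(f1$DL$beta1_hat, f2$DL$beta1_hat)
  expect_identical(f1$BIVREML$beta1_hat, f2$BIVREML$beta1_hat)
  # both methods saw the same dataset
  expect_identical(attr(f1, "dataset"), attr(f2, "dataset"))

  only_dl <- run_replicate(sc, 1, "DL", master_seed = 7, scenario_index = 1)
  expect_length(only_dl, 1)
  expect_named(only_dl, "DL")
})

test_that("an estimator failure is recorded, not fatal", {
  sc <- scenario_config(5, 250, "balanced", n_reps = 1)
  local_mocked_bindings(
    fit_pql = function(...) stop("synthetic divergence"),
    .package = "ipdmasim")
  fits <- run_replicate(sc, 1, c("DL", "PQL_M3"), master_seed = 3,
                        scenario_index = 1)
  expect_true(fits$DL$converged)
  expect_false(fits$PQL_M3$converged)
  expect_match(paste(fits$PQL_M3$messages, collapse = " "),
               "synthetic divergence")
})

test_that("experiments reproduce bit-identically from the master seed", {
  grid <- build_scenario_grid(
    sizes = list(list(5, 150, "balanced"), list(6, 180, "balanced")),
    tau0_sq = 1, tau1_sq = 1, rho = 0.5,
    generation_mode = "random_intercept", n_reps = 8)
  man <- function(dir) run_manifest(grid, methods = c("DL", "BIVREML"),
                                    master_seed = 11, output_dir = dir)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_experiment(man(d1))
  r2 <- run_experiment(man(d2))
  expect_equal(length(r1$summaries), 4)
  expect_true(all(r1$table$n_reps_attempted == 8))
  f1 <- file.path(d1, "performance.tsv")
  f2 <- file.path(d2, "performance.tsv")
  expect_identical(readLines(f1), readLines(f2))

  # scenario order does not change any summary
  man_rev <- run_manifest(rev(grid), methods = c("DL", "BIVREML"),
                          master_seed = 11)
  r3 <- run_experiment(man_rev)
  s_fwd <- r1$summaries[["scenario1_DL"]]
  s_rev <- r3$summaries[["scenario2_DL"]]
  expect_equal(s_fwd$stats, s_rev$stats)
})

test_that("extending the replicate stream preserves its prefix", {
  sc_small <- scenario_config(5, 150, "balanced", n_reps = 4)
  sc_big <- scenario_config(5, 150, "balanced", n_reps = 8)
  fits_small <- lapply(1:4, function(r)
    run_replicate(sc_small, r, "DL", master_seed = 5, scenario_index = 1))
  fits_big <- lapply(1:8, function(r)
    run_replicate(sc_big, r, "DL", master_seed = 5, scenario_index = 1))
  for (r in 1:4)
    expect_identical(fits_small[[r]]$DL$beta1_hat,
                     fits_big[[r]]$DL$beta1_hat)
})

test_that("checkpoints allow resuming an interrupted run", {
  grid <- build_scenario_grid(sizes = list(list(5, 150, "balanced")),
                              tau0_sq = 1, tau1_sq = 1, rho = 0,
                              generation_mode = "random_intercept",
                              n_reps = 5)
  dir <- withr::local_tempdir()
  man <- run_manifest(grid, methods = "DL", master_seed = 2,
                      output_dir = dir)
  r1 <- run_experiment(man)
  ckpt <- file.path(dir, "scenario_001_fits.tsv")
  expect_true(file.exists(ckpt))
  mtime <- file.mtime(ckpt)
  r2 <- run_experiment(man)  # must reuse, not recompute, the checkpoint
  expect_identical(file.mtime(ckpt), mtime)
  expect_equal(r1$table, r2$table)

  expect_error(run_manifest(grid, methods = "DL",
                            output_dir = "/proc/definitely/not/writable"),
               "not writable")
})
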