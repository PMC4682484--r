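test_that("case enumeration matches the study grids", {
  cfg <- experiment_config()
  cases <- enumerate_cases(cfg)
  expect_equal(sum(cases$kind == "random"), 15L)   # 3 distributions x 5 phi
  for (type in c("square", "hexagonal"))
    expect_equal(sum(cases$kind == "regular" & cases$packing_type == type),
                 40L)                               # 5 R_tilde x 8 p
  expect_false(any(duplicated(cases$case_id)))

  # empty phi set: no random cases, no error
  cfg0 <- experiment_config(phi = numeric(0))
  expect_equal(sum(enumerate_cases(cfg0)$kind == "random"), 0L)

  # deterministic ordering
  expect_identical(cases$case_id, enumerate_cases(cfg)$case_id)
})

test_that("the free-diffusion control case has residuals consistent with zero", {
  cfg <- experiment_config(n_walkers = 3000, n_steps = 20000, n_freq = 4,
                           seed = 6)
  cmp <- run_comparison(list(kind = "free", case_id = "free"), cfg)
  expect_true(all(abs(cmp$z) < 3))
})

test_that("recovery tables flag mis-specified packing types", {
  cfg <- experiment_config()
  case <- list(case_id = "square_Rt0.5_p1.12", kind = "regular",
               packing_type = "square", R_tilde = 0.5, p = 1.12)
  rec <- run_recovery(case, cfg)
  expect_true(all(abs(rec$rel_error) < 0.1))
  # fitting under the wrong lattice must not silently succeed
  rec_bad <- tryCatch(run_recovery(case, cfg, fit_type = "hexagonal"),
                      error = function(e) e)
  if (inherits(rec_bad, "error")) {
    expect_match(conditionMessage(rec_bad), "out-of-model")
  } else {
    expect_gt(max(abs(rec_bad$rel_error)), 0.1)
  }
})

test_that("experiment outputs are reproduced byte-identically from the manifest seed", {
  cfg <- experiment_config(R_tilde = 0.5, p = 1.5,
                           packing_types = "square",
                           phi = numeric(0), n_walkers = 200,
                           n_steps = 4000, n_freq = 3, seed = 12,
                           outdir = tempfile("exp"))
  m1 <- suppressWarnings(run_experiment(cfg))
  f <- file.path(cfg$outdir, "square_Rt0.5_p1.5_residuals.csv")
  expect_true(file.exists(f))
  bytes1 <- readBin(f, "raw", file.size(f))
  cfg2 <- cfg; cfg2$outdir <- tempfile("exp2")
  m2 <- suppressWarnings(run_experiment(cfg2))
  bytes2 <- readBin(file.path(cfg2$outdir, "square_Rt0.5_p1.5_residuals.csv"),
                    "raw", file.size(f))
  expect_identical(bytes1, bytes2)
  expect_identical(m1$config_hash, m2$config_hash)
  expect_true(file.exists(file.path(cfg$outdir, "manifest.json")))
})

test_that("experiment configs round-trip through YAML", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("packing_types: [square]",
               "R_tilde: [0.5, 1]",
               "p: [1.12, 1.5]",
               "phi: [0.5]",
               "multipliers: [1]",
               "n_walkers: 100",
               "seed: 4",
               "dist: {shape: 3.3, scale: 0.18, multiplier: 1}"), y)
  cfg <- read_experiment_config(y)
  expect_s3_class(cfg, "experiment_config")
  cases <- enumerate_cases(cfg)
  expect_equal(nrow(cases), 2 * 2 + 1)
})
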