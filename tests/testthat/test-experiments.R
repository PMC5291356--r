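# a compact two-pattern library shared across the experiment tests
tiny_patterns <- function() {
  list(
    hbar = pattern_recipe("bar_set", uid = "hbar", bars = list(
      list(angle = 0, length = 100, width = 20))),
    vbar = pattern_recipe("bar_set", uid = "vbar", bars = list(
      list(angle = 90, length = 100, width = 20))),
    obar = pattern_recipe("bar_set", uid = "obar", bars = list(
      list(angle = 45, length = 100, width = 20)))
  )
}

test_that("a noise-free trial with TS_COR identical to CS+ scores 1", {
  pats <- tiny_patterns()
  sp <- experiment_spec("t", "hbar", "hbar", "vbar", "DISTINCT")
  k <- run_trial(sp, pats, nonoise())
  expect_equal(k, 1)
})

test_that("trials and experiments are reproducible under a fixed seed", {
  pats <- tiny_patterns()
  sp <- experiment_spec("t", "hbar", "hbar", "vbar", "MERGED",
                        n_trials = 50)
  r1 <- run_experiment(sp, pats, seed = 123)
  r2 <- run_experiment(sp, pats, seed = 123)
  expect_identical(r1$trials, r2$trials)
  set.seed(9); k1 <- run_trial(sp, pats)
  set.seed(9); k2 <- run_trial(sp, pats)
  expect_identical(k1, k2)
})

test_that("experiment aggregation follows the protocol", {
  pats <- tiny_patterns()
  sp1 <- experiment_spec("t", "hbar", "hbar", "vbar", "DISTINCT",
                         n_trials = 1)
  r1 <- run_experiment(sp1, pats, seed = 5)
  expect_equal(r1$mean, r1$min)
  expect_equal(r1$mean, r1$max)
  expect_equal(r1$performance, 100 * r1$mean)
  sp <- experiment_spec("t", "hbar", "hbar", "vbar", "DISTINCT",
                        n_trials = 200)
  r <- run_experiment(sp, pats, seed = 6)
  expect_lte(r$min, r$mean); expect_lte(r$mean, r$max)
  expect_gte(r$performance, 0); expect_lte(r$performance, 100)
  expect_error(experiment_spec("t", "hbar", "vbar", "vbar"), "differ")
})

test_that("role-swapped performances sum to 100 within Monte-Carlo error", {
  pats <- tiny_patterns()
  fwd <- experiment_spec("f", "hbar", "obar", "vbar", "MERGED",
                         n_trials = 400)
  rev <- experiment_spec("r", "hbar", "vbar", "obar", "MERGED",
                         n_trials = 400)
  pf <- run_experiment(fwd, pats, seed = 21)$performance
  pr <- run_experiment(rev, pats, seed = 22)$performance
  expect_equal(pf + pr, 100, tolerance = 0.03)
})

test_that("Monte-Carlo means converge with trial count", {
  pats <- tiny_patterns()
  sp_small <- experiment_spec("t", "hbar", "obar", "vbar", "DISTINCT",
                              n_trials = 250)
  sp_big <- experiment_spec("t", "hbar", "obar", "vbar", "DISTINCT",
                            n_trials = 1000)
  r_small <- run_experiment(sp_small, pats, seed = 33)
  r_big <- run_experiment(sp_big, pats, seed = 33)
  se <- r_big$sd / sqrt(r_small$n_trials)
  expect_lt(abs(r_small$mean - r_big$mean), 4 * se)
})

test_that("generalization enumeration averages the per-triplet means", {
  pats <- tiny_patterns()
  # single CS+ with no reciprocal set reduces to a plain experiment
  g1 <- run_generalization("hbar", cor = "hbar", inc = "vbar",
                           model = "DISTINCT", patterns = pats,
                           n_trials = 60, seed = 41)
  sp <- experiment_spec("t", "hbar", "hbar", "vbar", "DISTINCT",
                        n_trials = 60)
  e1 <- run_experiment(sp, pats, seed = 41)
  expect_equal(g1$mean, e1$mean)
  # pooled mean equals the mean of per-triplet means (equal trials)
  g <- run_generalization(c("hbar", "obar"), cor = "hbar", inc = "vbar",
                          reciprocal_set = "vbar",
                          model = "MERGED", patterns = pats,
                          n_trials = 40, seed = 42)
  expect_length(g$triplets, 3)
  expect_equal(g$mean,
               mean(vapply(g$triplets, `[[`, numeric(1), "mean")))
  expect_error(run_generalization(character(0), cor = "a", inc = "b",
                                  patterns = pats), "empty")
})

test_that("offset sweeps agree with plain runs at zero offset", {
  pats <- tiny_patterns()
  sw <- run_offset_sweep("hbar", "hbar", "vbar", "DISTINCT", pats,
                         offsets = c(-50L, 0L, 50L), n_trials = 80,
                         seed = 50)
  expect_length(sw, 3)
  sp <- experiment_spec("sweep", "hbar", "hbar", "vbar", "DISTINCT",
                        n_trials = 80)
  direct <- run_experiment(sp, pats, seed = 52)  # matches seed + k of sweep
  expect_identical(sw[[2]]$trials, direct$trials)
  expect_equal(vapply(sw, `[[`, numeric(1), "offset"), c(-50, 0, 50))
})

test_that("unresolvable pattern UIDs are reported", {
  sp <- experiment_spec("t", "hbar", "hbar", "nope", "DISTINCT",
                        n_trials = 2)
  expect_error(run_experiment(sp, tiny_patterns(), nonoise()),
               "unresolvable pattern UID")
})

test_that("study files round-trip through YAML and results tabulate", {
  st <- study_crosses()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_study(st, path)
  back <- load_study(path)
  expect_equal(back$study_id, st$study_id)
  expect_equal(back$experiments, st$experiments)
  expect_equal(names(back$recipes), names(st$recipes))
  # re-rendered patterns are pixel-identical
  for (u in names(st$recipes))
    expect_identical(make_pattern(back$recipes[[u]])$pixels,
                     make_pattern(st$recipes[[u]])$pixels)
  # results table: one row per experiment x offset, reproducible by seed
  df1 <- run_study(st, model = "MERGED", n_trials = 20, seed = 61)
  df2 <- run_study(st, model = "MERGED", n_trials = 20, seed = 61)
  expect_identical(df1, df2)
  expect_equal(nrow(df1), length(st$experiments))
  expect_true(all(c("experiment_id", "model", "offset_px", "n_trials",
                    "kcsr_mean", "kcsr_sd", "kcsr_min", "kcsr_max",
                    "performance_pct", "bee_pct", "seed") %in% names(df1)))
  out <- withr::local_tempfile(fileext = ".csv")
  write_results(df1, out)
  expect_equal(nrow(utils::read.csv(out)), nrow(df1))
  # schema violations carry a usable message
  bad <- st; bad$experiments[[1]]$inc <- "missing_uid"
  write_study(bad, path)
  expect_error(load_study(path), "unknown UID")
})

test_that("shipped study files load and reference resolvable recipes", {
  dir <- system.file("extdata", "studies", package = "beekc")
  files <- list.files(dir, full.names = TRUE)
  expect_gte(length(files), 3)
  for (f in files) {
    st <- load_study(f)
    pats <- build_patterns(st)
    expect_true(all(vapply(pats, inherits, TRUE, "stimulus_image")))
  }
})
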