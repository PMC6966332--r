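# Synthetic cohort generator: copula calibration, configuration
# validation, endpoint construction semantics and ground-truth recovery.

test_that("sim_config validates its inputs", {
  expect_error(sim_config(n_patients = 10), "n_patients")
  bad <- default_marker_corr()
  bad[1, 2] <- 0.5 # asymmetric
  expect_error(sim_config(target_corr = bad), "symmetric")
  bad2 <- default_marker_corr()
  diag(bad2)[1] <- 0.9
  expect_error(sim_config(target_corr = bad2), "diagonal")
  expect_error(
    sim_config(true_effects = list(LRC = c(not_a_marker = 1))),
    "unknown variable")
  expect_error(
    sim_config(clinical_spec = list(sex = c(Male = 0.7, Female = 0.5))),
    "sum to 1")
  # a correlation matrix far from PSD is rejected rather than repaired
  m3 <- c("a", "b", "c")
  far <- matrix(c(1, .95, -.95, .95, 1, .95, -.95, .95, 1), 3, 3,
                dimnames = list(m3, m3))
  expect_error(sim_config(marker_names = m3, target_corr = far,
                          clinical_spec = list(), true_effects = list()),
               "positive semi-definite")
})

test_that("independent markers come out uncorrelated", {
  m <- c("m1", "m2", "m3")
  cfg <- sim_config(marker_names = m, target_corr = diag(3),
                    clinical_spec = list(), true_effects = list(), seed = 4)
  sc <- simulate_scores(cfg, n = 5000)
  cm <- cor(as.matrix(sc), method = "spearman")
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)
})

test_that("a single targeted Spearman correlation is recovered", {
  m <- c("a", "b")
  R <- matrix(c(1, 0.57, 0.57, 1), 2, dimnames = list(m, m))
  cfg <- sim_config(marker_names = m, target_corr = R,
                    clinical_spec = list(), true_effects = list(), seed = 9)
  sc <- simulate_scores(cfg, n = 5000)
  # independent oracle: direct rank correlation on the simulated columns
  r_hat <- cor(rank(sc$a), rank(sc$b))
  expect_lt(abs(r_hat - 0.57), 0.05)
})

test_that("per-operation seeding makes simulation piecewise reproducible", {
  cfg <- sim_config(seed = 21)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  sc <- simulate_scores(cfg)
  expect_identical(sc, a[, names(sc)])
})

test_that("cohort invariants hold and marginals match the configuration", {
  cfg <- sim_config(seed = 5)
  co <- simulate_cohort(cfg, n = 2000)
  expect_true(all(co$time_PFS > 0))
  expect_true(all(co$time_PFS <=
                    pmin(co$time_OS, co$time_LRC, co$time_DM) + 1e-12))
  for (e in c("LRC", "DM", "OS", "PFS"))
    expect_true(all(co[[paste0("event_", e)]] %in% 0:1))
  expect_false(anyNA(co))
  # configured cisplatin frequency is the cohort's 126/193
  expect_equal(unname(cfg$clinical_spec$cisplatin[">=200"]), 126 / 193)
  p_hat <- mean(co$cisplatin == ">=200")
  expect_lt(abs(p_hat - 126 / 193), 0.03)
})

test_that("null model yields all-events iid exponential endpoint times", {
  m <- "m"
  cfg <- sim_config(marker_names = m,
                    target_corr = matrix(1, 1, 1, dimnames = list(m, m)),
                    clinical_spec = list(), true_effects = list(),
                    baseline_hazard = c(LRC = 0.3, DM = 0.2),
                    death_rate = 0, censor_rate = 0,
                    follow_up_years = 1e6, seed = 2)
  co <- simulate_cohort(cfg, n = 1500)
  expect_true(all(co$event_LRC == 1))
  expect_true(all(co$event_DM == 1))
  ks <- suppressWarnings(stats::ks.test(co$time_LRC, "pexp", 0.3))
  expect_gt(ks$p.value, 0.01)
  ks2 <- suppressWarnings(stats::ks.test(co$time_DM, "pexp", 0.2))
  expect_gt(ks2$p.value, 0.01)
})

test_that("a step effect reproduces its hazard ratio (events/person-time oracle)", {
  co <- toy_step_cohort(n = 2000, hr = 3, cut_q = 0.5, seed = 3,
                        censor = 0)
  hi <- co$marker > qnorm(0.5)
  # under exponential hazards, events / person-time estimates the rate
  rate <- function(idx) sum(co$event_LRC[idx]) / sum(co$time_LRC[idx])
  ratio <- rate(hi) / rate(!hi)
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 3.6)
})

test_that("unknown effect variables and bad cutoffs are rejected", {
  expect_error(sim_config(true_cutoffs = c(chronic_hypoxia = 1.7)),
               "quantile")
  expect_error(sim_config(true_effects = list(XX = c(CD44 = 1))),
               "endpoint")
})

test_that("simulated expression is monotone in the target scores", {
  sig <- gene_signature("SIG", sprintf("G%02d", 1:20))
  scores <- matrix(c(-2, 0, 2), ncol = 1)
  counts <- simulate_expression(list(sig), scores, n_background_genes = 100,
                                seed = 1)
  expect_true(is.integer(counts))
  expect_true(all(counts >= 0))
  s <- score_rank_set(counts, sig)
  expect_true(all(diff(s) > 0))
})

test_that("zero-amplitude expression carries no signal; default amplitude recovers it", {
  sig <- gene_signature("SIG", sprintf("G%02d", 1:20))
  target <- matrix(rnorm(50, 0, 1), ncol = 1)
  null_counts <- simulate_expression(list(sig), target, amplitude = 0,
                                     n_background_genes = 100, seed = 2)
  s0 <- score_rank_set(null_counts, sig)
  expect_lt(abs(cor(s0, target[, 1], method = "spearman")), 0.3)

  target2 <- matrix(rnorm(100), ncol = 1)
  counts <- simulate_expression(list(sig), target2, amplitude = 2,
                                n_background_genes = 100, seed = 0)
  s1 <- score_rank_set(counts, sig)
  expect_gt(cor(s1, target2[, 1], method = "spearman"), 0.8)
})

test_that("simulate_expression rejects degenerate inputs", {
  expect_error(simulate_expression(list(), matrix(0, 3, 0)), "non-empty")
  expect_error(
    simulate_expression(list(gene_signature("S", "BG00001")),
                        matrix(rnorm(3), ncol = 1)),
    "overlap")
})

test_that("simulation configs round-trip through JSON files", {
  cfg <- sim_config(n_patients = 50, seed = 2,
                    true_cutoffs = c(chronic_hypoxia = 0.75, EMT = "linear"))
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$n_patients, 50)
  expect_equal(back$target_corr, cfg$target_corr)
  expect_equal(back$true_effects, cfg$true_effects)
  expect_equal(back$true_cutoffs[["chronic_hypoxia"]], 0.75)
  expect_equal(back$true_cutoffs[["EMT"]], "linear")
  expect_equal(back$baseline_hazard, cfg$baseline_hazard)
  # identical cohorts from the round-tripped config
  expect_equal(simulate_cohort(back), simulate_cohort(cfg))
  expect_error(read_sim_config("no-such-file.json"), "exist")
})

test_that("cohort tables round-trip through TSV", {
  co <- toy_step_cohort(n = 30, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back)[, sapply(co, is.numeric)],
               as.data.frame(co)[, sapply(co, is.numeric)],
               tolerance = 1e-12)
})
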