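# Regression metrics, thresholds, enrichment factor, screening, objectives,
# ledger and trajectories.

test_that("regression metrics match hand arithmetic", {
  y <- c(0, 1, 2)
  m <- regression_metrics(y, y)
  expect_identical(m$r2, 1)
  expect_identical(m$mse, 0)
  expect_identical(m$mae, 0)

  m <- regression_metrics(y, rep(mean(y), 3))
  expect_equal(m$r2, 0)

  # SSres = 1, SStot = 2
  m <- regression_metrics(c(0, 1, 2), c(0, 1, 1))
  expect_equal(m$mse, 1 / 3)
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$r2, 0.5)

  expect_message(m <- regression_metrics(rep(2, 4), c(1, 2, 3, 2)),
                 "zero-variance")
  expect_true(is.na(m$r2))
})

test_that("score threshold is the lowest-percentile order statistic", {
  set.seed(12)
  scores <- sample(seq(-13, -4, length.out = 1000))
  # rank ceil(0.001 * 1000) = 1: the minimum
  expect_identical(score_threshold(scores, 0.1), min(scores))
  # sort-based oracle at another percentile
  expect_identical(score_threshold(scores, 2.5), sort(scores)[25])
  expect_identical(score_threshold(rep(-7, 50)), -7)
  # published constants served from config
  expect_identical(published_threshold("KIT"), -10.7)
  expect_identical(published_threshold("PARP1"), -12.1)
  expect_identical(published_threshold("PGR"), -10.1)
  expect_error(published_threshold("NOPE"), "no published threshold")
})

test_that("enrichment factor arithmetic and bounds", {
  expect_identical(enrichment_factor(5000L, 5000L, 0.001), 1000)
  expect_identical(enrichment_factor(5000L, 0L, 0.001), 0)
  expect_identical(enrichment_factor(5000L, 50L, 0.001), 10)
  expect_error(enrichment_factor(0L, 0L, 0.001))
  expect_error(enrichment_factor(10L, 1L, 0))
})

test_that("EF of the whole library over itself is exactly 1", {
  for (base in c(0.01, 0.1, 0.3)) {
    n <- 500L
    n_active <- as.integer(round(base * n))
    expect_equal(enrichment_factor(n, n_active, n_active / n), 1)
  }
})

test_that("screening with an oracle ranker achieves the maximum EF", {
  lib <- fixture_library(40L)
  tgt <- make_mini_target_fixture("SCRN")
  backend <- mock_backend()
  # exhaustive docking of the library = ground truth
  truth <- vapply(lib, function(s) {
    suppressMessages(best_score(dock(tgt, s, docking_params(), backend)))
  }, numeric(1))
  thr <- score_threshold(truth, 20)          # top 20 percent are "active"
  base_rate <- mean(truth < thr)
  top_k <- 10L

  oracle_ranker <- function(v) truth[match(v, lib)]
  res <- run_screen(oracle_ranker, lib, tgt, backend, top_k = top_k,
                    threshold = thr, base_rate = base_rate)
  max_active <- min(top_k, sum(truth < thr))
  expect_identical(res$n_active, as.integer(max_active))
  expect_equal(res$ef, enrichment_factor(top_k, max_active, base_rate))

  expect_error(run_screen(oracle_ranker, lib, tgt, backend,
                          top_k = length(lib) + 1L, threshold = thr),
               "exceeds")
})

test_that("a random ranker yields EF near 1 in expectation", {
  lib <- fixture_library(60L)
  tgt <- make_mini_target_fixture("SCRN")
  backend <- mock_backend()
  truth <- vapply(lib, function(s) {
    suppressMessages(best_score(dock(tgt, s, docking_params(), backend)))
  }, numeric(1))
  thr <- score_threshold(truth, 25)
  base_rate <- mean(truth < thr)
  efs <- vapply(1:20, function(seed) {
    set.seed(seed)
    ranker <- function(v) runif(length(v))
    run_screen(ranker, lib, tgt, backend, top_k = 20L, threshold = thr,
               base_rate = base_rate)$ef
  }, numeric(1))
  expect_lt(abs(mean(efs) - 1), 0.35)   # Monte-Carlo tolerance over 20 seeds
})

test_that("QED penalty is linear with the stated endpoints", {
  expect_identical(qed_penalty(0), 10)
  expect_identical(qed_penalty(1), 0)
  expect_identical(qed_penalty(0.75), 2.5)
  expect_identical(qed_penalty(0.5, weight = 4), 2)
  expect_error(qed_penalty(1.2), "out of")
  expect_error(qed_penalty(-0.1), "out of")
})

test_that("objective specs carry the stated targets and constants", {
  f2 <- objective_spec("F2")
  expect_identical(f2$targets, "F2")
  ppar <- objective_spec("PROMISCUOUS_PPAR")
  expect_identical(ppar$targets, c("PPARA", "PPARD", "PPARG"))
  jak <- objective_spec("SELECTIVE_JAK2")
  expect_identical(jak$targets, c("JAK2", "LCK"))
  expect_identical(jak$lck_anchor, -8.1)
  expect_identical(jak$penalty_weight, 10)
  # configuration defaults mirror the benchmark constants
  cfg <- run_config()
  expect_identical(cfg$lck_anchor, -8.1)
  expect_identical(cfg$qed_penalty_weight, 10)
  expect_identical(cfg$budget, 5000L)
  expect_identical(cfg$top_k, 5000L)
})

test_that("objective values follow the three stated forms", {
  f2 <- objective_spec("F2")
  expect_identical(objective_value(f2, c(F2 = -10), qed = 1), -10)
  expect_identical(objective_value(f2, c(F2 = -10), qed = 0.5), -5)

  ppar <- objective_spec("PROMISCUOUS_PPAR")
  expect_identical(
    objective_value(ppar, c(PPARA = -10, PPARD = -9, PPARG = -8), qed = 1), -8)

  jak <- objective_spec("SELECTIVE_JAK2")
  # LCK above the anchor: min picks the anchor, -10 - (-8.1) = -1.9
  expect_equal(objective_value(jak, c(JAK2 = -10, LCK = -7), qed = 1), -1.9)
  # LCK below the anchor: the actual LCK score counts
  expect_equal(objective_value(jak, c(JAK2 = -10, LCK = -9), qed = 1), -1)

  expect_error(objective_value(ppar, c(PPARA = -10), qed = 1), "missing")
})

test_that("objectives are monotone and flat above the LCK anchor", {
  set.seed(61)
  f2 <- objective_spec("F2")
  ppar <- objective_spec("PROMISCUOUS_PPAR")
  jak <- objective_spec("SELECTIVE_JAK2")
  for (rep in 1:50) {
    s <- runif(5, -13, -4)
    names(s) <- c("F2", "PPARA", "PPARD", "PPARG", "JAK2")
    q <- runif(1)
    eps <- runif(1, 0.01, 2)
    # improving any constituent score never worsens F2 / PPAR
    expect_lte(objective_value(f2, c(F2 = s[["F2"]] - eps), q),
               objective_value(f2, c(F2 = s[["F2"]]), q))
    which_p <- sample(c("PPARA", "PPARD", "PPARG"), 1)
    s2 <- s; s2[[which_p]] <- s2[[which_p]] - eps
    expect_lte(objective_value(ppar, s2, q), objective_value(ppar, s, q))
    # JAK2 selectivity: weakening LCK binding above the anchor changes nothing
    lck_hi <- runif(1, -8.1, -4)       # above (weaker than) the anchor
    v1 <- objective_value(jak, c(JAK2 = s[["JAK2"]], LCK = lck_hi), q)
    v2 <- objective_value(jak, c(JAK2 = s[["JAK2"]], LCK = lck_hi + 1), q)
    expect_identical(v1, v2)
  }
})

test_that("the ledger enforces the budget with cache semantics", {
  led <- new_ledger(budget = 5L)
  spec <- objective_spec("F2")
  sf <- function(smiles, target) -9
  qf <- function(s) 0.8
  mols <- c("CCO", "CCC", "CCN", "CCCl", "CCF", "CCBr")
  for (s in mols[1:5]) evaluate_with_budget(led, spec, s, sf, qf)
  expect_identical(ledger_unique_calls(led), 5L)
  expect_identical(ledger_remaining(led), 0L)

  # cache hit: same value, no budget, still recorded as a call
  v <- evaluate_with_budget(led, spec, "CCO", sf, qf)
  expect_equal(v, -9 + 10 * (1 - 0.8))
  expect_identical(ledger_unique_calls(led), 5L)
  expect_identical(nrow(ledger_calls(led)), 6L)

  # the 6th unique molecule exhausts the budget
  expect_error(evaluate_with_budget(led, spec, mols[6], sf, qf),
               class = "BudgetExhausted")

  # failed preparation consumes budget with value +Inf
  led2 <- new_ledger(budget = 2L)
  v <- evaluate_with_budget(led2, spec, "CC.Cl", sf, qf)
  expect_identical(v, Inf)
  expect_identical(ledger_unique_calls(led2), 1L)
})

test_that("call counts are non-decreasing and append-only", {
  led <- new_ledger(10L)
  spec <- objective_spec("F2")
  sf <- function(smiles, target) -8
  qf <- function(s) 1
  counts <- integer(0)
  for (s in c("CCO", "CCO", "CCC", "CCO", "CCN")) {
    evaluate_with_budget(led, spec, s, sf, qf)
    counts <- c(counts, nrow(ledger_calls(led)))
  }
  expect_true(all(diff(counts) == 1L))
})

test_that("trajectories match a brute-force prefix-sort oracle", {
  led <- new_ledger(100L)
  spec <- objective_spec("F2")
  qf <- function(s) 1
  set.seed(9)
  vals <- round(runif(40, -12, -5), 3)
  env <- environment()
  env$i <- 0L
  sf <- function(smiles, target) { vals[[env$i]] }
  mols <- paste0("C", strrep("C", 1:40))
  for (k in 1:40) { env$i <- k; evaluate_with_budget(led, spec, mols[[k]], sf, qf) }

  oracle <- function(v, k) {
    vapply(seq_along(v), function(i) {
      if (i < k) NA_real_ else sort(v[1:i])[k]
    }, numeric(1))
  }
  got <- ledger_calls(led)$value
  expect_equal(trajectory(led, 1L), oracle(got, 1L))
  expect_equal(trajectory(led, 25L), oracle(got, 25L))

  # k = 1 is the running minimum, non-increasing
  t1 <- trajectory(led, 1L)
  expect_true(all(diff(t1) <= 0))
  # order dominance: trajectory(k) >= trajectory(k') for k > k'
  t5 <- trajectory(led, 5L)
  ok <- !is.na(t5)
  expect_true(all(t5[ok] >= t1[ok]))

  # explicit worked example: values 3, 1, 2 with k = 2
  led3 <- new_ledger(10L)
  v3 <- c(3, 1, 2)
  env$j <- 0L
  sf3 <- function(smiles, target) v3[[env$j]]
  for (k in 1:3) { env$j <- k; evaluate_with_budget(led3, spec, mols[[k]], sf3, qf) }
  expect_equal(trajectory(led3, 2L), c(NA, 3, 2))
})

test_that("ledger CSV serialization preserves call order and trajectories", {
  led <- new_ledger(10L)
  spec <- objective_spec("F2")
  sf <- function(smiles, target) -8.5
  for (s in c("CCO", "CCC")) evaluate_with_budget(led, spec, s, sf,
                                                  function(x) 0.9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ledger(led, path)
  df <- read.csv(path)
  expect_identical(nrow(df), 2L)
  expect_identical(df$call_index, 1:2)
  expect_true(all(c("smiles", "value", "best_so_far", "best_25th") %in%
                    names(df)))
})
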