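# Genetic algorithms, BO machinery, similarity search, random baseline.

test_that("graph GA keeps population size, elitism and child validity", {
  lib <- fixture_library(60L)
  sf <- mock_score_function()
  objective <- function(s) sf(s, "GA")
  pop <- data.frame(smiles = lib,
                    value = vapply(lib, objective, numeric(1)),
                    stringsAsFactors = FALSE)
  cfg <- ga_config(population_size = 40L, offspring_size = 15L, seed = 2L)
  set.seed(2)
  best <- min(pop$value)
  sizes <- integer(0)
  for (gen in 1:12) {
    pop <- graph_ga_generation(pop, cfg, objective)
    sizes <- c(sizes, nrow(pop))
    # elitism: best objective value never worsens
    expect_lte(min(pop$value), best)
    best <- min(pop$value)
    # every emitted SMILES is a valid single-fragment molecule
    expect_false(any(is.na(canonical_smiles(pop$smiles))))
    expect_true(all(vapply(pop$smiles,
                           function(s) isTRUE(validate_ligand(s)),
                           logical(1))))
  }
  expect_true(all(sizes <= 40L))
  expect_true(all(sizes >= 39L))  # merged pool is larger than the cap
})

test_that("GA defaults match the stated configuration", {
  cfg <- ga_config()
  expect_identical(cfg$population_size, 250L)
  expect_identical(cfg$offspring_size, 25L)
  expect_identical(cfg$mutation_rate, 0.01)
  bo <- bo_config()
  expect_identical(bo$beta, 10)
  expect_identical(bo$batch_size, 5L)
  expect_identical(bo$n_best_train, 2000L)
  expect_identical(bo$n_random_train, 3000L)
  expect_identical(bo$inner_ga_offspring, 1000L)
  expect_identical(bo$inner_ga_generations, 25L)
})

test_that("SELFIES GA children are valid and runs are seed-reproducible", {
  lib <- fixture_library(40L)
  sf <- mock_score_function()
  objective <- function(s) sf(s, "SGA")
  pop0 <- data.frame(smiles = lib,
                     value = vapply(lib, objective, numeric(1)),
                     stringsAsFactors = FALSE)
  cfg <- ga_config(population_size = 30L, offspring_size = 10L, seed = 3L)
  set.seed(3)
  p1 <- selfies_ga_generation(pop0, cfg, objective)
  set.seed(3)
  p2 <- selfies_ga_generation(pop0, cfg, objective)
  expect_identical(p1, p2)
  expect_false(any(is.na(canonical_smiles(p1$smiles))))
  set.seed(4)
  p3 <- selfies_ga_generation(pop0, cfg, objective)
  expect_false(identical(p1, p3))
})

test_that("BO training subset is best-2000 plus 3000 disjoint random", {
  set.seed(71)
  dataset <- data.frame(smiles = paste0("m", 1:6000),
                        value = rnorm(6000), stringsAsFactors = FALSE)
  cfg <- bo_config(seed = 1L)
  sub <- bo_training_subset(dataset, cfg)
  expect_identical(nrow(sub), 5000L)
  expect_false(any(duplicated(sub$smiles)))
  # the dataset global minimum is in the subset (best-2000 rule)
  expect_true(dataset$smiles[which.min(dataset$value)] %in% sub$smiles)
  # the best 2000 are all present
  best2000 <- dataset$smiles[order(dataset$value)[1:2000]]
  expect_true(all(best2000 %in% sub$smiles))
  # deterministic per seed
  expect_identical(bo_training_subset(dataset, cfg), sub)
  expect_false(identical(bo_training_subset(dataset, bo_config(seed = 2L)), sub))
  # small datasets fall back to all points, reported
  expect_message(all_back <- bo_training_subset(dataset[1:100, ], cfg),
                 "using all")
  expect_identical(nrow(all_back), 100L)
})

test_that("pool acquisition argmax matches exhaustive enumeration", {
  lib <- fixture_library(50L)
  sf <- mock_score_function()
  vals <- vapply(lib, function(s) sf(s, "BO"), numeric(1))
  evaluated <- data.frame(smiles = lib[1:20], value = vals[1:20],
                          stringsAsFactors = FALSE)
  fps <- lapply(evaluated$smiles, fingerprint, kind = "MORGAN2_1024")
  params <- gp_hyperparams(amplitude = 1, noise = 0.05,
                           constant_mean = mean(-evaluated$value))
  pre <- dockbench:::gp_precompute(params, fps, -evaluated$value)
  pool <- lib[21:50]

  for (acq in c("UCB", "EI")) {
    cfg <- bo_config(acquisition = acq, batch_size = 5L, seed = 1L)
    batch <- bo_select_batch(pre, evaluated, cfg, candidates = pool)
    expect_length(batch, 5L)
    expect_false(any(canonical_smiles(batch) %in%
                       canonical_smiles(evaluated$smiles)))

    # brute-force oracle over the pool via the public posterior
    post <- gp_predict(params, fps, -evaluated$value,
                       lapply(pool, fingerprint, kind = "MORGAN2_1024"))
    a <- dockbench:::acquisition_value(post$mean, sqrt(post$variance), cfg,
                                       incumbent = max(-evaluated$value))
    ord <- order(-a, canonical_smiles(pool))
    expect_identical(sort(canonical_smiles(batch)),
                     sort(canonical_smiles(pool[ord[1:5]])))
  }
})

test_that("fingerprint similarity search copies labels and discards inactives", {
  lib <- fixture_library(30L)
  refs <- c(lib[1], lib[5], lib[9])
  ref_fps <- fingerprint_set(refs, "PATH6")
  lib_fps <- fixture_fps(lib, "PATH6")
  active <- c(TRUE, FALSE, TRUE)
  res <- fss_rank(lib_fps, ref_fps, active, top_k = 10L)
  expect_lte(nrow(res), 10L)
  # the library copy of an active reference has similarity 1 and ranks first
  expect_identical(res$index[1], 1L)
  expect_equal(res$similarity[1], 1)
  # molecules nearest to the inactive reference are excluded
  M <- dockbench:::fp_matrix(lib_fps)
  R <- dockbench:::fp_matrix(ref_fps)
  S <- dockbench:::tanimoto_cross(M, R)
  nearest <- max.col(S, ties.method = "first")
  expect_false(any(nearest[res$index] == 2L))
  expect_error(fss_rank(lib_fps, list(), logical(0)), "reference")
})

test_that("random baseline sampling is uniform-without-replacement semantics", {
  lib <- fixture_library(30L)
  all30 <- random_baseline(lib, 30L, seed = 1L)
  expect_setequal(all30, lib)
  s1 <- random_baseline(lib, 10L, seed = 7L)
  expect_identical(random_baseline(lib, 10L, seed = 7L), s1)
  expect_false(identical(random_baseline(lib, 10L, seed = 8L), s1))
  expect_error(random_baseline(lib, 31L, seed = 1L))
})

test_that("optimizers halt within budget on objectives that always fail", {
  setup <- fixture_f2_setup(40L)
  failing_sf <- function(smiles, target) NA_real_   # every docking fails
  for (opt in c("graph_ga", "selfies_ga")) {
    res <- run_optimizer(opt, setup$spec, failing_sf,
                         init = setup$init, budget = 25L, seed = 1L,
                         ga = ga_config(population_size = 20L,
                                        offspring_size = 10L, seed = 1L))
    expect_lte(ledger_unique_calls(res$ledger), 25L)
  }
  res <- run_optimizer("random", setup$spec, failing_sf, init = setup$init,
                       candidate_library = fixture_library(50L, seed = 33L),
                       budget = 25L, seed = 1L)
  expect_lte(ledger_unique_calls(res$ledger), 25L)
})

test_that("the GP-BO driver runs end-to-end on a pool and respects the budget", {
  setup <- fixture_f2_setup(60L)
  pool <- fixture_library(80L, seed = 41L)
  res <- run_optimizer("gp_bo", setup$spec, setup$score_fun,
                       init = setup$init, budget = 20L, seed = 2L,
                       bo = bo_config(acquisition = "EI", batch_size = 5L,
                                      n_best_train = 20L, n_random_train = 20L,
                                      seed = 2L),
                       candidate_pool = pool)
  expect_lte(ledger_unique_calls(res$ledger), 20L)
  expect_false(is.null(res$best))
  # trajectory is the running minimum
  tr <- res$trajectory
  expect_true(all(diff(tr[!is.na(tr)]) <= 0))
})
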