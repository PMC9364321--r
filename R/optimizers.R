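# Baseline optimizers and rankers for the de novo design benchmark: a graph
# genetic algorithm (fragment crossover + atom-level mutation), a SELFIES
# genetic algorithm (single-token edits), Bayesian optimization over a
# Tanimoto-kernel GP (UCB / expected improvement), fingerprint similarity
# search, and a random library baseline.

#' Genetic-algorithm configuration
#'
#' Defaults: population 250, offspring 25, mutation rate 0.01.
#'
#' @param population_size,offspring_size,mutation_rate,seed Settings.
#' @param max_heavy_atoms Upper bound on child size (default 60).
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 250L, offspring_size = 25L,
                      mutation_rate = 0.01, seed = 0L, max_heavy_atoms = 60L) {
  structure(list(population_size = as.integer(population_size),
                 offspring_size = as.integer(offspring_size),
                 mutation_rate = mutation_rate, seed = as.integer(seed),
                 max_heavy_atoms = as.integer(max_heavy_atoms)),
            class = "ga_config")
}

#' Bayesian-optimization configuration
#'
#' Defaults: UCB with beta = 10, batches of 5, training subset of the 2000
#' best plus 3000 random points, inner GA with offspring 1000 for 25
#' generations.
#'
#' @param acquisition `"UCB"` or `"EI"`.
#' @param beta UCB exploration weight (default 10).
#' @param batch_size Molecules proposed per iteration (default 5).
#' @param n_best_train,n_random_train Training-subset sizes (2000 + 3000).
#' @param inner_ga_offspring,inner_ga_generations Acquisition-optimizer GA
#'   size (defaults 1000 and 25).
#' @param seed Integer seed.
#' @return A `bo_config` list.
#' @export
bo_config <- function(acquisition = c("UCB", "EI"), beta = 10, batch_size = 5L,
                      n_best_train = 2000L, n_random_train = 3000L,
                      inner_ga_offspring = 1000L, inner_ga_generations = 25L,
                      seed = 0L) {
  acquisition <- match.arg(acquisition)
  structure(list(acquisition = acquisition, beta = beta,
                 batch_size = as.integer(batch_size),
                 n_best_train = as.integer(n_best_train),
                 n_random_train = as.integer(n_random_train),
                 inner_ga_offspring = as.integer(inner_ga_offspring),
                 inner_ga_generations = as.integer(inner_ga_generations),
                 seed = as.integer(seed)),
            class = "bo_config")
}

# ---------------------------------------------------------------------------
# Graph GA edit operations

# Split a molecule at a random acyclic single bond; returns the two
# fragments as (atom index set, cut atom) pairs, or NULL if no cuttable bond.
.ga_cut <- function(g) {
  if (nrow(g$bonds) == 0L) return(NULL)
  bridges <- molgraph_bridges_cached(g)
  deg <- lengths(g$adj)
  cuttable <- which(g$bonds[, "order"] == 1L & bridges &
                      deg[g$bonds[, "a"]] > 1L & deg[g$bonds[, "b"]] > 1L)
  if (length(cuttable) == 0L) return(NULL)
  e <- cuttable[[sample.int(length(cuttable), 1L)]]
  a <- g$bonds[e, "a"]; b <- g$bonds[e, "b"]
  side_a <- .reachable_avoiding_edge(g, start = a, skip_edge = e)
  side_b <- setdiff(seq_len(g$n_atoms), side_a)
  list(list(atoms = side_a, cut = a), list(atoms = side_b, cut = b))
}

.reachable_avoiding_edge <- function(g, start, skip_edge) {
  seen <- logical(g$n_atoms)
  seen[start] <- TRUE
  queue <- start
  ea <- g$bonds[skip_edge, "a"]; eb <- g$bonds[skip_edge, "b"]
  while (length(queue) > 0L) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in g$adj[[v]]) {
      if ((v == ea && w == eb) || (v == eb && w == ea)) next
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  which(seen)
}

# Extract a fragment subgraph, remapping indices; `cut` becomes attr.
.ga_subgraph <- function(g, atoms, cut) {
  idx_map <- integer(g$n_atoms)
  idx_map[atoms] <- seq_along(atoms)
  sel <- g$bonds[, "a"] %in% atoms & g$bonds[, "b"] %in% atoms
  bonds <- g$bonds[sel, , drop = FALSE]
  if (nrow(bonds) > 0L) {
    bonds[, "a"] <- idx_map[bonds[, "a"]]
    bonds[, "b"] <- idx_map[bonds[, "b"]]
  }
  list(elements = g$elements[atoms], charges = g$charges[atoms],
       bonds = bonds, cut = idx_map[cut])
}

# Graph crossover: random fragment of parent A joined to random fragment of
# parent B at the cut atoms. Returns raw graph pieces, or NULL when no
# cuttable bond exists or the child would be too large. Serialization to
# SMILES happens in one batched call per generation.
.ga_crossover_raw <- function(ga, gb, max_heavy_atoms) {
  ca <- .ga_cut(ga); cb <- .ga_cut(gb)
  if (is.null(ca) || is.null(cb)) return(NULL)
  side_a <- ca[[sample.int(2, 1)]]
  side_b <- cb[[sample.int(2, 1)]]
  fa <- .ga_subgraph(ga, side_a$atoms, side_a$cut)
  fb <- .ga_subgraph(gb, side_b$atoms, side_b$cut)
  n_a <- length(fa$elements)
  if (n_a + length(fb$elements) > max_heavy_atoms) return(NULL)
  bonds_b <- fb$bonds
  if (nrow(bonds_b) > 0L) {
    bonds_b[, "a"] <- bonds_b[, "a"] + n_a
    bonds_b[, "b"] <- bonds_b[, "b"] + n_a
  }
  join <- matrix(c(fa$cut, fb$cut + n_a, 1L), ncol = 3,
                 dimnames = list(NULL, c("a", "b", "order")))
  list(elements = c(fa$elements, fb$elements),
       bonds = rbind(fa$bonds, bonds_b, join),
       charges = c(fa$charges, fb$charges))
}

# Atom-level mutation on raw graph pieces: append a light atom, delete a
# terminal atom, or swap an element. Returns (possibly unchanged) raw pieces.
.ga_mutate_raw <- function(raw, max_heavy_atoms) {
  g <- .raw_graph(raw$elements, raw$bonds, raw$charges)
  impl_h <- molgraph_implicit_h(g)
  op <- sample.int(3L, 1L)
  if (op == 1L && g$n_atoms < max_heavy_atoms) {        # append
    host <- which(impl_h > 0)
    if (length(host) > 0L) {
      v <- host[[sample.int(length(host), 1L)]]
      el <- sample(c("C", "C", "N", "O"), 1L)
      raw$bonds <- rbind(raw$bonds,
                         matrix(c(g$n_atoms + 1L, v, 1L), ncol = 3,
                                dimnames = list(NULL, c("a", "b", "order"))))
      raw$elements <- c(raw$elements, el)
      raw$charges <- c(raw$charges, 0L)
    }
  } else if (op == 2L && g$n_atoms > 2L) {              # delete terminal
    deg <- lengths(g$adj)
    term <- which(deg == 1L)
    if (length(term) > 0L) {
      v <- term[[sample.int(length(term), 1L)]]
      keep <- setdiff(seq_len(g$n_atoms), v)
      sub <- .ga_subgraph(g, keep, keep[[1]])
      raw <- list(elements = sub$elements, bonds = sub$bonds,
                  charges = sub$charges)
    }
  } else {                                              # element swap
    bos <- molgraph_bond_order_sum(g)
    v <- sample.int(g$n_atoms, 1L)
    opts <- c(C = 4, N = 3, O = 2)
    ok <- names(opts)[opts >= bos[v] & names(opts) != g$elements[v]]
    if (length(ok) > 0L && g$charges[v] == 0L) {
      raw$elements[v] <- ok[[sample.int(length(ok), 1L)]]
    }
  }
  raw
}

# Single-molecule mutation kept for external use: SMILES in, SMILES out.
.ga_mutate <- function(smiles, max_heavy_atoms) {
  g <- parse_molgraph(smiles)
  if (is.null(g)) return(smiles)
  raw <- .ga_mutate_raw(list(elements = g$elements, bonds = g$bonds,
                             charges = g$charges), max_heavy_atoms)
  out <- molgraph_build_smiles(raw$elements, raw$bonds, raw$charges)
  if (is.na(out)) smiles else out
}

# Fitness-proportional parent sampling on rank-transformed scores (lower
# objective value = higher rank weight).
.ga_select_parents <- function(values, n) {
  r <- rank(-values, ties.method = "average")   # best value -> largest rank
  probs <- r / sum(r)
  sample.int(length(values), size = n, replace = TRUE, prob = probs)
}

#' One generation of the graph genetic algorithm
#'
#' Creates `offspring_size` children by fragment crossover of
#' fitness-selected parents, mutates each child with probability
#' `mutation_rate`, evaluates children with `objective`, and keeps the best
#' `population_size` of parents and children (elitism). Crossover failures
#' are retried a bounded number of times, then the parent is cloned.
#'
#' @param population data.frame with columns `smiles` and `value`
#'   (objective values, lower is better).
#' @param config A [ga_config()].
#' @param objective Function `smiles -> value` (may return `Inf`).
#' @return data.frame of the next population, sorted by value.
#' @export
graph_ga_generation <- function(population, config, objective) {
  stopifnot(all(c("smiles", "value") %in% names(population)),
            nrow(population) >= 2L)
  prime_molgraph_cache(population$smiles)
  raws <- vector("list", config$offspring_size)
  fallback <- character(config$offspring_size)
  for (k in seq_len(config$offspring_size)) {
    raw <- NULL
    for (try in 1:5) {
      pidx <- .ga_select_parents(population$value, 2L)
      ga <- parse_molgraph(population$smiles[[pidx[1]]])
      gb <- parse_molgraph(population$smiles[[pidx[2]]])
      if (is.null(ga) || is.null(gb)) next
      raw <- .ga_crossover_raw(ga, gb, config$max_heavy_atoms)
      if (!is.null(raw)) break
    }
    fallback[[k]] <- population$smiles[[.ga_select_parents(population$value, 1L)]]
    if (!is.null(raw) && stats::runif(1) < config$mutation_rate) {
      raw <- .ga_mutate_raw(raw, config$max_heavy_atoms)
    }
    raws[[k]] <- raw
  }
  # one Open Babel call serializes and canonicalizes the whole brood;
  # children the toolkit rejects fall back to the cloned parent
  built <- rep(NA_character_, config$offspring_size)
  have <- !vapply(raws, is.null, logical(1))
  if (any(have)) built[have] <- batch_build_smiles(raws[have])
  children <- ifelse(is.na(built), fallback, built)
  .ga_merge(population, children, config, objective)
}

# Evaluate children (after an optional batched prefetch, e.g. cache warming)
# and apply the elitist survivor rule.
.ga_merge <- function(population, children, config, objective) {
  prime_molgraph_cache(children)
  pf <- attr(objective, "prefetch")
  if (!is.null(pf)) try(pf(unique(children)), silent = TRUE)
  vals <- vapply(children, function(s) {
    v <- tryCatch(objective(s), error = function(e) {
      if (inherits(e, "BudgetExhausted")) stop(e)
      Inf
    })
    if (is.na(v)) Inf else v
  }, numeric(1), USE.NAMES = FALSE)
  merged <- rbind(population[, c("smiles", "value")],
                  data.frame(smiles = children, value = vals,
                             stringsAsFactors = FALSE))
  merged <- merged[!duplicated(merged$smiles), , drop = FALSE]
  merged <- merged[order(merged$value), , drop = FALSE]
  utils::head(merged, config$population_size)
}

#' One generation of the SELFIES genetic algorithm
#'
#' Each child is obtained from a fitness-selected parent by exactly one
#' token edit (random insertion, deletion or substitution) of its
#' SELFIES-style string; the valence-constrained decoder guarantees every
#' child is a valid molecule. Parents that cannot be encoded are skipped.
#'
#' @inheritParams graph_ga_generation
#' @return data.frame of the next population, sorted by value.
#' @export
selfies_ga_generation <- function(population, config, objective) {
  stopifnot(nrow(population) >= 2L)
  alphabet <- selfies_alphabet()
  children <- character(0)
  for (k in seq_len(config$offspring_size)) {
    child <- NA_character_
    for (try in 1:5) {
      pidx <- .ga_select_parents(population$value, 1L)
      toks <- selfies_encode(population$smiles[[pidx]])
      if (is.null(toks)) next
      child <- selfies_decode(.selfies_token_edit(toks, alphabet))
      break
    }
    if (is.na(child)) child <- population$smiles[[.ga_select_parents(population$value, 1L)]]
    children <- c(children, child)
  }
  .ga_merge(population, children, config, objective)
}

# One random token edit: insert, delete or substitute a single token.
.selfies_token_edit <- function(tokens, alphabet) {
  op <- sample.int(3L, 1L)
  if (op == 1L) {                                   # substitute
    pos <- sample.int(length(tokens), 1L)
    tokens[[pos]] <- sample(alphabet, 1L)
  } else if (op == 2L) {                            # insert
    pos <- sample.int(length(tokens) + 1L, 1L) - 1L
    tokens <- append(tokens, sample(alphabet, 1L), after = pos)
  } else if (length(tokens) > 1L) {                 # delete
    tokens <- tokens[-sample.int(length(tokens), 1L)]
  }
  tokens
}

# ---------------------------------------------------------------------------
# Bayesian optimization

#' Training subset for the BO surrogate
#'
#' The `n_best_train` points with the smallest objective value plus
#' `n_random_train` random points drawn from the remainder; the two parts
#' are disjoint and the result is deterministic per seed. Datasets smaller
#' than the requested total are returned whole with a message.
#'
#' @param dataset data.frame with columns `smiles` and `value`.
#' @param config A [bo_config()].
#' @return Subset of `dataset` rows.
#' @export
bo_training_subset <- function(dataset, config = bo_config()) {
  n <- nrow(dataset)
  total <- config$n_best_train + config$n_random_train
  if (n < total) {
    message(sprintf("bo_training_subset: dataset (%d) smaller than %d, using all",
                    n, total))
    return(dataset)
  }
  ord <- order(dataset$value)
  best <- ord[seq_len(config$n_best_train)]
  rest <- ord[-seq_len(config$n_best_train)]
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  rnd <- sample(rest, config$n_random_train)
  dataset[c(best, rnd), , drop = FALSE]
}

# Acquisition value of posterior (mean, sd) pairs. The GP models the NEGATED
# objective, so larger acquisition = more promising; `incumbent` is the best
# (largest) negated-objective value observed.
acquisition_value <- function(mean, sd, config, incumbent = NULL) {
  if (config$acquisition == "UCB") {
    mean + config$beta * sd
  } else {
    stopifnot(!is.null(incumbent))
    imp <- mean - incumbent
    z <- ifelse(sd > 0, imp / sd, 0)
    ifelse(sd > 0, imp * stats::pnorm(z) + sd * stats::dnorm(z),
           pmax(imp, 0))
  }
}

#' Select a batch of candidate molecules by acquisition maximization
#'
#' The acquisition surface (UCB with beta = 10, or expected improvement) is
#' optimized with the graph genetic algorithm (`inner_ga_offspring` children
#' per generation for `inner_ga_generations` generations, seeded from the
#' best evaluated molecules); every molecule visited during the search is a
#' candidate. The best `batch_size` distinct molecules that have not yet
#' been evaluated are returned. If an explicit `candidates` pool is given,
#' the acquisition is instead maximized exhaustively over that pool. GP
#' hyperparameters are held fixed throughout.
#'
#' @param pre Precomputed GP state (from `gp_precompute` on the negated
#'   objective values).
#' @param evaluated data.frame with `smiles` and `value` (objective scale)
#'   of all molecules evaluated so far.
#' @param config A [bo_config()].
#' @param candidates Optional explicit candidate pool (character vector).
#' @param fp_cache Optional environment memoizing fingerprints by SMILES.
#' @return Character vector of up to `batch_size` SMILES.
#' @export
bo_select_batch <- function(pre, evaluated, config, candidates = NULL,
                            fp_cache = NULL) {
  if (is.null(fp_cache)) fp_cache <- new.env(parent = emptyenv())
  seen <- stats::setNames(rep(TRUE, nrow(evaluated)),
                          canonical_smiles(evaluated$smiles))
  incumbent <- max(-evaluated$value[is.finite(evaluated$value)])
  acq_of <- function(smis) {
    fps <- lapply(smis, .cached_fp, fp_cache)
    ok <- !vapply(fps, is.null, logical(1))
    out <- rep(-Inf, length(smis))
    if (any(ok)) {
      post <- gp_predict_pre(pre, fps[ok])
      out[ok] <- acquisition_value(post$mean, sqrt(post$variance), config,
                                   incumbent)
    }
    out
  }
  acq_memo <- new.env(parent = emptyenv())
  acq_memoized <- function(smis) {
    miss <- smis[vapply(smis, function(s) is.null(acq_memo[[s]]), logical(1))]
    if (length(miss) > 0L) {
      a <- acq_of(miss)
      for (i in seq_along(miss)) acq_memo[[miss[[i]]]] <- a[[i]]
    }
    vapply(smis, function(s) acq_memo[[s]], numeric(1), USE.NAMES = FALSE)
  }
  if (!is.null(candidates)) {
    acq <- acq_of(candidates)
    pool <- data.frame(smiles = candidates, acq = acq, stringsAsFactors = FALSE)
  } else {
    # inner GA maximizing the acquisition surface
    finite <- evaluated[is.finite(evaluated$value), , drop = FALSE]
    start <- utils::head(finite[order(finite$value), "smiles"],
                         max(20L, config$batch_size * 4L))
    pop <- data.frame(smiles = start, value = -acq_memoized(start),
                      stringsAsFactors = FALSE)
    inner_cfg <- ga_config(population_size = max(nrow(pop), 50L),
                           offspring_size = config$inner_ga_offspring,
                           mutation_rate = 0.05, seed = config$seed)
    objective <- function(s) -acq_memoized(s)   # the GA minimizes
    # GA generations prefetch their whole child batch in one GP call
    attr(objective, "prefetch") <- function(smis) invisible(acq_memoized(smis))
    for (gen in seq_len(config$inner_ga_generations)) {
      pop <- graph_ga_generation(pop, inner_cfg, objective)
    }
    keys <- ls(acq_memo)
    pool <- data.frame(
      smiles = keys,
      acq = vapply(keys, function(k) acq_memo[[k]], numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  pool$can <- canonical_smiles(pool$smiles)
  pool <- pool[!is.na(pool$can) & !(pool$can %in% names(seen)), , drop = FALSE]
  pool <- pool[!duplicated(pool$can), , drop = FALSE]
  pool <- pool[order(-pool$acq, pool$can), , drop = FALSE]
  utils::head(pool$smiles, config$batch_size)
}

.cached_fp <- function(smiles, cache) {
  key <- smiles
  if (!is.null(cache[[key]])) return(cache[[key]])
  fp <- tryCatch(fingerprint(smiles, "MORGAN2_1024"), error = function(e) NULL)
  if (!is.null(fp)) cache[[key]] <- fp
  fp
}

# ---------------------------------------------------------------------------
# Similarity search and random baseline

#' Fingerprint-similarity-search ranking
#'
#' Each library molecule receives the activity label of its Tanimoto-nearest
#' reference molecule (labels derive from a docking-score cutoff); molecules
#' labeled inactive are discarded, survivors are sorted by similarity to
#' their nearest reference (descending), and the `top_k` are returned.
#'
#' @param library_fps List of fingerprints of the candidate library.
#' @param reference_fps Nonempty list of reference fingerprints.
#' @param reference_active Logical vector of reference activity labels.
#' @param top_k Maximum number of molecules returned (default 5000).
#' @return data.frame with `index` (into the library), `similarity`,
#'   ordered by similarity descending.
#' @export
fss_rank <- function(library_fps, reference_fps, reference_active,
                     top_k = 5000L) {
  stopifnot(length(reference_fps) > 0L,
            length(reference_fps) == length(reference_active))
  S <- tanimoto_cross(fp_matrix(library_fps), fp_matrix(reference_fps))
  nearest <- max.col(S, ties.method = "first")
  sim <- S[cbind(seq_len(nrow(S)), nearest)]
  lab <- reference_active[nearest]
  keep <- which(lab)
  keep <- keep[order(-sim[keep], keep)]
  utils::head(data.frame(index = keep, similarity = sim[keep]), top_k)
}

#' Random library baseline
#'
#' Uniform sample without replacement, deterministic per seed.
#'
#' @param library Character vector of SMILES.
#' @param n Sample size (must not exceed the library size).
#' @param seed Integer seed.
#' @return Character vector of `n` molecules.
#' @export
random_baseline <- function(library, n, seed = 0L) {
  stopifnot(n <= length(library))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  library[sample.int(length(library), n)]
}

# ---------------------------------------------------------------------------
# De novo run drivers

#' Seed a ledger with known dataset values
#'
#' Dataset molecules count as known (the benchmark grants access to the
#' whole dataset); entering them into the cache consumes no budget.
#'
#' @param ledger An `evaluation_ledger`.
#' @param smiles,values Dataset molecules and their objective values.
#' @return The ledger, invisibly.
#' @export
ledger_seed <- function(ledger, smiles, values) {
  stopifnot(length(smiles) == length(values))
  keys <- canonical_smiles(smiles)
  for (i in seq_along(keys)) {
    if (!is.na(keys[[i]])) ledger$cache[[keys[[i]]]] <- values[[i]]
  }
  invisible(ledger)
}

#' Run a de novo optimizer against an objective under a budget
#'
#' Drives one of the baseline optimizers until the evaluation budget is
#' exhausted. `init` supplies the dataset (SMILES with known objective
#' values): it seeds the GA populations and the GP training set, and its
#' values are cache hits that consume no budget.
#'
#' @param optimizer One of `"graph_ga"`, `"selfies_ga"`, `"gp_bo"`,
#'   `"random"`.
#' @param spec An [objective_spec()].
#' @param score_fun Function `(smiles, target) -> docking score`.
#' @param init data.frame with `smiles` and `value` columns.
#' @param candidate_library Character vector for the random baseline.
#' @param budget Unique-evaluation budget (default 5000).
#' @param seed Integer seed.
#' @param ga Optional [ga_config()] override.
#' @param bo Optional [bo_config()] override.
#' @param qed_fun QED function (default [qed_cached()]).
#' @param init_population `"best"` (default) or `"random"`: how GA
#'   populations are drawn from `init`.
#' @param candidate_pool Optional explicit pool for the GP-BO acquisition
#'   (exhaustive acquisition maximization over the pool instead of the
#'   inner GA).
#' @param fp_cache Optional environment memoizing fingerprints across runs.
#' @return List with `ledger`, `best` (best evaluated molecule + value) and
#'   `trajectory` (running minimum per call).
#' @export
run_optimizer <- function(optimizer = c("graph_ga", "selfies_ga", "gp_bo", "random"),
                          spec, score_fun, init, candidate_library = NULL,
                          budget = 5000L, seed = 0L, ga = NULL, bo = NULL,
                          qed_fun = qed_cached, init_population = c("best", "random"),
                          candidate_pool = NULL, fp_cache = NULL) {
  optimizer <- match.arg(optimizer)
  init_population <- match.arg(init_population)
  ledger <- new_ledger(budget)
  ledger_seed(ledger, init$smiles, init$value)
  objective <- function(s) evaluate_with_budget(ledger, spec, s, score_fun,
                                                qed_fun = qed_fun)
  # children of a GA generation are all valid molecules: warm the QED cache
  # for the batch before the per-molecule ledger calls
  attr(objective, "prefetch") <- function(smis) qed_fun(smis)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  if (optimizer == "random") {
    stopifnot(!is.null(candidate_library))
    picks <- random_baseline(candidate_library,
                             min(budget, length(candidate_library)), seed)
    valid <- picks[!vapply(lapply(picks, validate_ligand), is_rejected, logical(1))]
    try(qed_fun(unique(valid)), silent = TRUE)
    tryCatch(for (s in picks) objective(s),
             BudgetExhausted = function(e) NULL)
  } else if (optimizer %in% c("graph_ga", "selfies_ga")) {
    cfg <- if (is.null(ga)) ga_config(seed = seed) else ga
    pool <- init[is.finite(init$value), , drop = FALSE]
    pop <- if (init_population == "best") {
      utils::head(pool[order(pool$value), ], cfg$population_size)
    } else {
      pool[sample.int(nrow(pool), min(nrow(pool), cfg$population_size)), ]
    }
    step <- if (optimizer == "graph_ga") graph_ga_generation else selfies_ga_generation
    stall <- 0L
    tryCatch(
      repeat {
        before <- ledger_unique_calls(ledger)
        pop <- step(pop, cfg, objective)
        # a fully cache-hit generation makes no budget progress; stop after a
        # long stall rather than spinning on duplicates
        stall <- if (ledger_unique_calls(ledger) == before) stall + 1L else 0L
        if (stall >= 50L) break
      },
      BudgetExhausted = function(e) NULL
    )
  } else {  # gp_bo
    cfg <- if (is.null(bo)) bo_config(seed = seed) else bo
    train <- bo_training_subset(init[is.finite(init$value), , drop = FALSE], cfg)
    if (is.null(fp_cache)) fp_cache <- new.env(parent = emptyenv())
    fps <- lapply(train$smiles, .cached_fp, fp_cache)
    ok <- !vapply(fps, is.null, logical(1))
    train <- train[ok, , drop = FALSE]; fps <- fps[ok]
    y_gp <- -train$value   # GP models the negated objective
    params <- gp_fit(fps, y_gp, gp_hyperparams(amplitude = stats::var(y_gp),
                                               noise = 0.1 * stats::var(y_gp),
                                               constant_mean = mean(y_gp)))
    evaluated <- train
    # training similarity matrix maintained incrementally across iterations
    Tmat <- fp_matrix(fps)
    S <- tanimoto_cross(Tmat, Tmat)
    stall <- 0L
    tryCatch(
      repeat {
        pre <- gp_precompute(params, fps, y_gp, Tmat = Tmat, S = S)
        before <- ledger_unique_calls(ledger)
        batch <- bo_select_batch(pre, evaluated, cfg, candidates = candidate_pool,
                                 fp_cache = fp_cache)
        if (length(batch) == 0L) break
        new_fps <- list()
        for (s in batch) {
          v <- objective(s)
          evaluated <- rbind(evaluated,
                             data.frame(smiles = s, value = v,
                                        stringsAsFactors = FALSE))
          if (is.finite(v)) {
            fp <- .cached_fp(s, fp_cache)
            if (!is.null(fp)) {
              fps <- c(fps, list(fp)); y_gp <- c(y_gp, -v)
              new_fps <- c(new_fps, list(fp))
            }
          }
        }
        if (length(new_fps) > 0L) {
          # block update of the training similarity matrix
          newM <- fp_matrix(new_fps)
          cross <- tanimoto_cross(Tmat, newM)
          self <- tanimoto_cross(newM, newM)
          S <- rbind(cbind(S, cross), cbind(t(cross), self))
          Tmat <- rbind(Tmat, newM)
        }
        stall <- if (ledger_unique_calls(ledger) == before) stall + 1L else 0L
        if (stall >= 20L) break
      },
      BudgetExhausted = function(e) NULL
    )
  }

  calls <- ledger_calls(ledger)
  best_idx <- if (nrow(calls) > 0L && any(is.finite(calls$value))) {
    which.min(calls$value)
  } else NA_integer_
  list(
    ledger = ledger,
    best = if (is.na(best_idx)) NULL else
      list(smiles = calls$smiles[[best_idx]], value = calls$value[[best_idx]]),
    trajectory = trajectory(ledger, 1L)
  )
}
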