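# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small clean druglike library (deterministic).
fixture_library <- function(n = 60L, seed = 11L) {
  key <- paste0("lib_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_library(library_spec(n, seed = seed))
  }
  .fixture_env[[key]]
}

fixture_fps <- function(smiles, kind = "PATH6") {
  key <- paste0("fps_", kind, "_", digest_smiles(smiles))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- fingerprint_set(smiles, kind)
  }
  .fixture_env[[key]]
}

digest_smiles <- function(smiles) {
  paste0(length(smiles), "_", substr(paste(smiles, collapse = ""), 1, 40))
}

# Mock F2 objective setup over a library: returns list(spec, score_fun,
# init) where init holds the library with known objective values.
fixture_f2_setup <- function(n = 80L, seed = 7L) {
  key <- paste0("f2_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    lib <- fixture_library(n, seed)
    sm <- generate_mock_targets(list(mock_target_spec("F2")), lib, seed = seed)
    spec <- objective_spec("F2")
    sf <- mock_score_function(sm$weights)
    q <- qed_cached(lib)
    vals <- vapply(seq_along(lib), function(i) {
      objective_value(spec, c(F2 = sm$scores[i, "F2"]), q[[i]])
    }, numeric(1))
    .fixture_env[[key]] <- list(
      spec = spec, score_fun = sf, score_matrix = sm,
      init = data.frame(smiles = lib, value = vals, stringsAsFactors = FALSE)
    )
  }
  .fixture_env[[key]]
}

# Random bitset fingerprints (for clustering / GP tests that do not need
# real molecules).
random_fp <- function(on_bits, nbits = 1024L, kind = "MORGAN2_1024") {
  structure(list(bits = as.integer(sort(unique(on_bits))), nbits = nbits,
                 kind = kind), class = "fingerprint")
}

random_fp_set <- function(n, nbits = 1024L, density = 0.05, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    random_fp(sample.int(nbits, max(1L, rpois(1, nbits * density))) - 1L,
              nbits = nbits)
  })
}

# Brute-force DBSCAN oracle: density-reachability from first principles.
# Returns list(core, components) where components is a partition of core
# points, plus a border-assignment validity checker.
dbscan_oracle <- function(D, eps, min_core) {
  n <- nrow(D)
  nb <- lapply(seq_len(n), function(i) setdiff(which(D[i, ] <= eps), i))
  core <- which(lengths(nb) >= min_core)
  # connected components over cores (edges between cores within eps)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (c0 in core) {
    if (!is.na(comp[c0])) next
    cid <- cid + 1L
    queue <- c0
    comp[c0] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in intersect(nb[[v]], core)) {
        if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  list(core = core, comp = comp, nb = nb)
}

# Fingerprint set with group structure (shared cores + private bits) and
# exact duplicates (odd/even pairs share a fingerprint): the varying
# similarity spectrum identifies the amplitude, and response differences
# between duplicate inputs pin down the noise.
structured_fp_set <- function(n, n_groups = 20L, core_bits = 40L,
                              private_bits = 15L, nbits = 1024L, seed = 1L) {
  set.seed(seed)
  cores <- lapply(seq_len(n_groups), function(g)
    sample.int(nbits, core_bits) - 1L)
  base <- lapply(seq_len(ceiling(n / 2)), function(i) {
    g <- ((i - 1L) %% n_groups) + 1L
    random_fp(c(cores[[g]], sample.int(nbits, private_bits) - 1L),
              nbits = nbits)
  })
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- base[[ceiling(i / 2)]]
  out
}
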