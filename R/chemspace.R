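# Chemical-space tooling: Jaccard-distance DBSCAN clustering, generic
# Bemis-Murcko scaffolds, cluster-respecting train/test splits, and
# druglikeness profiling.

#' DBSCAN clustering under Jaccard distance
#'
#' Standard density-based clustering: a molecule is a core point if at least
#' `min_core_neighbors` other molecules lie within Jaccard distance `eps` of
#' it; clusters are the connected components of density-reachability; points
#' reachable from no core point are noise.
#'
#' @param fps List of fingerprints (same kind).
#' @param eps Neighborhood cutoff as a Jaccard distance (default 0.25).
#' @param min_core_neighbors Minimum number of neighbors (excluding the
#'   point itself) for a core point (default 5).
#' @return Integer vector of cluster labels, contiguous from 0; noise = -1.
#' @export
dbscan_jaccard <- function(fps, eps = 0.25, min_core_neighbors = 5L) {
  n <- length(fps)
  stopifnot(n >= 1L)
  M <- fp_matrix(fps)
  D <- 1 - tanimoto_cross(M, M)
  dbscan_from_dist(D, eps = eps, min_core_neighbors = min_core_neighbors)
}

# DBSCAN on a precomputed distance matrix (exposed for testing against the
# brute-force reachability oracle).
dbscan_from_dist <- function(D, eps, min_core_neighbors) {
  n <- nrow(D)
  neighbors <- lapply(seq_len(n), function(i) {
    setdiff(which(D[i, ] <= eps), i)
  })
  is_core <- lengths(neighbors) >= min_core_neighbors
  labels <- rep(-2L, n)  # -2 = unvisited, -1 = noise
  cl <- -1L
  for (i in seq_len(n)) {
    if (labels[i] != -2L || !is_core[i]) next
    cl <- cl + 1L
    # expand cluster from this core point
    labels[i] <- cl
    queue <- neighbors[[i]]
    while (length(queue) > 0L) {
      j <- queue[[1]]; queue <- queue[-1]
      if (labels[j] == -1L) labels[j] <- cl       # border point claimed
      if (labels[j] != -2L) next
      labels[j] <- cl
      if (is_core[j]) queue <- c(queue, neighbors[[j]])
    }
  }
  labels[labels == -2L] <- -1L
  labels
}

#' Generic Bemis-Murcko scaffold
#'
#' Reduces a molecule to its ring systems and the linker atoms between them
#' (side chains pruned), substitutes every atom by carbon, and reduces all
#' bonds to single order; the result is reported as a canonical SMILES
#' string. Acyclic molecules have the empty scaffold.
#'
#' @param smiles A SMILES string.
#' @return A `scaffold_key`: list with `generic_scaffold` (canonical SMILES,
#'   `""` for acyclic molecules).
#' @export
generic_murcko_scaffold <- function(smiles) {
  g <- parse_molgraph(canonical_smiles(smiles))
  if (is.null(g)) stop(sprintf("invalid SMILES: %s", smiles))
  keep <- murcko_framework_atoms(g)
  if (!any(keep)) {
    return(structure(list(generic_scaffold = ""), class = "scaffold_key"))
  }
  idx_map <- cumsum(keep)
  sel <- g$bonds[, "a"] %in% which(keep) & g$bonds[, "b"] %in% which(keep)
  bonds <- g$bonds[sel, , drop = FALSE]
  bonds[, "a"] <- idx_map[bonds[, "a"]]
  bonds[, "b"] <- idx_map[bonds[, "b"]]
  bonds[, "order"] <- 1L
  smi <- molgraph_build_smiles(rep("C", sum(keep)), bonds)
  if (is.na(smi)) stop(sprintf("scaffold canonicalization failed for %s", smiles))
  structure(list(generic_scaffold = smi), class = "scaffold_key")
}

# Murcko framework: iteratively prune terminal (degree-1) atoms until only
# ring systems and linkers remain.
murcko_framework_atoms <- function(g) {
  n <- g$n_atoms
  alive <- rep(TRUE, n)
  if (nrow(g$bonds) == 0L) return(rep(FALSE, n))
  repeat {
    deg <- integer(n)
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds[i, "a"]; b <- g$bonds[i, "b"]
      if (alive[a] && alive[b]) { deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L }
    }
    terminal <- alive & deg <= 1L
    if (!any(terminal)) break
    alive[terminal] <- FALSE
    if (!any(alive)) break
  }
  alive
}

#' Cluster-respecting train/test split
#'
#' Shuffles cluster ids with a seeded RNG and greedily assigns whole
#' clusters to the test side until the requested fraction is reached, so no
#' cluster is divided between train and test. Noise points (label -1) are
#' treated as singleton clusters.
#'
#' @param labels Integer cluster labels (as from [dbscan_jaccard()]).
#' @param test_fraction Requested test share, in (0, 1).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
cluster_split <- function(labels, test_fraction, seed = 0L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- length(labels)
  # noise points become singleton clusters so the split stays a partition
  lab <- labels
  noise <- lab == -1L
  if (any(noise)) {
    lab[noise] <- max(lab) + seq_len(sum(noise))
  }
  ids <- unique(lab)
  if (length(ids) < 2L) {
    stop("degenerate input: a single cluster cannot be split without leakage")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  ids <- sample(ids)
  sizes <- vapply(ids, function(id) sum(lab == id), integer(1))
  target <- test_fraction * n
  take <- cumsum(sizes) <= target + 1e-9
  # take at least one and at most all-but-one cluster
  if (!any(take)) take[1] <- TRUE
  if (all(take)) take[length(take)] <- FALSE
  test_ids <- ids[take]
  test <- which(lab %in% test_ids)
  train <- setdiff(seq_len(n), test)
  achieved <- length(test) / n
  if (abs(achieved - test_fraction) > 0.05) {
    message(sprintf("cluster_split: achieved test fraction %.3f (requested %.3f)",
                    achieved, test_fraction))
  }
  list(train = train, test = test)
}

#' Physicochemical property profile of a molecule
#'
#' Computes logP, molecular weight, hydrogen-bond donor and acceptor counts,
#' rotatable bonds, QED, and the Lipinski rule-of-five verdict
#' (MW <= 500, logP <= 5, HBD <= 5, HBA <= 10).
#'
#' @param smiles Character vector of SMILES strings.
#' @return data.frame with one row per molecule and columns `smiles`,
#'   `logP`, `MW`, `HBD`, `HBA`, `RB`, `QED`, `lipinski_pass`.
#' @export
property_profile <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  d <- .ob_descriptors(smiles)
  qed <- qed_score_from_descriptors(d)
  data.frame(
    smiles = smiles,
    logP = d$logP, MW = d$MW, HBD = d$HBD, HBA = d$HBA, RB = d$ROTB,
    QED = qed,
    lipinski_pass = d$MW <= 500 & d$logP <= 5 & d$HBD <= 5 & d$HBA <= 10,
    stringsAsFactors = FALSE
  )
}

# Package-level descriptor cache: QED descriptor rows keyed by the SMILES
# string. Optimizer loops revisit molecules heavily; caching plus batched
# computation of the misses keeps objective evaluation fast.
.db_desc_cache <- new.env(parent = emptyenv())

# Cached, batch-computing variant of .ob_descriptors. All inputs must be
# valid SMILES.
.ob_descriptors_cached <- function(smiles) {
  miss <- unique(smiles[vapply(smiles, function(s)
    is.null(.db_desc_cache[[s]]), logical(1))])
  if (length(miss) > 0L) {
    d <- .ob_descriptors(miss)
    for (i in seq_along(miss)) .db_desc_cache[[miss[[i]]]] <- d[i, , drop = FALSE]
  }
  do.call(rbind, lapply(smiles, function(s) .db_desc_cache[[s]]))
}

#' QED with package-level memoization
#'
#' Same value as [qed_score()], served from a cache keyed by the SMILES
#' string, with cache misses computed in one batched call. Intended for
#' optimizer loops that revisit molecules.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Numeric vector of QED values.
#' @export
qed_cached <- function(smiles) {
  qed_score_from_descriptors(.ob_descriptors_cached(smiles))
}

# Batched descriptor computation for a SMILES vector: logP, TPSA and MW
# come from one Open Babel CLI invocation over the whole batch; counting
# descriptors (HBA, HBD, rotatable bonds, aromatic rings, structural
# alerts) are computed on the molecular graph. Invalid SMILES raise an
# error (callers validate first).
.ob_descriptors <- function(smiles) {
  p <- ob_batch_props(smiles)
  counts <- t(vapply(smiles, function(s) {
    g <- parse_molgraph(s)
    if (is.null(g)) stop(sprintf("invalid SMILES: %s", s))
    impl_h <- molgraph_implicit_h(g)
    c(HBA = sum(g$elements %in% c("N", "O")),
      HBD = sum(g$elements %in% c("N", "O") & impl_h > 0),
      ROTB = .count_rotatable(g),
      AROM = aromatic_ring_count(s),
      ALERTS = .alert_count_graph(g))
  }, numeric(5)))
  data.frame(
    MW = p$MW, logP = p$logP, HBA = counts[, "HBA"], HBD = counts[, "HBD"],
    PSA = p$TPSA, ROTB = as.integer(counts[, "ROTB"]),
    AROM = as.integer(counts[, "AROM"]),
    ALERTS = as.integer(counts[, "ALERTS"]),
    stringsAsFactors = FALSE
  )
}

# logP, TPSA, MW for a batch of valid SMILES in one obabel call.
ob_batch_props <- function(smiles) {
  in_file <- tempfile("props", fileext = ".smi")
  on.exit(unlink(in_file), add = TRUE)
  writeLines(smiles, in_file)
  res <- ob_run(c("-ismi", in_file, "-otxt", "--append", "logP TPSA MW"))
  lines <- strsplit(res$stdout, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != length(smiles)) {
    stop("descriptor batch failed: molecule count mismatch")
  }
  vals <- do.call(rbind, lapply(strsplit(trimws(lines), "[ \t]+"), as.numeric))
  data.frame(logP = vals[, 1], TPSA = vals[, 2], MW = vals[, 3])
}

#' Number of aromatic rings of a molecule
#'
#' Cycle rank of the aromatic-atom subgraph: atoms flagged aromatic in the
#' canonical SMILES, bonds between two such atoms that sit in a ring.
#' Naphthalene counts 2, biphenyl 2, benzene 1.
#'
#' @param smiles A valid SMILES string.
#' @return Integer ring count.
#' @export
aromatic_ring_count <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop(sprintf("invalid SMILES: %s", smiles))
  g <- parse_molgraph(can)
  arom <- smiles_aromatic_flags(can, g$n_atoms)
  if (is.null(arom) || !any(arom)) return(0L)
  in_ring_edge <- !molgraph_bridges_cached(g)
  sel <- arom[g$bonds[, "a"]] & arom[g$bonds[, "b"]] & in_ring_edge
  m <- sum(sel)
  if (m == 0L) return(0L)
  verts <- unique(as.integer(g$bonds[sel, c("a", "b")]))
  # components of the aromatic ring subgraph
  comp_count <- local({
    idx <- stats::setNames(seq_along(verts), verts)
    parent <- seq_along(verts)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (e in which(sel)) {
      a <- idx[[as.character(g$bonds[e, "a"])]]
      b <- idx[[as.character(g$bonds[e, "b"])]]
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
    length(unique(vapply(seq_along(verts), find, integer(1))))
  })
  as.integer(m - length(verts) + comp_count)
}

# Per-atom aromatic flags from the atom-token sequence of a canonical
# SMILES (atom order in the parsed graph matches token order).
smiles_aromatic_flags <- function(can, n_atoms) {
  toks <- regmatches(can, gregexpr(
    "\\[[^]]+\\]|Cl|Br|[BCNOPSFI]|[bcnops]", can))[[1]]
  if (length(toks) != n_atoms) return(NULL)
  vapply(toks, function(t) {
    if (startsWith(t, "[")) {
      body <- sub("^\\[([0-9]*)([A-Za-z@]+).*$", "\\2", t)
      substr(body, 1, 1) %in% letters
    } else {
      t %in% c("b", "c", "n", "o", "p", "s")
    }
  }, logical(1), USE.NAMES = FALSE)
}

# Curated structural-alert patterns (common reactive/unstable motifs used in
# hit triage: nitro, azide, acyl halide, aldehyde, peroxide, Michael
# acceptor, isocyanate, thiourea, hydrazine, epoxide/aziridine, disulfide,
# alkyl halide, anhydride, imine, long aliphatic chain).
.alert_smarts <- c(
  nitro = "[N+](=O)[O-]",
  azide = "N=[N+]=[N-]",
  acyl_halide = "C(=O)[Cl,Br,I]",
  aldehyde = "[CX3H1](=O)[#6]",
  peroxide = "[OX2][OX2]",
  michael_acceptor = "C=CC(=O)[!O]",
  isocyanate = "N=C=O",
  thiourea = "NC(=S)N",
  hydrazine = "[NX3][NX3]",
  three_ring_het = "C1[O,N]C1",
  disulfide = "[SX2][SX2]",
  alkyl_halide = "[CX4][Cl,Br,I]",
  anhydride = "C(=O)OC(=O)",
  acyclic_imine = "[CX3]=[NX2][!#7]",
  long_chain = "[CH2][CH2][CH2][CH2][CH2][CH2][CH2]"
)

# SMARTS-based alert counter (kept as the slower reference route; the
# graph-based matchers below are validated against it in the test suite).
.alert_counts_smarts <- function(sdf) {
  total <- integer(length(sdf))
  for (pat in .alert_smarts) {
    hits <- tryCatch(
      ChemmineR::smartsSearchOB(sdf, pat, uniqueMatches = TRUE),
      error = function(e) integer(length(sdf))
    )
    total <- total + as.integer(hits > 0)
  }
  total
}

# Graph-based matchers for the same fifteen alert motifs: number of motifs
# present (0/1 per motif), mirroring the SMARTS route.
.alert_count_graph <- function(g) {
  el <- g$elements
  ch <- g$charges
  impl_h <- molgraph_implicit_h(g)
  deg <- lengths(g$adj)
  bonds <- g$bonds
  hal <- c("F", "Cl", "Br", "I")
  heavy_hal <- c("Cl", "Br", "I")
  arom <- smiles_aromatic_flags(g$smiles, g$n_atoms)
  if (is.null(arom)) arom <- rep(FALSE, g$n_atoms)
  # neighbor lists with orders
  nb <- lapply(seq_len(g$n_atoms), function(i) {
    sel <- bonds[, "a"] == i | bonds[, "b"] == i
    if (!any(sel)) return(cbind(atom = integer(0), order = integer(0)))
    b <- bonds[sel, , drop = FALSE]
    cbind(atom = ifelse(b[, "a"] == i, b[, "b"], b[, "a"]), order = b[, "order"])
  })
  has_nb <- function(i, elem, order = NULL) {
    n <- nb[[i]]
    sel <- el[n[, "atom"]] %in% elem
    if (!is.null(order)) sel <- sel & n[, "order"] == order
    n[sel, "atom"]
  }
  in_ring <- molgraph_ring_atoms(g)
  bridges <- molgraph_bridges_cached(g)

  hits <- logical(15)
  names(hits) <- names(.alert_smarts)
  for (i in seq_len(g$n_atoms)) {
    ni <- nb[[i]]
    if (el[i] == "N" && ch[i] == 1L &&
        length(has_nb(i, "O", 2L)) >= 1L &&
        any(ch[has_nb(i, "O", 1L)] == -1L)) hits["nitro"] <- TRUE
    if (el[i] == "N" && ch[i] == 1L && deg[i] == 2L &&
        length(has_nb(i, "N", 2L)) == 2L) hits["azide"] <- TRUE
    if (el[i] == "C" && length(has_nb(i, "O", 2L)) >= 1L) {
      if (length(has_nb(i, hal, 1L)) >= 1L) hits["acyl_halide"] <- TRUE
      if (impl_h[i] >= 1L && length(has_nb(i, "C", 1L)) >= 1L)
        hits["aldehyde"] <- TRUE
      # anhydride: C(=O)-O-C(=O)
      for (o in has_nb(i, "O", 1L)) {
        others <- setdiff(has_nb(o, "C", 1L), i)
        if (any(vapply(others, function(c2)
          length(has_nb(c2, "O", 2L)) >= 1L, logical(1)))) hits["anhydride"] <- TRUE
      }
      # Michael acceptor: C=C-C(=O)[!O] (enone, aliphatic alkene only)
      if (length(has_nb(i, "O", 1L)) == 0L) {
        for (c2 in has_nb(i, "C", 1L)) {
          cc <- has_nb(c2, "C", 2L)
          if (!arom[c2] && any(!arom[cc])) hits["michael_acceptor"] <- TRUE
        }
      }
    }
    if (el[i] == "O" && ch[i] == 0L && length(has_nb(i, "O", 1L)) >= 1L)
      hits["peroxide"] <- TRUE
    if (el[i] == "S" && length(has_nb(i, "S", 1L)) >= 1L &&
        deg[i] <= 2L) hits["disulfide"] <- TRUE
    if (el[i] == "C" && length(has_nb(i, "S", 2L)) >= 1L &&
        length(has_nb(i, "N", 1L)) >= 2L) hits["thiourea"] <- TRUE
    if (el[i] == "N" && ch[i] == 0L && !in_ring[i] &&
        any(ch[has_nb(i, "N", 1L)] == 0L & !in_ring[has_nb(i, "N", 1L)]))
      hits["hydrazine"] <- TRUE
    if (el[i] == "N" && deg[i] == 2L && length(has_nb(i, "C", 2L)) >= 1L) {
      cc <- has_nb(i, "C", 2L)
      if (any(vapply(cc, function(c2) length(has_nb(c2, "O", 2L)) >= 1L,
                     logical(1))) && length(has_nb(i, "C", 1L)) == 0L &&
          impl_h[i] == 0L && deg[i] == 2L &&
          any(vapply(cc, function(c2) deg[c2] == 2L, logical(1))))
        hits["isocyanate"] <- TRUE
      # acyclic imine C=N-[!N]
      if (!in_ring[i] && !arom[i]) {
        others <- nb[[i]][nb[[i]][, "order"] == 1L, "atom"]
        if ((impl_h[i] > 0L && length(others) == 0L) ||
            any(el[others] != "N")) {
          cc2 <- has_nb(i, "C", 2L)
          if (any(!in_ring[cc2] & !arom[cc2])) hits["acyclic_imine"] <- TRUE
        }
      }
    }
    if (el[i] == "C" && length(has_nb(i, heavy_hal, 1L)) >= 1L &&
        sum(nb[[i]][, "order"] > 1L) == 0L && !arom[i])
      hits["alkyl_halide"] <- TRUE
  }
  # three-membered ring with O or N
  hits["three_ring_het"] <- .has_three_ring_het(g)
  # seven consecutive CH2 groups
  hits["long_chain"] <- .has_long_ch2_chain(g, impl_h, 7L)
  sum(hits)
}

.is_aromatic_atom <- function(g, i) {
  can <- g$smiles
  if (is.na(can)) return(FALSE)
  fl <- smiles_aromatic_flags(can, g$n_atoms)
  if (is.null(fl)) FALSE else fl[[i]]
}

.has_three_ring_het <- function(g) {
  bonds <- g$bonds
  if (nrow(bonds) < 3L) return(FALSE)
  adj <- g$adj
  for (e in seq_len(nrow(bonds))) {
    a <- bonds[e, "a"]; b <- bonds[e, "b"]
    common <- intersect(adj[[a]], adj[[b]])
    for (c3 in common) {
      if (any(g$elements[c(a, b, c3)] %in% c("O", "N")) &&
          all(g$elements[c(a, b, c3)] %in% c("C", "O", "N"))) return(TRUE)
    }
  }
  FALSE
}

.has_long_ch2_chain <- function(g, impl_h, k) {
  is_ch2 <- g$elements == "C" & impl_h == 2L & !molgraph_ring_atoms(g)
  if (sum(is_ch2) < k) return(FALSE)
  # longest path within CH2-only subgraph (paths, so DFS per start is fine
  # at fixture scale)
  best <- 0L
  for (s in which(is_ch2)) {
    stack <- list(list(v = s, seen = s))
    while (length(stack) > 0L) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      best <- max(best, length(fr$seen))
      if (best >= k) return(TRUE)
      for (w in g$adj[[fr$v]]) {
        if (is_ch2[w] && !(w %in% fr$seen)) {
          stack[[length(stack) + 1L]] <- list(v = w, seen = c(fr$seen, w))
        }
      }
    }
  }
  best >= k
}

# ---------------------------------------------------------------------------
# QED (quantitative estimate of druglikeness), weighted variant.
#
# Asymmetric double sigmoid (ADS) desirability functions with the published
# parameters of Bickerton et al. (2012), applied to eight descriptors; QED
# is the weighted geometric mean of the normalized desirabilities and lies
# in (0, 1].

.qed_ads_params <- list(
  MW     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764, d = 2.419764353,
             e = 49.22325677, f = 65.37051707, dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431, d = 4.581497897,
             e = 0.822739154, f = 0.576295591, dmax = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657, d = 4.435986202,
             e = 0.290141953, f = 1.300669958, dmax = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388, d = 1e-09,
             e = 0.713820843, f = 0.920922555, dmax = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.2232657, c = 62.90773554, d = 87.83366614,
             e = 12.01999824, f = 28.51324732, dmax = 104.5686167),
  ROTB   = c(a = 0.01, b = 272.4121427, c = 2.55837997, d = 1.565547684,
             e = 1.271567166, f = 2.758063707, dmax = 105.4420403),
  AROM   = c(a = 3.21778897, b = 957.7374108, c = 2.274627939, d = 1e-09,
             e = 1.317690384, f = 0.375760881, dmax = 312.337261),
  ALERTS = c(a = 0.01, b = 1199.094025, c = -0.09002883, d = 1e-09,
             e = 0.185904477, f = 0.875193782, dmax = 417.725314)
)

.qed_weights <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61, PSA = 0.06,
                  ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

.ads <- function(x, p) {
  p[["a"]] + p[["b"]] /
    (1 + exp(-(x - p[["c"]] + p[["d"]] / 2) / p[["e"]])) *
    (1 - 1 / (1 + exp(-(x - p[["c"]] - p[["d"]] / 2) / p[["f"]])))
}

qed_score_from_descriptors <- function(d) {
  desc <- list(MW = d$MW, ALOGP = d$logP, HBA = d$HBA, HBD = d$HBD,
               PSA = d$PSA, ROTB = d$ROTB, AROM = d$AROM, ALERTS = d$ALERTS)
  n <- length(d$MW)
  num <- numeric(n)
  for (k in names(.qed_weights)) {
    p <- .qed_ads_params[[k]]
    dk <- pmax(.ads(desc[[k]], p) / p[["dmax"]], 1e-10)
    dk <- pmin(dk, 1)
    num <- num + .qed_weights[[k]] * log(dk)
  }
  exp(num / sum(.qed_weights))
}

#' QED of one or more molecules
#'
#' @param smiles Character vector of SMILES strings.
#' @return Numeric vector of QED values in (0, 1].
#' @export
qed_score <- function(smiles) {
  qed_score_from_descriptors(.ob_descriptors(smiles))
}
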