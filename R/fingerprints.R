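# Binary molecular fingerprints over the heavy-atom graph.
#
# Two kinds are provided:
#   PATH6        - hashed linear paths of 1..6 bonds (plus single atoms),
#                  2048 bits, in the spirit of the topological path
#                  fingerprint commonly used for similarity search;
#   MORGAN2_1024 - circular (Morgan/ECFP-style) fingerprint of radius 2
#                  folded to 1024 bits.
#
# Both are computed on the canonicalized molecule, so they are invariant to
# the atom ordering of the input SMILES. Fingerprints are stored sparsely as
# sorted on-bit indices (0-based).

.fp_nbits <- c(PATH6 = 2048L, MORGAN2_1024 = 1024L)

# Deterministic 31-bit string hash (polynomial rolling hash, no external
# dependency; stable across platforms because it avoids integer overflow).
.hash_string <- function(s) {
  v <- utf8ToInt(s)
  h <- 7
  for (x in v) h <- (h * 131 + x) %% 2147483647
  as.integer(h)
}

# Mix a vector of integer codes into one 31-bit code.
.hash_codes <- function(codes) {
  h <- 11
  for (x in codes) h <- (h * 1000003 + (x %% 2147483647)) %% 2147483647
  as.integer(h)
}

#' Compute a molecular fingerprint
#'
#' @param smiles A single SMILES string (canonicalized internally).
#' @param kind `"PATH6"` (linear paths up to six bonds, 2048 bits) or
#'   `"MORGAN2_1024"` (radius-2 circular fingerprint, 1024 bits).
#' @return An object of class `fingerprint`: list with `bits` (sorted
#'   0-based on-bit indices), `nbits`, `kind`.
#' @export
fingerprint <- function(smiles, kind = c("MORGAN2_1024", "PATH6")) {
  kind <- match.arg(kind)
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop(sprintf("invalid SMILES: %s", smiles))
  g <- parse_molgraph(can)
  if (is.null(g)) stop(sprintf("invalid SMILES: %s", smiles))
  fingerprint_from_graph(g, kind)
}

# Fingerprint from an already-parsed (canonical-order) molgraph.
fingerprint_from_graph <- function(g, kind = c("MORGAN2_1024", "PATH6")) {
  kind <- match.arg(kind)
  nbits <- .fp_nbits[[kind]]
  codes <- if (kind == "PATH6") .path_codes(g, max_len = 6L) else .morgan_codes(g, radius = 2L)
  bits <- sort(unique(codes %% nbits))
  structure(list(bits = as.integer(bits), nbits = nbits, kind = kind),
            class = "fingerprint")
}

# Linear-path enumeration: all simple paths of 0..max_len bonds, each path
# hashed from its atom/bond label sequence (direction-independent).
.path_codes <- function(g, max_len = 6L) {
  n <- g$n_atoms
  bond_order <- new.env(parent = emptyenv())
  if (nrow(g$bonds) > 0L) {
    for (i in seq_len(nrow(g$bonds))) {
      key <- paste0(min(g$bonds[i, 1:2]), "_", max(g$bonds[i, 1:2]))
      assign(key, g$bonds[i, "order"], envir = bond_order)
    }
  }
  get_order <- function(a, b) get(paste0(min(a, b), "_", max(a, b)), envir = bond_order)

  codes <- integer(0)
  label <- vapply(seq_len(n), function(i) {
    .hash_string(paste0(g$elements[i], ":", g$charges[i]))
  }, integer(1))
  # single atoms
  codes <- c(codes, label)

  # DFS over simple paths from every start atom
  for (start in seq_len(n)) {
    stack <- list(list(path = start))
    while (length(stack) > 0L) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      path <- fr$path
      last <- path[[length(path)]]
      if (length(path) - 1L >= max_len) next
      for (w in g$adj[[last]]) {
        if (w %in% path) next
        new_path <- c(path, w)
        # label sequence: atom, bond, atom, bond, ...
        seq_fwd <- integer(0)
        for (k in seq_along(new_path)) {
          seq_fwd <- c(seq_fwd, label[new_path[[k]]])
          if (k < length(new_path)) {
            seq_fwd <- c(seq_fwd, get_order(new_path[[k]], new_path[[k + 1L]]))
          }
        }
        seq_rev <- rev(seq_fwd)
        # canonical direction: lexicographically smaller sequence
        use <- if (isTRUE(all(seq_fwd == seq_rev)) ||
                   .seq_less(seq_fwd, seq_rev)) seq_fwd else seq_rev
        codes <- c(codes, .hash_codes(use))
        stack[[length(stack) + 1L]] <- list(path = new_path)
      }
    }
  }
  codes
}

.seq_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[[i]] != b[[i]]) return(a[[i]] < b[[i]])
  }
  FALSE
}

# Morgan/ECFP-style iterative neighborhood hashing, radius 0..radius.
.morgan_codes <- function(g, radius = 2L) {
  n <- g$n_atoms
  impl_h <- molgraph_implicit_h(g)
  degree <- lengths(g$adj)
  in_ring <- molgraph_ring_atoms(g)
  # initial atom invariants (Daylight-style tuple)
  inv <- vapply(seq_len(n), function(i) {
    .hash_codes(c(
      .hash_string(g$elements[[i]]), degree[[i]], impl_h[[i]],
      g$charges[[i]] + 10L, as.integer(in_ring[[i]])
    ))
  }, integer(1))
  bond_order <- matrix(0L, n, n)
  if (nrow(g$bonds) > 0L) {
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds[i, "a"]; b <- g$bonds[i, "b"]; o <- g$bonds[i, "order"]
      bond_order[a, b] <- o; bond_order[b, a] <- o
    }
  }
  codes <- inv
  cur <- inv
  for (r in seq_len(radius)) {
    nxt <- integer(n)
    for (i in seq_len(n)) {
      nbs <- g$adj[[i]]
      if (length(nbs) == 0L) { nxt[[i]] <- .hash_codes(c(r, cur[[i]])); next }
      pairs <- cbind(bond_order[i, nbs], cur[nbs])
      ord <- order(pairs[, 1], pairs[, 2])
      flat <- as.integer(t(pairs[ord, , drop = FALSE]))
      nxt[[i]] <- .hash_codes(c(r, cur[[i]], flat))
    }
    cur <- nxt
    codes <- c(codes, cur)
  }
  codes
}

#' Jaccard (Tanimoto) distance between two fingerprints
#'
#' @param a,b Fingerprints of the same kind.
#' @return `1 - |intersection| / |union|`, in `[0, 1]`; 0 for two empty
#'   fingerprints.
#' @export
jaccard_distance <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (!identical(a$kind, b$kind)) stop("fingerprint kind mismatch")
  1 - tanimoto_similarity_bits(a$bits, b$bits)
}

# Tanimoto similarity of two sorted on-bit index vectors.
tanimoto_similarity_bits <- function(ba, bb) {
  if (length(ba) == 0L && length(bb) == 0L) return(1)
  inter <- length(intersect(ba, bb))
  inter / (length(ba) + length(bb) - inter)
}

#' Fingerprints for a vector of SMILES
#'
#' @param smiles Character vector of SMILES strings.
#' @param kind Fingerprint kind, see [fingerprint()].
#' @return List of `fingerprint` objects.
#' @export
fingerprint_set <- function(smiles, kind = c("MORGAN2_1024", "PATH6")) {
  kind <- match.arg(kind)
  lapply(smiles, fingerprint, kind = kind)
}

# Dense 0/1 matrix (n x nbits) from a list of fingerprints; used for fast
# batched Tanimoto computations in the GP and similarity search.
fp_matrix <- function(fps) {
  stopifnot(length(fps) > 0L)
  nbits <- fps[[1]]$nbits
  m <- matrix(0, nrow = length(fps), ncol = nbits)
  for (i in seq_along(fps)) m[i, fps[[i]]$bits + 1L] <- 1
  m
}

# Pairwise Tanimoto similarity between rows of two 0/1 matrices.
tanimoto_cross <- function(A, B) {
  inter <- A %*% t(B)
  ra <- rowSums(A); rb <- rowSums(B)
  un <- outer(ra, rb, "+") - inter
  sim <- inter / un
  sim[un == 0] <- 1  # two empty fingerprints
  sim
}
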