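# A compact SELFIES-style molecular string representation: a token alphabet
# of atoms (with optional bond-order prefix), branches and rings, decoded by
# a valence-constrained derivation so that EVERY token sequence yields a
# valid molecule. This robustness is what makes single-token genetic edits
# safe. The dialect covers the neutral organic subset (C, N, O, S, P, F,
# Cl, Br, I) with nested branches and (kekulized) rings, which is the
# chemistry emitted by the synthetic library generator and the genetic
# algorithms.

.sf_valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                 F = 1L, Cl = 1L, Br = 1L, I = 1L)

.sf_atom_tokens <- c(
  "[C]", "[=C]", "[#C]", "[N]", "[=N]", "[#N]", "[O]", "[=O]",
  "[S]", "[=S]", "[P]", "[F]", "[Cl]", "[Br]", "[I]"
)

# index alphabet for branch lengths / ring distances (value = position)
.sf_index_tokens <- paste0("[n", 1:30, "]")

#' The SELFIES-style token alphabet
#'
#' @return Character vector of all tokens the decoder understands.
#' @export
selfies_alphabet <- function() {
  c(.sf_atom_tokens, "[Branch]", "[Ring]", "[=Ring]", .sf_index_tokens)
}

#' Tokenize a SELFIES-style string
#'
#' @param s A string of bracketed tokens.
#' @return Character vector of tokens.
#' @export
selfies_tokens <- function(s) {
  regmatches(s, gregexpr("\\[[^][]*\\]", s))[[1]]
}

.sf_parse_atom <- function(tok) {
  body <- substr(tok, 2, nchar(tok) - 1L)
  order <- 1L
  if (startsWith(body, "=")) { order <- 2L; body <- substring(body, 2) }
  else if (startsWith(body, "#")) { order <- 3L; body <- substring(body, 2) }
  if (!body %in% names(.sf_valence)) return(NULL)
  list(element = body, order = order)
}

# Index value of a token (1-based). Non-index tokens map onto the index
# range by alphabet position, so every sequence stays decodable.
.sf_index_value <- function(tok) {
  m <- match(tok, .sf_index_tokens)
  if (!is.na(m)) return(m)
  m2 <- match(tok, selfies_alphabet())
  if (is.na(m2)) 1L else ((m2 - 1L) %% length(.sf_index_tokens)) + 1L
}

#' Decode a SELFIES-style token sequence into a molecule
#'
#' Derivation caps every bond order by the remaining valence of both
#' partners; tokens that cannot be realized (no free valence, dangling
#' branch or ring reference) are skipped or truncated rather than failing,
#' so the decoded molecule is always valid. The empty sequence decodes to
#' methane.
#'
#' @param tokens Character vector of tokens, or a single string of
#'   concatenated bracketed tokens.
#' @return Canonical SMILES of the decoded molecule.
#' @export
selfies_decode <- function(tokens) {
  if (length(tokens) == 1L && grepl("]", tokens, fixed = TRUE)) {
    tokens <- selfies_tokens(tokens)
  }
  st <- new.env(parent = emptyenv())
  st$elements <- character(0)
  st$free <- integer(0)
  st$bonds <- list()
  .sf_run(tokens, st, attach = 0L, max_atoms = 150L)
  if (length(st$elements) == 0L) return("C")
  bonds <- if (length(st$bonds)) do.call(rbind, st$bonds) else
    matrix(integer(0), ncol = 3)
  colnames(bonds) <- c("a", "b", "order")
  smi <- molgraph_build_smiles(st$elements, bonds)
  if (is.na(smi)) "C" else smi
}

# Recursive derivation over a token window. `attach` is the atom the first
# derived atom bonds to (0 = chain start). Mutates `st`; returns nothing.
.sf_run <- function(tokens, st, attach, max_atoms) {
  cur <- attach
  i <- 1L
  n_tok <- length(tokens)
  while (i <= n_tok) {
    tok <- tokens[[i]]
    atom <- .sf_parse_atom(tok)
    if (!is.null(atom)) {
      if (cur > 0L && st$free[cur] == 0L) return(invisible())  # derivation ends
      if (length(st$elements) >= max_atoms) return(invisible())
      cap <- .sf_valence[[atom$element]]
      st$elements <- c(st$elements, atom$element)
      st$free <- c(st$free, cap)
      new_idx <- length(st$elements)
      if (cur > 0L) {
        b <- min(atom$order, st$free[cur], cap)
        st$bonds[[length(st$bonds) + 1L]] <- c(new_idx, cur, b)
        st$free[cur] <- st$free[cur] - b
        st$free[new_idx] <- st$free[new_idx] - b
      }
      cur <- new_idx
      i <- i + 1L
      next
    }
    if (tok == "[Branch]") {
      if (i >= n_tok || cur == 0L || st$free[cur] == 0L) { i <- i + 1L; next }
      q <- .sf_index_value(tokens[[i + 1L]])
      win <- tokens[seq(i + 2L, length.out = min(q, n_tok - i - 1L))]
      .sf_run(win, st, attach = cur, max_atoms = max_atoms)
      i <- i + 2L + length(win)
      next
    }
    if (tok %in% c("[Ring]", "[=Ring]")) {
      if (i >= n_tok || cur == 0L) { i <- i + 1L; next }
      q <- .sf_index_value(tokens[[i + 1L]])
      partner <- cur - q
      want <- if (tok == "[=Ring]") 2L else 1L
      if (partner >= 1L && partner != cur &&
          !.sf_bond_exists(st$bonds, cur, partner)) {
        b <- min(want, st$free[cur], st$free[partner])
        if (b >= 1L) {
          st$bonds[[length(st$bonds) + 1L]] <- c(cur, partner, b)
          st$free[cur] <- st$free[cur] - b
          st$free[partner] <- st$free[partner] - b
        }
      }
      i <- i + 2L
      next
    }
    # stray index token: skipped
    i <- i + 1L
  }
  invisible()
}

.sf_bond_exists <- function(bonds, a, b) {
  for (bd in bonds) {
    if ((bd[1] == a && bd[2] == b) || (bd[1] == b && bd[2] == a)) return(TRUE)
  }
  FALSE
}

#' Encode a molecule as a SELFIES-style token sequence
#'
#' DFS spanning-tree encoding with branch and ring tokens; round-trips
#' through [selfies_decode()] to the same molecule for the supported
#' chemistry (neutral organic subset, kekulized rings, branch subtrees and
#' ring-closure distances within the index alphabet).
#'
#' @param smiles A SMILES string.
#' @return Character vector of tokens, or `NULL` if the molecule cannot be
#'   represented in this dialect.
#' @export
selfies_encode <- function(smiles) {
  g <- parse_molgraph(canonical_smiles(smiles))
  if (is.null(g)) return(NULL)
  if (any(!(g$elements %in% names(.sf_valence))) || any(g$charges != 0L) ||
      g$radical || molgraph_n_fragments(g) != 1L) {
    return(NULL)
  }
  # sulfur/phosphorus above the dialect's fixed valence cannot round-trip
  bos <- molgraph_bond_order_sum(g)
  if (any(bos > .sf_valence[g$elements])) return(NULL)
  n <- g$n_atoms
  bond_of <- matrix(0L, n, n)
  if (nrow(g$bonds) > 0L) {
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds[i, "a"]; b <- g$bonds[i, "b"]
      bond_of[a, b] <- bond_of[b, a] <- g$bonds[i, "order"]
    }
  }
  env <- new.env(parent = emptyenv())
  env$visited <- logical(n)
  env$emit_pos <- integer(n)   # derivation index of each atom
  env$count <- 0L
  env$edge_done <- matrix(FALSE, n, n)
  env$failed <- FALSE

  dfs <- function(v, incoming_order) {
    env$visited[v] <- TRUE
    env$count <- env$count + 1L
    env$emit_pos[v] <- env$count
    prefix <- c("", "=", "#")[incoming_order]
    toks <- paste0("[", prefix, g$elements[[v]], "]")
    nbs <- which(bond_of[v, ] > 0L)
    # ring-closure edges to already-visited atoms
    for (b in nbs[env$visited[nbs]]) {
      if (env$edge_done[v, b]) next
      env$edge_done[v, b] <- env$edge_done[b, v] <- TRUE
      q <- env$emit_pos[v] - env$emit_pos[b]
      if (q < 1L || q > length(.sf_index_tokens)) { env$failed <- TRUE; next }
      ring_tok <- if (bond_of[v, b] >= 2L) "[=Ring]" else "[Ring]"
      toks <- c(toks, ring_tok, .sf_index_tokens[[q]])
    }
    children <- nbs[!env$visited[nbs]]
    if (length(children) == 0L) return(toks)
    # visit small side chains first so the largest subtree stays unwrapped on
    # the main chain (branch windows are limited by the index alphabet);
    # child order is fixed BEFORE recursion because ring indices refer to
    # derivation order
    if (length(children) > 1L) {
      approx_size <- vapply(children, function(ch) {
        .component_size_avoiding(g, start = ch, avoid = which(env$visited))
      }, integer(1))
      children <- children[order(approx_size, children)]
    }
    subs <- list()
    for (ch in children) {
      if (env$visited[ch]) next   # may have been reached through a sibling
      env$edge_done[v, ch] <- env$edge_done[ch, v] <- TRUE
      subs[[length(subs) + 1L]] <- dfs(ch, bond_of[v, ch])
    }
    if (length(subs) > 0L) {
      # all but the last subtree are wrapped as branches; emission must keep
      # visitation order because ring indices refer to derivation order
      for (k in seq_along(subs)) {
        if (k < length(subs)) {
          if (length(subs[[k]]) > length(.sf_index_tokens)) {
            env$failed <- TRUE
            next
          }
          toks <- c(toks, "[Branch]", .sf_index_tokens[[length(subs[[k]])]],
                    subs[[k]])
        } else {
          toks <- c(toks, subs[[k]])
        }
      }
    }
    toks
  }
  tokens <- dfs(1L, 1L)
  if (env$failed || any(!env$visited)) return(NULL)
  tokens
}

# Size of the connected component reachable from `start` without passing
# through `avoid` atoms (cheap subtree-size heuristic for the encoder).
.component_size_avoiding <- function(g, start, avoid) {
  seen <- logical(g$n_atoms)
  seen[avoid] <- TRUE
  if (seen[start]) return(0L)
  seen[start] <- TRUE
  queue <- start
  count <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1]]; queue <- queue[-1]
    count <- count + 1L
    for (w in g$adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  count
}
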