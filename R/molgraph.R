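# Lightweight molecular-graph view of a molecule, parsed from the SDF block
# that Open Babel produces for a SMILES string. Heavy atoms only; hydrogens
# are implicit. This is the substrate for fingerprints, scaffold pruning and
# the genetic-algorithm edit operations.

# Default valences for implicit-hydrogen bookkeeping on the organic subset.
.default_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, Cl = 1, Br = 1, I = 1, B = 3)

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles A single SMILES string.
#' @return A list of class `molgraph` with elements `elements` (character),
#'   `charges` (integer per atom), `bonds` (matrix with columns a, b, order),
#'   `n_atoms`, `radical` (logical: any radical-electron atom), `adj`
#'   (adjacency list), `smiles` (the input). `NULL` if the SMILES does not
#'   parse.
#' @keywords internal
parse_molgraph <- function(smiles) {
  use_cache <- is.character(smiles) && length(smiles) == 1L &&
    !is.na(smiles) && nchar(smiles) < 400L
  if (use_cache) {
    hit <- .molgraph_cache[[smiles]]
    if (!is.null(hit)) return(if (isFALSE(hit)) NULL else hit)
  }
  sdf_text <- ob_smiles_to_sdf(smiles)
  g <- if (is.null(sdf_text)) NULL else
    molgraph_from_sdf_text(sdf_text, smiles = smiles)
  if (use_cache) .molgraph_cache[[smiles]] <- if (is.null(g)) FALSE else g
  g
}

# Parse results are immutable, so they are memoized package-wide; failed
# parses are cached as FALSE.
.molgraph_cache <- new.env(parent = emptyenv())

# Parse the first molecule of a V2000 molfile/SDF text into a molgraph.
molgraph_from_sdf_text <- function(sdf_text, smiles = NA_character_) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  counts_i <- grep("V2000", lines, fixed = TRUE)
  if (length(counts_i) == 0L) return(NULL)
  counts_i <- counts_i[[1]]
  n_atoms <- as.integer(substr(lines[counts_i], 1, 3))
  n_bonds <- as.integer(substr(lines[counts_i], 4, 6))
  if (is.na(n_atoms) || n_atoms < 1L) return(NULL)

  atom_lines <- lines[(counts_i + 1L):(counts_i + n_atoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  coords <- cbind(
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30))
  )
  # legacy per-atom fields: charge code (cols 37-39), valence (cols 49-51)
  chg_code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  valence_field <- suppressWarnings(as.integer(substr(atom_lines, 49, 51)))
  chg_code[is.na(chg_code)] <- 0L
  valence_field[is.na(valence_field)] <- 0L
  charge_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
                  `6` = -2L, `7` = -3L)
  charges <- integer(n_atoms)
  nz <- chg_code != 0L
  charges[nz] <- charge_map[as.character(chg_code[nz])]
  doublet <- chg_code == 4L  # molfile code 4 = doublet radical

  bonds <- matrix(integer(0), ncol = 3, dimnames = list(NULL, c("a", "b", "order")))
  if (!is.na(n_bonds) && n_bonds > 0L) {
    bond_lines <- lines[(counts_i + n_atoms + 1L):(counts_i + n_atoms + n_bonds)]
    bonds <- cbind(
      a = as.integer(substr(bond_lines, 1, 3)),
      b = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  }

  # property block: modern charge/radical specifications override atom fields
  prop_lines <- lines[seq_along(lines) > counts_i + n_atoms + max(0L, n_bonds)]
  for (ln in grep("^M  CHG", prop_lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "[ ]+")[[1]])
    k <- flds[[1]]
    if (length(flds) >= 1L + 2L * k) {
      charges <- replace(charges, flds[seq(2, by = 2, length.out = k)],
                         flds[seq(3, by = 2, length.out = k)])
    }
  }
  has_rad_line <- any(grepl("^M  RAD", prop_lines))

  # radical detection: an explicit valence field that disagrees with the
  # default valence of the (charge-adjusted) element marks unpaired electrons
  # for the C/N/O organic core; hypervalent S/P are left alone.
  expected <- .default_valence[elements] + ifelse(elements == "N" & charges > 0, 1L,
                                          ifelse(elements %in% c("N", "O") & charges < 0, charges, 0L))
  rad_by_valence <- valence_field != 0L &
    elements %in% c("C", "N", "O") &
    valence_field != expected[]
  # 15 in the valence field means "zero valence" per the molfile spec
  rad_by_valence[valence_field == 15L & expected == 0] <- FALSE
  radical <- has_rad_line || any(doublet) || any(rad_by_valence, na.rm = TRUE)

  adj <- vector("list", n_atoms)
  if (nrow(bonds) > 0L) {
    for (i in seq_len(nrow(bonds))) {
      a <- bonds[i, "a"]; b <- bonds[i, "b"]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }

  structure(
    list(elements = elements, charges = charges, bonds = bonds,
         coords = coords, n_atoms = n_atoms, radical = radical,
         adj = adj, smiles = smiles),
    class = "molgraph"
  )
}

# Number of connected components of the heavy-atom graph.
molgraph_n_fragments <- function(g) {
  n <- g$n_atoms
  if (n == 0L) return(0L)
  seen <- logical(n)
  comps <- 0L
  for (start in seq_len(n)) {
    if (seen[start]) next
    comps <- comps + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0L) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in g$adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  comps
}

# Sum of explicit bond orders incident to each atom.
molgraph_bond_order_sum <- function(g) {
  s <- numeric(g$n_atoms)
  if (nrow(g$bonds) > 0L) {
    for (i in seq_len(nrow(g$bonds))) {
      o <- g$bonds[i, "order"]
      s[g$bonds[i, "a"]] <- s[g$bonds[i, "a"]] + o
      s[g$bonds[i, "b"]] <- s[g$bonds[i, "b"]] + o
    }
  }
  s
}

# Implicit hydrogen count per atom (never negative).
molgraph_implicit_h <- function(g) {
  base <- .default_valence[g$elements]
  base[is.na(base)] <- 0
  # simple charge adjustment on N/O covers the ionizable groups we emit
  base <- base + ifelse(g$elements == "N", g$charges,
                 ifelse(g$elements == "O", g$charges, 0))
  pmax(0, base - molgraph_bond_order_sum(g))
}

# Atoms that belong to at least one ring: endpoints of non-bridge edges.
molgraph_ring_atoms <- function(g) {
  n <- g$n_atoms
  in_ring <- logical(n)
  if (nrow(g$bonds) == 0L) return(in_ring)
  bridges <- molgraph_bridges_cached(g)
  for (i in seq_len(nrow(g$bonds))) {
    if (!bridges[i]) {
      in_ring[g$bonds[i, "a"]] <- TRUE
      in_ring[g$bonds[i, "b"]] <- TRUE
    }
  }
  in_ring
}

# Bridge (cut-edge) detection via iterative DFS with discovery/low times.
# Returns a logical vector aligned with the rows of g$bonds.
molgraph_bridges <- function(g) {
  n <- g$n_atoms
  m <- nrow(g$bonds)
  if (m == 0L) return(logical(0))
  # adjacency with edge ids
  adj <- vector("list", n)
  for (i in seq_len(m)) {
    a <- g$bonds[i, "a"]; b <- g$bonds[i, "b"]
    adj[[a]] <- rbind(adj[[a]], c(b, i))
    adj[[b]] <- rbind(adj[[b]], c(a, i))
  }
  disc <- integer(n); low <- integer(n)
  is_bridge <- logical(m)
  timer <- 0L
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    # iterative DFS stack: rows of (vertex, parent-edge-id, next-neighbor-ptr)
    stack <- list(list(v = root, pe = 0L, ptr = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack) > 0L) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      nb <- adj[[v]]
      if (is.null(nb) || fr$ptr > nrow(nb)) {
        stack[[length(stack)]] <- NULL
        if (length(stack) > 0L) {
          pf <- stack[[length(stack)]]
          low[pf$v] <- min(low[pf$v], low[v])
          if (low[v] > disc[pf$v]) is_bridge[fr$pe] <- TRUE
        }
        next
      }
      w <- nb[fr$ptr, 1]; eid <- nb[fr$ptr, 2]
      stack[[length(stack)]]$ptr <- fr$ptr + 1L
      if (eid == fr$pe) next
      if (disc[w] == 0L) {
        timer <- timer + 1L; disc[w] <- low[w] <- timer
        stack[[length(stack) + 1L]] <- list(v = w, pe = eid, ptr = 1L)
      } else {
        low[v] <- min(low[v], disc[w])
      }
    }
  }
  is_bridge
}

# Emit V2000 molfile text for a constructed graph so Open Babel can
# canonicalize arbitrary fragments. (ChemmineR's SDF writer does not
# fixed-width-format atom blocks built from scratch, which strict MDL
# readers reject, so the few fixed-width lines are emitted directly.)
molgraph_to_molfile <- function(elements, bonds, charges = NULL, coords = NULL,
                                name = "mol") {
  n <- length(elements)
  m <- nrow(bonds)
  if (is.null(coords)) coords <- matrix(0, nrow = n, ncol = 3)
  lines <- c(
    name, " dockbench", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m)
  )
  lines <- c(lines, vapply(seq_len(n), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[i, 1], coords[i, 2], coords[i, 3], elements[[i]])
  }, character(1)))
  if (m > 0L) {
    lines <- c(lines, vapply(seq_len(m), function(i) {
      sprintf("%3d%3d%3d  0  0  0  0", bonds[i, "a"], bonds[i, "b"],
              bonds[i, "order"])
    }, character(1)))
  }
  if (!is.null(charges) && any(charges != 0L)) {
    nz <- which(charges != 0L)
    lines <- c(lines, sprintf("M  CHG%3d%s", length(nz),
                              paste(sprintf("%4d%4d", nz, charges[nz]),
                                    collapse = "")))
  }
  paste(c(lines, "M  END", "$$$$"), collapse = "\n")
}

# Canonical SMILES of a constructed graph, NA if Open Babel rejects it.
molgraph_build_smiles <- function(elements, bonds, charges = NULL) {
  sdf_text <- molgraph_to_molfile(elements, bonds, charges)
  out <- ob_sdf_to_smiles(paste0(sdf_text, "\n"))
  out[[1]]
}

# Bridge vector memoized per molecule (keyed by the graph's SMILES).
.bridge_cache <- new.env(parent = emptyenv())

molgraph_bridges_cached <- function(g) {
  key <- g$smiles
  if (is.na(key) || nchar(key) >= 400L) return(molgraph_bridges(g))
  hit <- .bridge_cache[[key]]
  if (!is.null(hit)) return(hit)
  b <- molgraph_bridges(g)
  .bridge_cache[[key]] <- b
  b
}

# Light graph view over raw (elements, bonds, charges) pieces. All graph
# consumers (fragment count, implicit hydrogens, descriptors, fingerprints)
# are invariant to atom order, so a raw edit-product graph can stand in for
# the parsed canonical form.
.raw_graph <- function(elements, bonds, charges) {
  n <- length(elements)
  adj <- vector("list", n)
  if (nrow(bonds) > 0L) {
    for (i in seq_len(nrow(bonds))) {
      a <- bonds[i, "a"]; b <- bonds[i, "b"]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  structure(list(elements = elements, charges = charges, bonds = bonds,
                 n_atoms = n, radical = FALSE, adj = adj,
                 smiles = NA_character_),
            class = "molgraph")
}

# Batch-convert several constructed graphs to canonical SMILES in one Open
# Babel call (resuming after unparseable molecules); NA where conversion
# failed. Successful outputs are primed into the canonicalization cache
# (canonical SMILES is idempotent) and, with `prime_graphs`, into the
# molgraph cache from the raw pieces (closed-shell edit products only).
batch_build_smiles <- function(raws, prime_graphs = TRUE) {
  n <- length(raws)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  texts <- vapply(seq_len(n), function(i) {
    r <- raws[[i]]
    molgraph_to_molfile(r$elements, r$bonds, r$charges, name = paste0("idx", i))
  }, character(1))
  start <- 1L
  while (start <= n) {
    res <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SDF", "CAN", paste0(paste(texts[start:n], collapse = "\n"), "\n"))),
      error = function(e) ""
    )
    got <- 0L
    for (ln in strsplit(res, "\n", fixed = TRUE)[[1]]) {
      parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(parts) < 2L) next
      idx <- suppressWarnings(as.integer(sub("^idx", "", parts[[2]])))
      if (!is.na(idx) && nzchar(parts[[1]])) {
        out[idx] <- parts[[1]]
        got <- max(got, idx)
      }
    }
    start <- if (got >= start) got + 2L else start + 1L
  }
  for (i in seq_len(n)) {
    s <- out[[i]]
    if (is.na(s) || nchar(s) >= 400L) next
    .canon_cache[[s]] <- s
    if (prime_graphs && is.null(.molgraph_cache[[s]])) {
      g <- .raw_graph(raws[[i]]$elements, raws[[i]]$bonds, raws[[i]]$charges)
      g$smiles <- s
      .molgraph_cache[[s]] <- g
    }
  }
  out
}

# Batch SMILES -> molgraph cache priming: one Open Babel call for the whole
# vector instead of one per molecule.
prime_molgraph_cache <- function(smiles) {
  smiles <- unique(smiles[!is.na(smiles) & nchar(smiles) < 400L])
  miss <- smiles[vapply(smiles, function(s) is.null(.molgraph_cache[[s]]),
                        logical(1))]
  if (length(miss) == 0L) return(invisible())
  src <- paste0(miss, " idx", seq_along(miss), collapse = "\n")
  res <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", paste0(src, "\n"))),
    error = function(e) ""
  )
  blocks <- strsplit(res, "\\$\\$\\$\\$\n?")[[1]]
  for (b in blocks) {
    if (!grepl("V2000", b, fixed = TRUE)) next
    title <- strsplit(b, "\n", fixed = TRUE)[[1]][[1]]
    idx <- suppressWarnings(as.integer(sub("^.*idx", "", title)))
    if (is.na(idx) || idx < 1L || idx > length(miss)) next
    g <- molgraph_from_sdf_text(b, smiles = miss[[idx]])
    if (!is.null(g)) .molgraph_cache[[miss[[idx]]]] <- g
  }
  invisible()
}
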