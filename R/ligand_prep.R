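# Ligand preparation: SMILES -> validated, protonation-adjusted, 3D-embedded,
# Gasteiger-charged ligand record, deterministically. Chemistry is delegated
# to Open Babel: pH transform model for protonation, rule-based 3D builder
# plus MMFF94 refinement for embedding, Gasteiger charges and torsion-tree
# serialization at PDBQT emission.

#' Rejection reason for a ligand that fails preparation
#'
#' @param code One of `"UNPARSEABLE"`, `"MULTI_FRAGMENT"`, `"RADICAL"`,
#'   `"EMBED_FAILED"`, `"REFINE_FAILED"`.
#' @param detail Free-text explanation.
#' @return Object of class `rejection_reason`.
#' @export
rejection_reason <- function(code, detail = "") {
  code <- match.arg(code, c("UNPARSEABLE", "MULTI_FRAGMENT", "RADICAL",
                            "EMBED_FAILED", "REFINE_FAILED"))
  structure(list(code = code, detail = detail), class = "rejection_reason")
}

#' @export
print.rejection_reason <- function(x, ...) {
  cat(sprintf("<rejected: %s> %s\n", x$code, x$detail))
  invisible(x)
}

#' Is an object a rejection?
#' @param x Any object.
#' @return `TRUE` if `x` is a `rejection_reason`.
#' @export
is_rejected <- function(x) inherits(x, "rejection_reason")

#' Validate a ligand SMILES
#'
#' A ligand is accepted iff it parses, consists of exactly one molecular
#' fragment, and carries no radical electrons. Rejection is returned as a
#' value, never thrown.
#'
#' @param smiles A single SMILES string.
#' @return `TRUE` if the ligand is acceptable, otherwise a
#'   [rejection_reason()] with code `UNPARSEABLE`, `MULTI_FRAGMENT` or
#'   `RADICAL`.
#' @export
validate_ligand <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    return(rejection_reason("UNPARSEABLE", "empty or non-string input"))
  }
  g <- parse_molgraph(smiles)
  if (is.null(g)) {
    return(rejection_reason("UNPARSEABLE", sprintf("cannot parse %s", smiles)))
  }
  if (molgraph_n_fragments(g) > 1L) {
    return(rejection_reason("MULTI_FRAGMENT",
                            sprintf("%d fragments", molgraph_n_fragments(g))))
  }
  if (g$radical) {
    return(rejection_reason("RADICAL", "radical electrons present"))
  }
  TRUE
}

#' Embed a single 3D conformer
#'
#' Builds one 3D conformation with Open Babel's deterministic rule-based
#' builder and refines it with MMFF94 (at most `steps` iterations,
#' convergence criterion `crit`). Defined stereocenters are preserved;
#' undefined stereocenters receive a fixed configuration that is identical
#' across runs, keeping the full pipeline deterministic.
#'
#' @param smiles Protonation-adjusted SMILES.
#' @param seed Integer seed recorded in the output (the builder itself is
#'   deterministic and does not consume randomness).
#' @param steps Maximum force-field iterations (default 1000).
#' @param crit Convergence criterion on the energy (default 1e-4).
#' @return List with `elements`, `coords` (n x 3 matrix, Angstrom),
#'   `sdf_text`; or a [rejection_reason()] with code `EMBED_FAILED`.
#' @export
embed_conformer <- function(smiles, seed = 0L, steps = 1000L, crit = 1e-4) {
  sdf_text <- ob_embed3d(smiles, steps = steps, crit = crit)
  if (is.null(sdf_text)) {
    return(rejection_reason("EMBED_FAILED", sprintf("3D build failed for %s", smiles)))
  }
  g <- molgraph_from_sdf_text(sdf_text, smiles = smiles)
  if (is.null(g) || any(!is.finite(g$coords))) {
    return(rejection_reason("REFINE_FAILED", "non-finite coordinates after refinement"))
  }
  list(elements = g$elements, coords = g$coords, sdf_text = sdf_text, seed = seed)
}

# Net formal charge of a molecule, from its graph.
net_formal_charge <- function(smiles) {
  g <- parse_molgraph(smiles)
  if (is.null(g)) return(NA_integer_)
  sum(g$charges)
}

#' Prepare a ligand for docking
#'
#' Full deterministic pipeline: validation, (de)protonation at the requested
#' pH, 3D embedding with force-field refinement, Gasteiger partial charges
#' and PDBQT serialization.
#'
#' @param smiles Input SMILES string.
#' @param pH pH for the protonation adjustment (default 7.4).
#' @param seed Integer seed recorded in the record (default 0).
#' @param engine Protonation engine: any function `SMILES -> SMILES`.
#'   Defaults to [adjust_protonation()] (Open Babel pH model).
#' @return A `prepared_ligand` object with fields `input_smiles`,
#'   `canonical_smiles` (post-protonation), `atom_elements` (including
#'   explicit hydrogens present in the PDBQT), `coords`, `partial_charges`,
#'   `net_charge`, `seed`, `pdbqt`; or a [rejection_reason()].
#' @export
prepare_ligand <- function(smiles, pH = 7.4, seed = 0L, engine = NULL) {
  verdict <- validate_ligand(smiles)
  if (is_rejected(verdict)) return(verdict)
  prot <- if (is.null(engine)) {
    tryCatch(adjust_protonation(smiles, pH = pH), error = function(e) NULL)
  } else {
    tryCatch(engine(smiles), error = function(e) NULL)
  }
  if (is.null(prot)) {
    return(rejection_reason("UNPARSEABLE", "protonation adjustment failed"))
  }
  emb <- embed_conformer(prot, seed = seed)
  if (is_rejected(emb)) return(emb)
  pdbqt <- ob_sdf_to_pdbqt(emb$sdf_text)
  if (is.null(pdbqt)) {
    return(rejection_reason("REFINE_FAILED", "PDBQT serialization failed"))
  }
  net <- net_formal_charge(prot)
  # Open Babel's Gasteiger routine does not seed formal charges, so ionic
  # ligands come back with charges summing to ~0; redistribute the residual
  # uniformly so the serialized record conserves the net formal charge.
  pdbqt <- fix_pdbqt_charges(pdbqt, net)
  at <- parse_pdbqt_atoms(pdbqt)
  structure(
    list(
      input_smiles = smiles,
      canonical_smiles = prot,
      atom_elements = at$element,
      coords = as.matrix(at[, c("x", "y", "z")]),
      partial_charges = at$charge,
      net_charge = net,
      seed = as.integer(seed),
      pdbqt = pdbqt
    ),
    class = "prepared_ligand"
  )
}

#' @export
print.prepared_ligand <- function(x, ...) {
  cat(sprintf("<prepared_ligand> %s  (%d atoms, net charge %+d, seed %d)\n",
              x$canonical_smiles, length(x$atom_elements), x$net_charge, x$seed))
  invisible(x)
}

#' Per-atom partial charges of a prepared ligand
#'
#' Charges are Gasteiger partial charges assigned at PDBQT emission; their
#' sum equals the net formal charge to within 0.01 e.
#'
#' @param ligand A `prepared_ligand`.
#' @return Numeric vector of per-atom charges (elementary-charge units).
#' @export
assign_partial_charges <- function(ligand) {
  stopifnot(inherits(ligand, "prepared_ligand"))
  ligand$partial_charges
}

#' Serialize a prepared ligand to PDBQT text
#'
#' @param ligand A `prepared_ligand`.
#' @return PDBQT text (AutoDock dialect with ROOT/BRANCH/TORSDOF records).
#' @export
ligand_to_pdbqt <- function(ligand) {
  stopifnot(inherits(ligand, "prepared_ligand"))
  ligand$pdbqt
}

# Parse ATOM/HETATM records of PDBQT text into a data.frame with element,
# coordinates and partial charge (fixed-column PDBQT layout).
parse_pdbqt_atoms <- function(pdbqt_text) {
  lines <- strsplit(pdbqt_text, "\n", fixed = TRUE)[[1]]
  at <- lines[grepl("^(ATOM|HETATM)", lines)]
  ad_type <- trimws(substr(at, 78, 79))
  # AutoDock types -> element symbols
  elem <- vapply(ad_type, function(t) {
    switch(t, OA = "O", NA_ = "N", SA = "S", HD = "H", HS = "H", A = "C",
           NA1 = "N",
           if (t == "NA") "N" else t)
  }, character(1), USE.NAMES = FALSE)
  data.frame(
    element = elem,
    x = as.numeric(substr(at, 31, 38)),
    y = as.numeric(substr(at, 39, 46)),
    z = as.numeric(substr(at, 47, 54)),
    charge = as.numeric(substr(at, 67, 76)),
    stringsAsFactors = FALSE
  )
}

# Shift per-atom charges uniformly so they sum to the net formal charge,
# placing the rounding residual on the atom of largest magnitude, and
# rewrite the PDBQT charge columns (67-76).
fix_pdbqt_charges <- function(pdbqt_text, net) {
  if (is.na(net)) return(pdbqt_text)
  lines <- strsplit(pdbqt_text, "\n", fixed = TRUE)[[1]]
  sel <- grepl("^(ATOM|HETATM)", lines)
  if (!any(sel)) return(pdbqt_text)
  q <- as.numeric(substr(lines[sel], 67, 76))
  q <- q + (net - sum(q)) / length(q)
  q <- round(q, 3)
  imax <- which.max(abs(q))
  q[imax] <- round(q[imax] + (net - sum(q)), 3)
  at <- lines[sel]
  substr(at, 67, 76) <- sprintf("%10s", sprintf("%+.3f", q))
  lines[sel] <- at
  paste(lines, collapse = "\n")
}

#' Count of declared active torsions in ligand PDBQT text
#'
#' @param pdbqt_text Ligand PDBQT text with a TORSDOF record.
#' @return Integer torsion count (`NA` if no TORSDOF record is present).
#' @export
pdbqt_torsion_count <- function(pdbqt_text) {
  m <- regmatches(pdbqt_text, regexpr("TORSDOF +([0-9]+)", pdbqt_text))
  if (length(m) == 0L) return(NA_integer_)
  as.integer(sub("TORSDOF +", "", m))
}

#' Prepare a library of ligands
#'
#' Runs [prepare_ligand()] over a vector of SMILES and separates successes
#' from rejections.
#'
#' @param smiles Character vector of SMILES.
#' @param pH,seed,engine Passed to [prepare_ligand()].
#' @return List with `prepared` (named list of `prepared_ligand`) and
#'   `rejected` (data.frame with columns smiles, code, detail).
#' @export
prepare_library <- function(smiles, pH = 7.4, seed = 0L, engine = NULL) {
  prepared <- list()
  rej <- list()
  for (s in smiles) {
    r <- prepare_ligand(s, pH = pH, seed = seed, engine = engine)
    if (is_rejected(r)) {
      rej[[length(rej) + 1L]] <- data.frame(smiles = s, code = r$code,
                                            detail = r$detail,
                                            stringsAsFactors = FALSE)
    } else {
      prepared[[s]] <- r
    }
  }
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(smiles = character(0), code = character(0), detail = character(0))
  list(prepared = prepared, rejected = rejected)
}
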