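# Thin wrappers around Open Babel, used by every chemistry-facing module.
# In-process conversions go through ChemmineOB::convertFormat; operations the
# library API does not expose (3D building, MMFF94 minimization, PDBQT
# emission) shell out to the `obabel` executable.

#' Locate the Open Babel executable
#'
#' @return Path to `obabel`, or `""` if it is not on the PATH.
#' @keywords internal
ob_executable <- function() {
  Sys.which("obabel")[[1]]
}

#' Canonicalize SMILES strings
#'
#' Converts one or more SMILES strings to Open Babel canonical SMILES in a
#' single in-process call. Unparseable entries come back as `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0L) return(character(0))
  # memoized fast path (canonicalization is a pure function)
  cached <- vapply(smiles, function(s) {
    if (is.na(s) || nchar(s) >= 400L) return(NA_character_)
    v <- .canon_cache[[s]]
    if (is.null(v)) NA_character_ else v
  }, character(1), USE.NAMES = FALSE)
  todo <- is.na(cached) &
    !vapply(smiles, function(s) isTRUE(.canon_cache[[paste0("\r", s)]]),
            logical(1), USE.NAMES = FALSE)
  if (!any(todo)) return(cached)
  fresh <- .canonical_smiles_uncached(smiles[todo])
  for (i in seq_along(fresh)) {
    s <- smiles[todo][[i]]
    if (!is.na(s) && nchar(s) < 400L) {
      if (is.na(fresh[[i]])) {
        .canon_cache[[paste0("\r", s)]] <- TRUE   # remember failures
      } else {
        .canon_cache[[s]] <- fresh[[i]]
      }
    }
  }
  cached[todo] <- fresh
  cached
}

.canon_cache <- new.env(parent = emptyenv())

.canonical_smiles_uncached <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  # Conversion stops at the first unparseable molecule, so convert in chunks
  # and resume after each failure; the failing entry itself stays NA.
  start <- 1L
  while (start <= n) {
    idxs <- start:n
    src <- paste0(smiles[idxs], " idx", idxs, collapse = "\n")
    res <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(src, "\n"))),
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
    # resume after the molecule that broke the run (or finish)
    start <- max(got + 1L, start) + if (got < n) 1L else 0L
    if (got == 0L && start <= n) start <- idxs[[1]] + 1L
  }
  out
}

# Single-molecule SMILES -> SDF text (2D, kekulized bond orders), NULL on
# failure. Used by the molgraph parser.
ob_smiles_to_sdf <- function(smiles) {
  res <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"))),
    error = function(e) NULL
  )
  if (is.null(res) || !nzchar(res) || !grepl("V2000", res, fixed = TRUE)) return(NULL)
  res
}

# SDF text -> canonical SMILES (vector, one per molecule); NA on failure.
ob_sdf_to_smiles <- function(sdf_text) {
  res <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", sdf_text)),
    error = function(e) NULL
  )
  if (is.null(res)) return(NA_character_)
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(NA_character_)
  vapply(strsplit(lines, "[ \t]+"), function(p) p[[1]], character(1))
}

# Run the obabel CLI. `args` is a character vector; returns list(status,
# stdout, stderr). Never throws on non-zero exit.
ob_run <- function(args) {
  exe <- ob_executable()
  if (!nzchar(exe)) stop("Open Babel executable `obabel` not found on PATH")
  out_file <- tempfile("ob_out")
  err_file <- tempfile("ob_err")
  on.exit(unlink(c(out_file, err_file)), add = TRUE)
  status <- suppressWarnings(
    system2(exe, args = args, stdout = out_file, stderr = err_file)
  )
  list(
    status = status,
    stdout = paste(readLines(out_file, warn = FALSE), collapse = "\n"),
    stderr = paste(readLines(err_file, warn = FALSE), collapse = "\n")
  )
}

# SMILES -> deterministic 3D SDF: rule-based builder followed by MMFF94
# minimization (steps/crit per package defaults). Returns SDF text or NULL.
ob_embed3d <- function(smiles, steps = 1000L, crit = 1e-4, forcefield = "MMFF94") {
  in_file <- tempfile("lig", fileext = ".smi")
  out_file <- tempfile("lig", fileext = ".sdf")
  on.exit(unlink(c(in_file, out_file)), add = TRUE)
  writeLines(smiles, in_file)
  res <- ob_run(c(
    "-ismi", in_file, "-osdf", "-O", out_file,
    "--gen3d", "fast",
    "--minimize", "--ff", forcefield,
    "--steps", format(steps, scientific = FALSE),
    "--crit", format(crit, scientific = FALSE)
  ))
  if (!file.exists(out_file) || file.size(out_file) == 0) return(NULL)
  txt <- paste(readLines(out_file, warn = FALSE), collapse = "\n")
  if (!grepl("V2000", txt, fixed = TRUE)) return(NULL)
  txt
}

# 3D SDF text -> ligand PDBQT text with Gasteiger charges and torsion tree.
ob_sdf_to_pdbqt <- function(sdf_text) {
  in_file <- tempfile("lig", fileext = ".sdf")
  out_file <- tempfile("lig", fileext = ".pdbqt")
  on.exit(unlink(c(in_file, out_file)), add = TRUE)
  writeLines(sdf_text, in_file)
  res <- ob_run(c("-isdf", in_file, "-opdbqt", "-O", out_file,
                  "--partialcharge", "gasteiger"))
  if (!file.exists(out_file) || file.size(out_file) == 0) return(NULL)
  paste(readLines(out_file, warn = FALSE), collapse = "\n")
}

#' Adjust ligand protonation for a given pH
#'
#' Applies Open Babel's pH transform model, which rewrites ionizable groups
#' to their majority microstate at the requested pH (carboxylic acids and
#' phosphates deprotonate, aliphatic amines, amidines and guanidines
#' protonate at pH 7.4, and so on). The operation is idempotent.
#'
#' Any function mapping a SMILES string to a SMILES string can be substituted
#' through the `engine` argument of [prepare_ligand()], e.g. a bespoke rule
#' table; this is the default engine.
#'
#' @param smiles A single SMILES string (must be parseable).
#' @param pH Target pH; default 7.4 (physiological).
#' @return The protonation-adjusted canonical SMILES string.
#' @export
adjust_protonation <- function(smiles, pH = 7.4) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  opts <- data.frame(names = "p", args = as.character(pH))
  res <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"),
                                               options = opts)),
    error = function(e) NULL
  )
  if (is.null(res) || !nzchar(trimws(res))) {
    stop(sprintf("UNPARSEABLE: cannot protonate %s", smiles))
  }
  strsplit(trimws(res), "[ \t]+")[[1]][[1]]
}
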