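# Receptor-side preparation: derive an axis-aligned docking search box from
# reference-ligand coordinates, and produce prepared receptor records via a
# pluggable external-tool adapter.

#' Search-box parameters
#'
#' @param padding Padding added on all sides of the reference ligand's
#'   bounding box, in Angstrom (default 12.5).
#' @param min_side Minimum box side length, Angstrom (default 30).
#' @return A `box_params` list.
#' @export
box_params <- function(padding = 12.5, min_side = 30) {
  stopifnot(padding >= 0, min_side > 0)
  structure(list(padding = padding, min_side = min_side), class = "box_params")
}

#' Derive a docking search box from reference-ligand coordinates
#'
#' Per axis, the side length is the coordinate span plus twice the padding,
#' raised to `min_side` if smaller; the center is the midpoint of the span.
#'
#' @param ref_coords Numeric matrix (or data.frame) with columns x, y, z of
#'   reference-ligand atom positions in Angstrom. All atoms present in the
#'   reference are used.
#' @param params A [box_params()] object.
#' @return A `search_box`: list with `center` (length-3) and `size`
#'   (length-3), both named x/y/z.
#' @export
derive_search_box <- function(ref_coords, params = box_params()) {
  ref_coords <- as.matrix(ref_coords)
  if (nrow(ref_coords) < 1L) stop("empty reference coordinate set")
  stopifnot(ncol(ref_coords) >= 3L)
  ref_coords <- ref_coords[, 1:3, drop = FALSE]
  lo <- apply(ref_coords, 2, min)
  hi <- apply(ref_coords, 2, max)
  size <- pmax(hi - lo + 2 * params$padding, params$min_side)
  center <- (hi + lo) / 2
  names(size) <- names(center) <- c("x", "y", "z")
  structure(list(center = center, size = size), class = "search_box")
}

#' @export
print.search_box <- function(x, ...) {
  cat(sprintf("<search_box> center (%.2f, %.2f, %.2f)  size (%.1f, %.1f, %.1f) A\n",
              x$center[1], x$center[2], x$center[3],
              x$size[1], x$size[2], x$size[3]))
  invisible(x)
}

#' Read atom coordinates from a PDB or PDBQT file or text
#'
#' @param path_or_text A file path, or the file content as a single string.
#' @return Matrix with columns x, y, z (one row per ATOM/HETATM record).
#' @export
read_ligand_coords <- function(path_or_text) {
  lines <- .as_lines(path_or_text)
  at <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (length(at) == 0L) stop("no ATOM/HETATM records found")
  cbind(
    x = as.numeric(substr(at, 31, 38)),
    y = as.numeric(substr(at, 39, 46)),
    z = as.numeric(substr(at, 47, 54))
  )
}

.as_lines <- function(path_or_text) {
  if (length(path_or_text) == 1L && !grepl("\n", path_or_text) &&
      file.exists(path_or_text)) {
    readLines(path_or_text, warn = FALSE)
  } else {
    strsplit(paste(path_or_text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
}

#' Heavy-atom count of PDB/PDBQT text
#'
#' Element inferred from columns 77-78 (PDB) or the AutoDock type field
#' (PDBQT), falling back to the atom name; hydrogens excluded.
#'
#' @param path_or_text File path or structure text.
#' @return Integer count of non-hydrogen ATOM/HETATM records.
#' @export
count_heavy_atoms <- function(path_or_text) {
  lines <- .as_lines(path_or_text)
  at <- lines[grepl("^(ATOM|HETATM)", lines)]
  elem <- trimws(substr(at, 77, 78))
  fallback <- trimws(substr(at, 13, 14))
  elem[!nzchar(elem)] <- fallback[!nzchar(elem)]
  elem <- sub("^([A-Za-z]+).*$", "\\1", elem)
  sum(!(toupper(elem) %in% c("H", "HD", "HS")))
}

#' Normalize element symbols in PDB text
#'
#' Upper-cases and right-justifies two-letter element symbols (e.g. metal
#' atoms written as `ZN` or `Zn `) in the element columns of ATOM/HETATM
#' records so that downstream conversion tools recognize them.
#'
#' @param pdb_text PDB file content as a single string or vector of lines.
#' @return Normalized PDB text (single string).
#' @export
normalize_pdb_elements <- function(pdb_text) {
  lines <- .as_lines(pdb_text)
  sel <- grepl("^(ATOM|HETATM)", lines)
  fix <- function(ln) {
    if (nchar(ln) < 78) ln <- formatC(ln, width = 78, flag = "-")
    el <- trimws(substr(ln, 77, 78))
    if (!nzchar(el)) {
      # infer from atom name (columns 13-16)
      nm <- trimws(substr(ln, 13, 16))
      el <- sub("^([A-Za-z]{1,2}).*$", "\\1", nm)
      if (nchar(el) == 2L && !(toupper(el) %in% c("CL", "BR", "ZN", "MG", "FE",
                                                  "MN", "CA", "NA", "CU", "NI",
                                                  "CO", "SE", "CD", "HG")))
        el <- substr(el, 1, 1)
    }
    el <- toupper(el)
    if (nchar(el) == 1L) el <- paste0(" ", el)
    substr(ln, 77, 78) <- el
    ln
  }
  lines[sel] <- vapply(lines[sel], fix, character(1), USE.NAMES = FALSE)
  paste(lines, collapse = "\n")
}

#' Receptor-tool adapters
#'
#' A receptor adapter is a function `pdb_text -> pdbqt_text` wrapping an
#' external preparation tool. `null_adapter()` passes fixture PDBQT through
#' unchanged (for tests and pre-prepared receptors); `obabel_adapter()` adds
#' polar hydrogens and converts to rigid-receptor PDBQT with Open Babel.
#'
#' @return A function of one argument (the receptor text).
#' @export
null_adapter <- function() {
  structure(function(pdb_text) paste(.as_lines(pdb_text), collapse = "\n"),
            class = c("receptor_adapter", "function"), label = "null")
}

#' @rdname null_adapter
#' @param pH pH at which hydrogens are added (default 7.4).
#' @export
obabel_adapter <- function(pH = 7.4) {
  f <- function(pdb_text) {
    in_file <- tempfile("rec", fileext = ".pdb")
    out_file <- tempfile("rec", fileext = ".pdbqt")
    on.exit(unlink(c(in_file, out_file)), add = TRUE)
    writeLines(.as_lines(pdb_text), in_file)
    res <- ob_run(c("-ipdb", in_file, "-opdbqt", "-O", out_file, "-xr",
                    "-p", as.character(pH)))
    if (!file.exists(out_file) || file.size(out_file) == 0) {
      stop(sprintf("receptor conversion failed: %s", res$stderr))
    }
    paste(readLines(out_file, warn = FALSE), collapse = "\n")
  }
  structure(f, class = c("receptor_adapter", "function"), label = "obabel")
}

#' Prepare a receptor target
#'
#' Normalizes element symbols, runs the receptor adapter to produce PDBQT,
#' and attaches a docking search box derived from reference-ligand
#' coordinates (or supplied explicitly, as for binding sites chosen by
#' visual inspection).
#'
#' @param pdb_text Receptor structure (PDB or, with the null adapter,
#'   pre-prepared PDBQT) as text or file path.
#' @param name Target name (gene symbol).
#' @param adapter A receptor adapter, see [null_adapter()].
#' @param ref_coords Reference-ligand coordinate matrix for box derivation
#'   (mutually exclusive with `box`).
#' @param box An explicit `search_box`.
#' @param params [box_params()] used when deriving from `ref_coords`.
#' @return A `prepared_target`: list with `name`, `receptor_pdbqt`, `box`.
#' @export
prepare_target <- function(pdb_text, name, adapter = obabel_adapter(),
                           ref_coords = NULL, box = NULL,
                           params = box_params()) {
  if (is.null(box) == is.null(ref_coords)) {
    stop("supply exactly one of `ref_coords` or `box`")
  }
  txt <- paste(.as_lines(pdb_text), collapse = "\n")
  txt <- normalize_pdb_elements(txt)
  pdbqt <- adapter(txt)
  if (!any(grepl("^(ATOM|HETATM)", strsplit(pdbqt, "\n")[[1]]))) {
    stop("adapter produced no atom records")
  }
  if (is.null(box)) box <- derive_search_box(ref_coords, params)
  structure(list(name = name, receptor_pdbqt = pdbqt, box = box),
            class = "prepared_target")
}

#' @export
print.prepared_target <- function(x, ...) {
  cat(sprintf("<prepared_target> %s (%d heavy atoms)\n", x$name,
              count_heavy_atoms(x$receptor_pdbqt)))
  print(x$box)
  invisible(x)
}

#' Write a prepared target to disk
#'
#' Writes `NAME.pdbqt` and a sidecar box file `NAME_conf.txt` holding the
#' name, center and size as six floats.
#'
#' @param target A `prepared_target`.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_target <- function(target, dir = ".") {
  stopifnot(inherits(target, "prepared_target"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pdbqt_path <- file.path(dir, paste0(target$name, ".pdbqt"))
  conf_path <- file.path(dir, paste0(target$name, "_conf.txt"))
  writeLines(target$receptor_pdbqt, pdbqt_path)
  b <- target$box
  writeLines(c(
    paste0("name ", target$name),
    sprintf("center_x %.3f", b$center[["x"]]),
    sprintf("center_y %.3f", b$center[["y"]]),
    sprintf("center_z %.3f", b$center[["z"]]),
    sprintf("size_x %.3f", b$size[["x"]]),
    sprintf("size_y %.3f", b$size[["y"]]),
    sprintf("size_z %.3f", b$size[["z"]])
  ), conf_path)
  invisible(c(pdbqt_path, conf_path))
}
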