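# Docking of a prepared ligand against a prepared target through a pluggable
# backend. Two backends ship with the package: an AutoDock Vina subprocess
# adapter, and a deterministic mock backend that maps molecular descriptors
# to scores in the empirical docking-score range so that every benchmark can
# run without a docking binary.

#' Docking parameters
#'
#' Defaults follow the AutoDock Vina defaults used throughout the benchmark
#' suites: exhaustiveness 8, at most 9 binding modes, energy range 3.
#'
#' @param exhaustiveness Search effort (default 8).
#' @param num_modes Maximum number of poses (default 9).
#' @param energy_range Maximum score spread among reported poses (default 3).
#' @param seed Integer random seed (default 0).
#' @return A `docking_params` list.
#' @export
docking_params <- function(exhaustiveness = 8L, num_modes = 9L,
                           energy_range = 3, seed = 0L) {
  stopifnot(num_modes >= 1L)
  structure(list(exhaustiveness = as.integer(exhaustiveness),
                 num_modes = as.integer(num_modes),
                 energy_range = energy_range, seed = as.integer(seed)),
            class = "docking_params")
}

#' Construct a docking result
#'
#' @param poses List of poses, each a list with `score` (finite numeric) and
#'   optionally `coords`. Sorted ascending by score on construction.
#' @param target_name,ligand_smiles Identification of the run.
#' @return A `docking_result`.
#' @export
docking_result <- function(poses, target_name, ligand_smiles) {
  stopifnot(length(poses) >= 1L)
  scores <- vapply(poses, function(p) p$score, numeric(1))
  stopifnot(all(is.finite(scores)))
  poses <- poses[order(scores)]
  structure(list(poses = poses, target_name = target_name,
                 ligand_smiles = ligand_smiles),
            class = "docking_result")
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf("<docking_result> %s vs %s: %d pose(s), best %.3f\n",
              x$ligand_smiles, x$target_name, length(x$poses), best_score(x)))
  invisible(x)
}

#' Best (lowest) docking score of a result
#'
#' Only the lowest score of a docking run is used downstream. A positive
#' best score indicates a highly constrained pose and is flagged with a
#' message.
#'
#' @param result A `docking_result`.
#' @return The minimum pose score.
#' @export
best_score <- function(result) {
  stopifnot(inherits(result, "docking_result"), length(result$poses) >= 1L)
  s <- min(vapply(result$poses, function(p) p$score, numeric(1)))
  if (s > 0) {
    message(sprintf("constrained: positive best score %.3f for %s vs %s",
                    s, result$ligand_smiles, result$target_name))
  }
  s
}

#' Dock a ligand against a prepared target
#'
#' The ligand SMILES is passed through the full preparation pipeline first;
#' preparation rejections propagate as errors before any backend call.
#' Identical inputs and seed produce identical results with either backend.
#'
#' @param target A `prepared_target`.
#' @param smiles Ligand SMILES string.
#' @param params A [docking_params()].
#' @param backend A docking backend, see [mock_backend()] and
#'   [vina_backend()].
#' @return A `docking_result`.
#' @export
dock <- function(target, smiles, params = docking_params(),
                 backend = mock_backend()) {
  stopifnot(inherits(target, "prepared_target"))
  verdict <- validate_ligand(smiles)
  if (is_rejected(verdict)) {
    stop(sprintf("ligand rejected (%s): %s", verdict$code, verdict$detail))
  }
  backend$dock(target, smiles, params)
}

# ---------------------------------------------------------------------------
# Mock backend

# Descriptor vector for the mock scoring model: cheap whole-molecule
# features plus hashed fingerprint-block features, all computed from the
# canonical molecular graph (no 3D embedding required).
#' Mock-backend descriptors of a molecule
#'
#' Twelve deterministic descriptors: molecular weight (scaled), a
#' lipophilicity proxy, ring count, hydrogen-bond donors and acceptors,
#' rotatable bonds, and six Morgan-fingerprint block densities.
#'
#' @param smiles A SMILES string.
#' @return Numeric vector of length 12, or `NULL` for invalid input.
#' @export
mock_descriptors <- function(smiles) {
  g <- parse_molgraph(canonical_smiles(smiles))
  if (is.null(g)) return(NULL)
  impl_h <- molgraph_implicit_h(g)
  masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
              F = 18.998, Cl = 35.45, Br = 79.904, I = 126.9, B = 10.81)
  mw <- sum(masses[g$elements], na.rm = TRUE) + 1.008 * sum(impl_h)
  n_rings <- nrow(g$bonds) - g$n_atoms + molgraph_n_fragments(g)
  hbd <- sum(g$elements %in% c("N", "O") & impl_h > 0)
  hba <- sum(g$elements %in% c("N", "O"))
  # lipophilicity proxy: carbon/halogen excess per atom
  lp <- (sum(g$elements %in% c("C", "Cl", "Br", "I", "F")) - hba) /
    max(1L, g$n_atoms)
  rb <- .count_rotatable(g)
  fp <- fingerprint_from_graph(g, "MORGAN2_1024")
  blocks <- vapply(0:5, function(k) {
    sum(fp$bits >= k * 170L & fp$bits < (k + 1L) * 170L)
  }, numeric(1))
  c(mw / 100, lp, n_rings, hbd, hba, rb, blocks / 8)
}

# Rotatable bonds: acyclic single bonds between two non-terminal heavy atoms.
.count_rotatable <- function(g) {
  if (nrow(g$bonds) == 0L) return(0L)
  deg <- lengths(g$adj)
  bridges <- molgraph_bridges_cached(g)
  n <- 0L
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds[i, "a"]; b <- g$bonds[i, "b"]
    if (g$bonds[i, "order"] == 1L && bridges[i] && deg[a] > 1L && deg[b] > 1L) {
      # exclude bonds adjacent to triple bonds (linear, not rotatable)
      n <- n + 1L
    }
  }
  n
}

#' Deterministic mock docking score
#'
#' A pure function of descriptors and target weights: the weighted sum is
#' squashed onto the empirical docking-score range \[-13, -4\] with a tanh
#' map, so two targets' scores over a molecule library correlate according
#' to the angle between their weight vectors.
#'
#' @param descriptors Numeric descriptor vector ([mock_descriptors()]).
#' @param target_weights Weight vector of the same length, with attributes
#'   `center` and `scale` (affine standardization of the weighted sum;
#'   defaults 0/1).
#' @return A single finite score in (-13, -4).
#' @export
mock_score <- function(descriptors, target_weights) {
  if (length(descriptors) != length(target_weights)) {
    stop("descriptor/weight dimension mismatch")
  }
  center <- attr(target_weights, "center"); if (is.null(center)) center <- 0
  scale <- attr(target_weights, "scale"); if (is.null(scale)) scale <- 1
  z <- (sum(descriptors * target_weights) - center) / scale
  -8.5 - 4.5 * tanh(z / 2)
}

#' Mock docking backend
#'
#' Deterministic, download-free backend. Target weight vectors are taken
#' from the `prepared_target` (attribute `mock_weights`) or derived
#' reproducibly from the target name. Poses are generated at the prepared
#' conformer geometry (if `embed = TRUE`) or with deterministic pseudo-random
#' coordinates, with scores spaced above the best score within the energy
#' range.
#'
#' @param embed If `TRUE`, run the real 3D preparation to obtain pose
#'   coordinates; if `FALSE` (default) synthesize coordinates cheaply.
#' @return A backend object with a `dock(target, smiles, params)` function.
#' @export
mock_backend <- function(embed = FALSE) {
  backend <- list(
    name = "mock",
    dock = function(target, smiles, params) {
      w <- attr(target, "mock_weights")
      if (is.null(w)) w <- mock_target_weights(target$name)
      d <- mock_descriptors(smiles)
      if (is.null(d)) stop(sprintf("ligand rejected (UNPARSEABLE): %s", smiles))
      s_best <- mock_score(d, w)
      # deterministic per-(target, ligand, seed) stream for pose spacing
      rng_seed <- (.hash_string(paste(target$name, canonical_smiles(smiles),
                                      params$seed, sep = "|")) %% 2147483587L)
      n_pose <- 1L + (rng_seed %% params$num_modes)
      gaps <- ((rng_seed %% 97L) + seq_len(n_pose) * 13L) %% 100L / 100
      scores <- s_best + params$energy_range * cumsum(c(0, gaps[-1])) /
        max(1, sum(gaps[-1]) + 1e-9)
      scores <- scores[scores <= s_best + params$energy_range]
      coords <- NULL
      if (embed) {
        lig <- prepare_ligand(smiles, seed = params$seed)
        if (!is_rejected(lig)) coords <- lig$coords
      }
      if (is.null(coords)) {
        m <- 8L + (rng_seed %% 17L)
        base <- matrix(((rng_seed + seq_len(3L * m) * 2654435761) %% 1000L) / 100,
                       ncol = 3)
        coords <- sweep(base, 2, unlist(target$box$center) - 5, "+")
      }
      poses <- lapply(scores, function(s) list(coords = coords, score = s))
      docking_result(poses, target$name, smiles)
    }
  )
  structure(backend, class = "docking_backend")
}

#' Reproducible mock weight vector for a target name
#'
#' @param name Target name.
#' @param p Descriptor dimension (default 12).
#' @return Numeric weight vector with standardization attributes.
#' @export
mock_target_weights <- function(name, p = 12L) {
  seed <- .hash_string(paste0("mock_target:", name)) %% 2147483587L
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  w <- stats::rnorm(p)
  attr(w, "center") <- 2
  attr(w, "scale") <- 4
  w
}

# Save/restore .Random.seed so internal seeding never disturbs the caller's
# RNG stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---------------------------------------------------------------------------
# AutoDock Vina adapter

#' AutoDock Vina backend
#'
#' Invokes the `vina` executable as a subprocess with an explicit seed and
#' parses the score table from its output; the Vina version string is
#' recorded in the result metadata. The executable path is configuration,
#' not a bundled dependency.
#'
#' @param vina_path Path to the Vina executable (default: found on PATH).
#' @return A backend object with a `dock(target, smiles, params)` function.
#' @export
vina_backend <- function(vina_path = Sys.which("vina")[[1]]) {
  backend <- list(
    name = "vina",
    path = vina_path,
    dock = function(target, smiles, params) {
      if (!nzchar(vina_path)) stop("vina executable not found")
      lig <- prepare_ligand(smiles, seed = params$seed)
      if (is_rejected(lig)) {
        stop(sprintf("ligand rejected (%s): %s", lig$code, lig$detail))
      }
      dir <- tempfile("vina")
      dir.create(dir)
      on.exit(unlink(dir, recursive = TRUE), add = TRUE)
      rec <- file.path(dir, "receptor.pdbqt")
      ligf <- file.path(dir, "ligand.pdbqt")
      outf <- file.path(dir, "out.pdbqt")
      writeLines(target$receptor_pdbqt, rec)
      writeLines(lig$pdbqt, ligf)
      args <- vina_command_args(target, rec, ligf, outf, params)
      res <- suppressWarnings(system2(vina_path, args, stdout = TRUE,
                                      stderr = TRUE))
      status <- attr(res, "status")
      if (!is.null(status) && status != 0) {
        stop(sprintf("vina failed (%d): %s", status,
                     paste(utils::tail(res, 5), collapse = " / ")))
      }
      scores <- parse_vina_scores(paste(res, collapse = "\n"))
      if (length(scores) == 0L) stop("no scores in vina output")
      pose_txt <- if (file.exists(outf)) readLines(outf, warn = FALSE) else character(0)
      coords_list <- parse_vina_poses(pose_txt)
      poses <- lapply(seq_along(scores), function(i) {
        list(score = scores[[i]],
             coords = if (i <= length(coords_list)) coords_list[[i]] else NULL)
      })
      r <- docking_result(poses, target$name, smiles)
      attr(r, "vina_version") <- vina_version_string(paste(res, collapse = "\n"))
      r
    }
  )
  structure(backend, class = "docking_backend")
}

# Command-line arguments for a Vina run (exposed for testing).
vina_command_args <- function(target, receptor_file, ligand_file, out_file,
                              params) {
  b <- target$box
  c("--receptor", receptor_file, "--ligand", ligand_file, "--out", out_file,
    "--center_x", format(b$center[["x"]]), "--center_y", format(b$center[["y"]]),
    "--center_z", format(b$center[["z"]]),
    "--size_x", format(b$size[["x"]]), "--size_y", format(b$size[["y"]]),
    "--size_z", format(b$size[["z"]]),
    "--exhaustiveness", format(params$exhaustiveness),
    "--num_modes", format(params$num_modes),
    "--energy_range", format(params$energy_range),
    "--seed", format(params$seed))
}

# Parse mode scores from Vina's result table (kcal/mol column).
parse_vina_scores <- function(stdout_text) {
  lines <- strsplit(stdout_text, "\n", fixed = TRUE)[[1]]
  hits <- regmatches(lines, regexec("^\\s*(\\d+)\\s+(-?\\d+\\.\\d+)\\s+", lines))
  scores <- vapply(hits, function(h) {
    if (length(h) == 3L) as.numeric(h[[3]]) else NA_real_
  }, numeric(1))
  scores[!is.na(scores)]
}

# Split MODEL-separated pose PDBQT into per-pose coordinate matrices.
parse_vina_poses <- function(lines) {
  if (length(lines) == 0L) return(list())
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) model_starts <- 1L
  model_ends <- c(model_starts[-1] - 1L, length(lines))
  lapply(seq_along(model_starts), function(i) {
    chunk <- lines[model_starts[i]:model_ends[i]]
    at <- chunk[grepl("^(ATOM|HETATM)", chunk)]
    cbind(x = as.numeric(substr(at, 31, 38)),
          y = as.numeric(substr(at, 39, 46)),
          z = as.numeric(substr(at, 47, 54)))
  })
}

vina_version_string <- function(stdout_text) {
  m <- regmatches(stdout_text, regexpr("AutoDock Vina[^\n(]*", stdout_text))
  if (length(m) == 0L) "unknown" else trimws(m[[1]])
}

#' Write docking poses to PDBQT files
#'
#' One MODEL-separated file per pose.
#'
#' @param result A `docking_result`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_poses <- function(result, dir = ".") {
  stopifnot(inherits(result, "docking_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(result$poses)) {
    p <- result$poses[[i]]
    path <- file.path(dir, sprintf("pose_%02d.pdbqt", i))
    lines <- c(sprintf("MODEL %d", i),
               sprintf("REMARK SCORE %.4f", p$score))
    if (!is.null(p$coords)) {
      lines <- c(lines, vapply(seq_len(nrow(p$coords)), function(j) {
        sprintf("ATOM  %5d  C   UNL     1    %8.3f%8.3f%8.3f  0.00  0.00    %+6.3f C ",
                j, p$coords[j, 1], p$coords[j, 2], p$coords[j, 3], 0)
      }, character(1)))
    }
    lines <- c(lines, "ENDMDL")
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
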