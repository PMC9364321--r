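# Synthetic data generation: druglike SMILES libraries built by decorating a
# scaffold pool, mock score matrices with controllable inter-target
# correlation, and a miniature protein fixture — so every module runs with
# no download and no docking binary.

# Scaffold pool: common druglike ring systems (as SMILES with open
# attachment positions handled by substitution on carbons).
.fixture_scaffolds <- c(
  "c1ccccc1",            # benzene
  "c1ccncc1",            # pyridine
  "c1ccc2ccccc2c1",      # naphthalene
  "c1ccc2[nH]ccc2c1",    # indole
  "c1ccoc1",             # furan
  "c1ccsc1",             # thiophene
  "C1CCNCC1",            # piperidine
  "C1CCOCC1",            # oxane
  "C1CCCCC1",            # cyclohexane
  "c1cnc2[nH]ccc2c1",    # azaindole
  "c1ccc(-c2ccccc2)cc1", # biphenyl
  "C1CN(CCN1)C",         # methylpiperazine (ring + N-methyl)
  "c1ccc2ncccc2c1",      # quinoline
  "O=C1NCCN1"            # imidazolidinone
)

.fixture_substituents <- c("C", "CC", "CCC", "C(C)C", "O", "OC", "N", "NC",
                           "F", "Cl", "Br", "C(=O)O", "C(=O)N", "C(=O)C",
                           "C#N", "S", "CO", "CN", "C(F)(F)F", "OCC")

#' Specification for a synthetic molecule library
#'
#' @param n_molecules Library size.
#' @param seed Integer seed.
#' @param scaffold_pool_size Number of distinct scaffolds drawn from the
#'   built-in pool (default: all of them).
#' @param decoration_rate Expected number of substituents per molecule
#'   (default 2).
#' @param n_radicals,n_multi_fragment Planted defects for rejection tests
#'   (default 0).
#' @return A `library_spec` list.
#' @export
library_spec <- function(n_molecules, seed = 0L,
                         scaffold_pool_size = length(.fixture_scaffolds),
                         decoration_rate = 2, n_radicals = 0L,
                         n_multi_fragment = 0L) {
  stopifnot(n_molecules >= 1L,
            scaffold_pool_size >= 1L,
            scaffold_pool_size <= length(.fixture_scaffolds))
  structure(list(n_molecules = as.integer(n_molecules), seed = as.integer(seed),
                 scaffold_pool_size = as.integer(scaffold_pool_size),
                 decoration_rate = decoration_rate,
                 n_radicals = as.integer(n_radicals),
                 n_multi_fragment = as.integer(n_multi_fragment)),
            class = "library_spec")
}

#' Generate a synthetic druglike SMILES library
#'
#' Molecules are built by decorating scaffolds from a fixed pool with random
#' substituents (substitution at ring carbons with a free hydrogen), a
#' construction that keeps the majority of the library within Lipinski
#' bounds. Optional defects (radicals, multi-fragment SMILES) are planted at
#' the end of the library for rejection accounting. Deterministic per seed.
#'
#' @param spec A [library_spec()].
#' @return Character vector of `n_molecules` SMILES.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  scaffolds <- .fixture_scaffolds[seq_len(spec$scaffold_pool_size)]
  n_clean <- spec$n_molecules - spec$n_radicals - spec$n_multi_fragment
  stopifnot(n_clean >= 0L)
  out <- character(0)
  guard <- 0L
  while (length(out) < n_clean && guard < 50L * spec$n_molecules) {
    guard <- guard + 1L
    base <- sample(scaffolds, 1L)
    k <- stats::rpois(1L, spec$decoration_rate)
    smi <- .decorate(base, sample(.fixture_substituents, min(k, 4L),
                                  replace = TRUE))
    if (is.na(smi)) next
    if (!isTRUE(validate_ligand(smi))) next
    out <- c(out, smi)
  }
  out <- out[seq_len(min(length(out), n_clean))]
  radicals <- rep("[CH2]c1ccccc1", spec$n_radicals)  # benzyl radical
  multi <- rep("CCO.Cl", spec$n_multi_fragment)
  c(out, radicals, multi)
}

# Parsed-graph cache for scaffold and substituent SMILES (fixture pool only).
.fixture_graph_cache <- new.env(parent = emptyenv())

.fixture_graph <- function(smiles) {
  g <- .fixture_graph_cache[[smiles]]
  if (is.null(g)) {
    g <- parse_molgraph(smiles)
    if (!is.null(g)) .fixture_graph_cache[[smiles]] <- g
  }
  g
}

# Attach substituents to a scaffold at random CH positions in one graph
# pass, then canonicalize once.
.decorate <- function(scaffold, subs) {
  g <- .fixture_graph(scaffold)
  if (is.null(g)) return(NA_character_)
  elements <- g$elements
  charges <- g$charges
  bonds <- g$bonds
  # per-atom free hydrogens, updated as substituents attach
  free_h <- molgraph_implicit_h(g)
  for (sub in subs) {
    sg <- .fixture_graph(sub)
    if (is.null(sg)) next
    host <- which(elements == "C" & free_h > 0)
    if (length(host) == 0L) break
    v <- host[[sample.int(length(host), 1L)]]
    n0 <- length(elements)
    bonds_s <- sg$bonds
    if (nrow(bonds_s) > 0L) {
      bonds_s[, "a"] <- bonds_s[, "a"] + n0
      bonds_s[, "b"] <- bonds_s[, "b"] + n0
    }
    join <- matrix(c(v, n0 + 1L, 1L), ncol = 3,
                   dimnames = list(NULL, c("a", "b", "order")))
    elements <- c(elements, sg$elements)
    charges <- c(charges, sg$charges)
    bonds <- rbind(bonds, bonds_s, join)
    free_h <- c(free_h, molgraph_implicit_h(sg))
    free_h[v] <- free_h[v] - 1L
    free_h[n0 + 1L] <- max(0L, free_h[n0 + 1L] - 1L)
  }
  molgraph_build_smiles(elements, bonds, charges)
}

#' Specification of a mock docking target
#'
#' @param name Target name (gene symbol).
#' @param correlation_to Optional name of a previously specified target the
#'   scores should correlate with.
#' @param rho Requested Pearson correlation to `correlation_to` (|rho| <= 1).
#' @return A `mock_target_spec` list.
#' @export
mock_target_spec <- function(name, correlation_to = NULL, rho = NULL) {
  if (!is.null(rho) && abs(rho) > 1) stop("infeasible correlation request: |rho| > 1")
  structure(list(name = name, correlation_to = correlation_to, rho = rho),
            class = "mock_target_spec")
}

#' Generate a mock score matrix over a molecule library
#'
#' Builds one weight vector per target and scores every molecule with the
#' deterministic mock model. For a target with a `correlation_to` request,
#' the weight vector is constructed in the library's descriptor covariance
#' metric so that the (pre-squashing) score correlation with the anchor
#' target equals the requested rho; after the bounded squashing map the
#' realized sample correlation stays within a few percent of the request.
#' All scores lie in the empirical docking-score range (-13, -4).
#'
#' @param specs List of [mock_target_spec()] objects.
#' @param library Character vector of SMILES (nonempty).
#' @param seed Integer seed for the weight draws.
#' @return A list of class `score_matrix`: `scores` (molecule x target
#'   matrix), `molecule_ids` (canonical SMILES), `targets`, plus per-target
#'   weight vectors in `weights` (usable with [mock_score()]).
#' @export
generate_mock_targets <- function(specs, library, seed = 0L) {
  stopifnot(length(library) > 0L, length(specs) > 0L)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  desc <- t(vapply(library, function(s) {
    d <- mock_descriptors(s)
    if (is.null(d)) rep(NA_real_, 12L) else d
  }, numeric(12L)))
  ok <- stats::complete.cases(desc)
  if (!all(ok)) stop("library contains invalid molecules")
  p <- ncol(desc)
  Sigma <- stats::cov(desc)
  Sigma <- Sigma + diag(1e-8, p)
  mu <- colMeans(desc)

  weights <- list()
  for (sp in specs) {
    if (is.null(sp$correlation_to)) {
      w <- stats::rnorm(p)
    } else {
      u <- weights[[sp$correlation_to]]
      if (is.null(u)) stop(sprintf("unknown anchor target %s", sp$correlation_to))
      u <- .strip_attrs(u)
      g <- stats::rnorm(p)
      uSu <- drop(t(u) %*% Sigma %*% u)
      v0 <- g - drop(t(u) %*% Sigma %*% g) / uSu * u       # Sigma-orthogonal
      v0 <- v0 / sqrt(drop(t(v0) %*% Sigma %*% v0))
      w <- sp$rho * u / sqrt(uSu) + sqrt(1 - sp$rho^2) * v0
    }
    # standardize the weighted sum over this library so the squashing map is
    # exercised in its near-linear core
    z <- drop(desc %*% w)
    attr(w, "center") <- mean(z)
    attr(w, "scale") <- max(stats::sd(z), 1e-9)
    weights[[sp$name]] <- w
  }
  scores <- vapply(names(weights), function(nm) {
    w <- weights[[nm]]
    apply(desc, 1L, mock_score, target_weights = w)
  }, numeric(nrow(desc)))
  ids <- canonical_smiles(library)
  structure(
    list(scores = matrix(scores, ncol = length(weights),
                         dimnames = list(ids, names(weights))),
         molecule_ids = ids, targets = names(weights), weights = weights),
    class = "score_matrix"
  )
}

.strip_attrs <- function(w) { attributes(w) <- NULL; w }

#' Score function backed by a mock target set
#'
#' @param weights Named list of weight vectors (from
#'   [generate_mock_targets()]`$weights`), or `NULL` to derive weights from
#'   target names on the fly.
#' @return Function `(smiles, target) -> score` with per-molecule descriptor
#'   memoization.
#' @export
mock_score_function <- function(weights = NULL) {
  desc_cache <- new.env(parent = emptyenv())
  function(smiles, target) {
    key <- smiles
    d <- desc_cache[[key]]
    if (is.null(d)) {
      d <- mock_descriptors(smiles)
      if (is.null(d)) return(NA_real_)
      desc_cache[[key]] <- d
    }
    w <- if (!is.null(weights)) weights[[target]] else NULL
    if (is.null(w)) w <- mock_target_weights(target)
    mock_score(d, w)
  }
}

#' Write a score matrix to CSV
#'
#' Rows are molecules, columns are target gene symbols.
#'
#' @param sm A `score_matrix`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_score_matrix <- function(sm, path) {
  df <- data.frame(smiles = sm$molecule_ids, sm$scores, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a score matrix from CSV
#'
#' @param path CSV with a `smiles` column and one column per target.
#' @return A `score_matrix` (without mock weights).
#' @export
read_score_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("smiles" %in% names(df))
  targets <- setdiff(names(df), "smiles")
  m <- as.matrix(df[, targets, drop = FALSE])
  rownames(m) <- df$smiles
  structure(list(scores = m, molecule_ids = df$smiles, targets = targets,
                 weights = NULL),
            class = "score_matrix")
}

# ---------------------------------------------------------------------------
# Miniature protein fixture

#' Miniature synthetic protein target fixture
#'
#' An 8-residue poly-alanine helix written as synthetic PDBQT text, plus a
#' small reference-ligand coordinate set near its surface. The attached
#' search box is derived with default parameters (so all sides are at least
#' 30 Angstrom). Entirely synthetic; for tests and examples.
#'
#' @param name Target name (default `"MINI1"`).
#' @return A `prepared_target` with mock weights attached.
#' @export
make_mini_target_fixture <- function(name = "MINI1") {
  pdbqt <- .mini_protein_pdbqt()
  ref <- cbind(x = c(4.5, 5.7, 6.2, 5.1), y = c(1.0, 1.8, 0.4, -0.6),
               z = c(2.0, 3.1, 4.0, 2.8))
  target <- prepare_target(pdbqt, name = name, adapter = null_adapter(),
                           ref_coords = ref)
  attr(target, "mock_weights") <- mock_target_weights(name)
  target
}

# Synthetic poly-alanine backbone trace in PDBQT form (N, CA, C, O, CB per
# residue along an idealized helix).
.mini_protein_pdbqt <- function() {
  lines <- c("REMARK  synthetic mini protein fixture (poly-alanine helix)")
  serial <- 0L
  types <- c(N = "N", CA = "C", C = "C", O = "OA", CB = "C")
  offs <- list(N = c(0, 0, 0), CA = c(0.8, 0.9, 0.4), C = c(1.9, 0.3, 1.0),
               O = c(2.1, -0.9, 1.0), CB = c(0.9, 1.9, -0.7))
  for (res in 1:8) {
    theta <- (res - 1) * 100 * pi / 180
    base <- c(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (res - 1))
    for (atom in names(types)) {
      serial <- serial + 1L
      xyz <- base + offs[[atom]]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s ALA A%4d    %8.3f%8.3f%8.3f  0.00  0.00    %+6.3f %-2s",
        serial, atom, res, xyz[1], xyz[2], xyz[3],
        if (atom == "O") -0.27 else if (atom == "N") -0.35 else 0.15,
        types[[atom]]
      ))
    }
  }
  paste(c(lines, "TER", "END"), collapse = "\n")
}
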