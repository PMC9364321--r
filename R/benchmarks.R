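# The three evaluation suites: regression metrics, enrichment-factor virtual
# screening, and QED-penalized de novo design objectives with evaluation
# budget accounting and best-so-far trajectories.

#' Regression metrics
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return List with `r2` (`1 - SSres/SStot`; `NA` with a message when
#'   `y_true` has zero variance), `mse`, `mae`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0L)
  res <- y_true - y_pred
  mse <- mean(res^2)
  mae <- mean(abs(res))
  sstot <- sum((y_true - mean(y_true))^2)
  r2 <- if (sstot == 0) {
    message("regression_metrics: zero-variance y_true, r2 undefined")
    NA_real_
  } else {
    1 - sum(res^2) / sstot
  }
  list(r2 = r2, mse = mse, mae = mae)
}

#' Score threshold at the lowest percentile
#'
#' The activity threshold used by the screening benchmark: the order
#' statistic at rank `ceil(percentile/100 * n)` of the ascending scores.
#'
#' @param scores Nonempty numeric vector.
#' @param percentile Lower-tail percentile (default 0.1, i.e. the lowest
#'   0.1\%).
#' @return The threshold score.
#' @export
score_threshold <- function(scores, percentile = 0.1) {
  stopifnot(length(scores) > 0L)
  r <- max(1L, ceiling(percentile / 100 * length(scores)))
  sort(scores)[r]
}

#' Published activity thresholds for the screening benchmark targets
#'
#' The lowest-0.1-percentile docking-score thresholds of the reference
#' screening library, served from configuration: KIT -10.7, PARP1 -12.1,
#' PGR -10.1.
#'
#' @param target Gene symbol.
#' @return The configured threshold.
#' @export
published_threshold <- function(target) {
  th <- c(KIT = -10.7, PARP1 = -12.1, PGR = -10.1)
  if (!target %in% names(th)) stop(sprintf("no published threshold for %s", target))
  th[[target]]
}

#' Enrichment factor
#'
#' Rate of actives in a selected subset over the rate of actives in the
#' initial library.
#'
#' @param n_selected Number of selected molecules (> 0).
#' @param n_active_selected Number of actives among them.
#' @param base_rate Active rate of the full library, in (0, 1].
#' @return `(n_active_selected/n_selected) / base_rate`.
#' @export
enrichment_factor <- function(n_selected, n_active_selected, base_rate) {
  stopifnot(n_selected > 0L, base_rate > 0, base_rate <= 1,
            n_active_selected >= 0L, n_active_selected <= n_selected)
  (n_active_selected / n_selected) / base_rate
}

#' Run a virtual-screening benchmark
#'
#' Ranks the library with the supplied ranker, docks the `top_k` molecules
#' with the lowest predicted scores, labels a molecule active iff its best
#' docking score is below the threshold, and computes the enrichment factor
#' against the base active rate. Ties at the top-k boundary are broken by
#' canonical-SMILES lexicographic order for determinism. Preparation-
#' rejected molecules are excluded from the selection count; other backend
#' failures are logged and count as inactive selections.
#'
#' @param ranker Function `character vector of SMILES -> numeric predicted
#'   scores` (lower = better).
#' @param library_smiles Candidate library.
#' @param target A `prepared_target`.
#' @param backend Docking backend.
#' @param top_k Number of molecules to select (default 5000; must not
#'   exceed the library size).
#' @param threshold Activity threshold; default the published threshold for
#'   `target$name`.
#' @param base_rate Library active rate (default 0.001).
#' @param params Docking parameters.
#' @return A `screening_result`: list with `threshold`, `n_selected`,
#'   `n_active`, `ef`, and the selected data.frame `selection`.
#' @export
run_screen <- function(ranker, library_smiles, target, backend = mock_backend(),
                       top_k = 5000L, threshold = NULL, base_rate = 0.001,
                       params = docking_params()) {
  if (top_k > length(library_smiles)) {
    stop("top_k exceeds the library size")
  }
  if (is.null(threshold)) threshold <- published_threshold(target$name)
  pred <- ranker(library_smiles)
  stopifnot(length(pred) == length(library_smiles))
  can <- canonical_smiles(library_smiles)
  ord <- order(pred, can, seq_along(pred))
  sel_idx <- ord[seq_len(top_k)]
  scores <- rep(NA_real_, top_k)
  rejected <- logical(top_k)
  for (i in seq_len(top_k)) {
    s <- library_smiles[[sel_idx[i]]]
    v <- validate_ligand(s)
    if (is_rejected(v)) { rejected[i] <- TRUE; next }
    r <- tryCatch(dock(target, s, params = params, backend = backend),
                  error = function(e) NULL)
    if (is.null(r)) {
      message(sprintf("run_screen: docking failed for %s", s))
      next
    }
    scores[i] <- suppressMessages(best_score(r))
  }
  n_selected <- sum(!rejected)
  n_active <- sum(scores < threshold, na.rm = TRUE)
  ef <- enrichment_factor(n_selected, n_active, base_rate)
  structure(
    list(threshold = threshold, n_selected = n_selected, n_active = n_active,
         ef = ef,
         selection = data.frame(smiles = library_smiles[sel_idx],
                                predicted = pred[sel_idx], score = scores,
                                rejected = rejected, stringsAsFactors = FALSE)),
    class = "screening_result"
  )
}

#' QED druglikeness penalty
#'
#' Linear penalty `weight * (1 - qed)`: 0 for a perfectly druglike molecule
#' (QED = 1) and `weight` (default 10) at QED = 0.
#'
#' @param qed QED value(s) in \[0, 1\].
#' @param weight Penalty weight (default 10).
#' @return Numeric penalty value(s).
#' @export
qed_penalty <- function(qed, weight = 10) {
  if (any(qed < 0 | qed > 1)) stop("qed out of [0, 1]")
  weight * (1 - qed)
}

#' De novo design objective specification
#'
#' Three QED-penalized objectives over docking scores (lower is better):
#' \describe{
#'   \item{F2}{`s(F2) + penalty`: dock well against the coagulation-factor
#'     protease F2.}
#'   \item{PROMISCUOUS_PPAR}{`max(s(PPARA), s(PPARD), s(PPARG)) + penalty`:
#'     strong binding to all three PPAR nuclear receptors (the worst of the
#'     three scores is optimized).}
#'   \item{SELECTIVE_JAK2}{`s(JAK2) - min(s(LCK), lck_anchor) + penalty`:
#'     strong binding to the kinase JAK2 and weak binding to LCK, with the
#'     LCK score anchored at its library median -8.1 so that weakening LCK
#'     binding beyond the anchor brings no further gain.}
#' }
#' The penalty is `penalty_weight * (1 - QED)`.
#'
#' @param kind One of `"F2"`, `"PROMISCUOUS_PPAR"`, `"SELECTIVE_JAK2"`.
#' @param lck_anchor LCK anchor score (default -8.1).
#' @param penalty_weight QED penalty weight (default 10).
#' @return An `objective_spec` with the target list filled in.
#' @export
objective_spec <- function(kind = c("F2", "PROMISCUOUS_PPAR", "SELECTIVE_JAK2"),
                           lck_anchor = -8.1, penalty_weight = 10) {
  kind <- match.arg(kind)
  targets <- switch(kind,
    F2 = "F2",
    PROMISCUOUS_PPAR = c("PPARA", "PPARD", "PPARG"),
    SELECTIVE_JAK2 = c("JAK2", "LCK")
  )
  structure(list(kind = kind, targets = targets, lck_anchor = lck_anchor,
                 penalty_weight = penalty_weight),
            class = "objective_spec")
}

#' Evaluate a de novo objective from scores and QED
#'
#' @param spec An [objective_spec()].
#' @param scores Named numeric vector of docking scores covering every
#'   target of the objective.
#' @param qed QED value in \[0, 1\].
#' @return The objective value (lower is better).
#' @export
objective_value <- function(spec, scores, qed) {
  stopifnot(inherits(spec, "objective_spec"))
  missing <- setdiff(spec$targets, names(scores))
  if (length(missing) > 0L) {
    stop(sprintf("missing target score(s): %s", paste(missing, collapse = ", ")))
  }
  penalty <- qed_penalty(qed, spec$penalty_weight)
  base <- switch(spec$kind,
    F2 = scores[["F2"]],
    PROMISCUOUS_PPAR = max(scores[c("PPARA", "PPARD", "PPARG")]),
    SELECTIVE_JAK2 = scores[["JAK2"]] - min(scores[["LCK"]], spec$lck_anchor)
  )
  unname(base + penalty)
}

# ---------------------------------------------------------------------------
# Evaluation ledger: budget accounting with cache semantics.

#' Open an evaluation ledger
#'
#' Tracks objective-function calls for a de novo design run. Each unique
#' molecule consumes one unit of budget; repeated evaluations are served
#' from the cache for free. The call list is append-only.
#'
#' @param budget Maximum number of unique evaluations (default 5000).
#' @return An `evaluation_ledger` (environment with reference semantics).
#' @export
new_ledger <- function(budget = 5000L) {
  env <- new.env(parent = emptyenv())
  env$budget <- as.integer(budget)
  env$calls <- list()       # list of (smiles, value)
  env$cache <- new.env(parent = emptyenv())
  env$n_unique <- 0L
  class(env) <- "evaluation_ledger"
  env
}

#' @export
print.evaluation_ledger <- function(x, ...) {
  cat(sprintf("<evaluation_ledger> %d/%d unique evaluations, %d calls\n",
              x$n_unique, x$budget, length(x$calls)))
  invisible(x)
}

#' Number of unique evaluations consumed
#' @param ledger An `evaluation_ledger`.
#' @return Integer count.
#' @export
ledger_unique_calls <- function(ledger) ledger$n_unique

#' Remaining budget of a ledger
#' @param ledger An `evaluation_ledger`.
#' @return Integer count.
#' @export
ledger_remaining <- function(ledger) ledger$budget - ledger$n_unique

#' All recorded calls in order
#' @param ledger An `evaluation_ledger`.
#' @return data.frame with columns `smiles`, `value` in call order.
#' @export
ledger_calls <- function(ledger) {
  if (length(ledger$calls) == 0L) {
    return(data.frame(smiles = character(0), value = numeric(0)))
  }
  data.frame(
    smiles = vapply(ledger$calls, `[[`, character(1), "smiles"),
    value = vapply(ledger$calls, `[[`, numeric(1), "value"),
    stringsAsFactors = FALSE
  )
}

#' Evaluate an objective under the ledger's budget
#'
#' A cache hit returns the stored value without consuming budget; a new
#' molecule consumes one unit. A molecule that fails preparation receives
#' the value `+Inf` and still consumes budget. The call after the budget is
#' exhausted raises a condition of class `BudgetExhausted`.
#'
#' @param ledger An open `evaluation_ledger`.
#' @param spec An [objective_spec()].
#' @param smiles Molecule to evaluate.
#' @param score_fun Function `(smiles, target) -> docking score` (e.g. from
#'   [mock_score_function()]).
#' @param qed_fun Function `smiles -> QED`; defaults to [qed_score()].
#' @return The objective value (may be `+Inf`).
#' @export
evaluate_with_budget <- function(ledger, spec, smiles, score_fun,
                                 qed_fun = qed_score) {
  stopifnot(inherits(ledger, "evaluation_ledger"))
  key <- tryCatch(canonical_smiles(smiles), error = function(e) NA_character_)
  if (is.na(key)) key <- paste0("invalid:", smiles)
  if (!is.null(ledger$cache[[key]])) {
    val <- ledger$cache[[key]]
    ledger$calls[[length(ledger$calls) + 1L]] <- list(smiles = smiles, value = val)
    return(val)
  }
  if (ledger$n_unique >= ledger$budget) {
    stop(structure(
      class = c("BudgetExhausted", "error", "condition"),
      list(message = sprintf("evaluation budget (%d) exhausted", ledger$budget),
           call = sys.call())
    ))
  }
  verdict <- validate_ligand(smiles)
  val <- if (is_rejected(verdict)) {
    Inf
  } else {
    sc <- vapply(spec$targets, function(t) score_fun(smiles, t), numeric(1))
    q <- tryCatch(qed_fun(smiles), error = function(e) NA_real_)
    v <- if (is.na(q) || anyNA(sc)) NA_real_ else objective_value(spec, sc, q)
    if (is.na(v)) Inf else v  # a failed evaluation still consumes budget
  }
  ledger$n_unique <- ledger$n_unique + 1L
  ledger$cache[[key]] <- val
  ledger$calls[[length(ledger$calls) + 1L]] <- list(smiles = smiles, value = val)
  val
}

#' Best-so-far trajectory
#'
#' At each call index `i`, the `k`-th smallest objective value among calls
#' `1..i`; `NA` while fewer than `k` calls have been made.
#'
#' @param ledger An `evaluation_ledger`.
#' @param k Order of the running statistic (k = 1: running minimum).
#' @return Numeric vector, one entry per recorded call.
#' @export
trajectory <- function(ledger, k = 1L) {
  stopifnot(k >= 1L)
  vals <- ledger_calls(ledger)$value
  out <- rep(NA_real_, length(vals))
  # maintain the k smallest seen so far
  heap <- numeric(0)
  for (i in seq_along(vals)) {
    heap <- sort(c(heap, vals[[i]]))
    if (length(heap) > k) heap <- heap[seq_len(k)]
    if (length(heap) >= k) out[[i]] <- heap[[k]]
  }
  out
}

#' Serialize a ledger to CSV
#'
#' @param ledger An `evaluation_ledger`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ledger <- function(ledger, path) {
  df <- ledger_calls(ledger)
  df$call_index <- seq_len(nrow(df))
  df$best_so_far <- trajectory(ledger, 1L)
  df$best_25th <- trajectory(ledger, 25L)
  utils::write.csv(df[, c("call_index", "smiles", "value", "best_so_far",
                          "best_25th")], path, row.names = FALSE)
  invisible(path)
}
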