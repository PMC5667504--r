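#' ROC AUC of a p-value ranking against ground truth
#'
#' Area under the ROC curve obtained by ranking features by ascending
#' p-value against a binary truth, via the rank (Wilcoxon) identity with
#' mid-ranks for ties. Missing p-values are ranked last (least significant).
#' Invariant to any strictly monotone transform of the p-values.
#'
#' @param p_values Numeric vector (smaller = more significant; `NA` allowed).
#' @param truth Logical (or 0/1) vector: `TRUE` for truly differential.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(.001, .02, .3, .8), c(TRUE, TRUE, FALSE, FALSE)) # 1
#' @export
roc_auc <- function(p_values, truth) {
  truth <- as.logical(truth)
  stopifnot(length(p_values) == length(truth), !anyNA(truth))
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    abort("`truth` must contain both classes to compute an AUC.")
  }
  p <- ifelse(is.na(p_values), Inf, p_values)
  r <- rank(p, ties.method = "average")
  # pairs where a positive ranks above (larger p than) a negative, ties half
  u <- sum(r[truth]) - n_pos * (n_pos + 1) / 2
  1 - u / (n_pos * n_neg)
}

#' Genuine/mock dataset pairs by sample swop
#'
#' Builds label-exchange negative controls: for a balanced design with k
#' replicates per condition, the k cyclic replicate pairings (A1-B2, A2-B3,
#' ..., Ak-B1) each yield a "mock" dataset in which that one A-replicate and
#' B-replicate exchange conditions — a replicate's IP and input columns move
#' together, since they are one paired library. The mock column multiset
#' equals the genuine one; only the condition assignment differs, so mock
#' calls estimate the no-signal background.
#'
#' @param dataset A balanced [merip_dataset()] (equal replicates per
#'   condition).
#' @return A list of `swop_pair` objects, each with elements `genuine`,
#'   `mock` (both `merip_dataset`s) and `swapped`, the pair of replicate
#'   column indices exchanged.
#' @export
make_swop_pairs <- function(dataset) {
  stopifnot(inherits(dataset, "merip_dataset"))
  idx <- condition_index(dataset)
  k <- lengths(idx)
  if (k[1L] != k[2L]) {
    abort("sample swop requires a balanced design (equal replicates per condition).")
  }
  lapply(seq_len(k[1L]), function(r) {
    a <- idx[[1L]][r]
    b <- idx[[2L]][(r %% k[2L]) + 1L]
    cond <- as.character(dataset$conditions)
    cond[c(a, b)] <- cond[c(b, a)]
    mock <- merip_dataset(dataset$ip, dataset$input, cond,
                          feature_ids = dataset$feature_ids)
    structure(list(genuine = dataset, mock = mock, swapped = c(a, b)),
              class = "swop_pair")
  })
}

#' @export
print.swop_pair <- function(x, ...) {
  cat(sprintf("<swop_pair> swapped replicate columns %d and %d\n",
              x$swapped[1L], x$swapped[2L]))
  invisible(x)
}

#' Genuine-vs-mock calling curve
#'
#' For each target fraction x of features called on the mock (label-exchanged)
#' results, finds the p-value threshold achieving at least that mock fraction
#' (the empirical mock p-value quantile; boundary ties included) and reports
#' the fraction of genuine features called at the same threshold, averaged
#' over the swop pairs. A method with real signal shows genuine fractions
#' well above the identity line. The ratio mock/genuine at each x is the
#' implied empirical false discovery rate of the genuine calls.
#'
#' @param genuine_p p-values from the correctly labelled dataset (vector, or
#'   a list of vectors — one per swop pair).
#' @param mock_p p-values from the mock dataset(s): vector or list matching
#'   `genuine_p`.
#' @param fractions Target mock calling fractions (default
#'   `c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2)`).
#' @return A tibble with `mock_fraction` (target), `mock_called`,
#'   `genuine_fraction` and `implied_fdr`, averaged over pairs.
#' @export
swop_curve <- function(genuine_p, mock_p,
                       fractions = c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2)) {
  if (!is.list(genuine_p)) genuine_p <- list(genuine_p)
  if (!is.list(mock_p)) mock_p <- list(mock_p)
  stopifnot(length(genuine_p) == length(mock_p), length(fractions) >= 1)
  if (!length(genuine_p[[1L]])) abort("empty result vectors.")

  one_pair <- function(gp, mp) {
    stopifnot(length(gp) == length(mp))
    n <- length(mp)
    mp_sorted <- sort(mp) # NAs dropped: never called
    vapply(fractions, function(x) {
      k <- ceiling(x * n)
      if (k < 1L || k > length(mp_sorted)) {
        thr <- if (k < 1L) -Inf else Inf
      } else {
        thr <- mp_sorted[k]
      }
      c(mock = mean(!is.na(mp) & mp <= thr),
        genuine = mean(!is.na(gp) & gp <= thr))
    }, c(mock = 0, genuine = 0))
  }
  per_pair <- Map(one_pair, genuine_p, mock_p)
  avg <- Reduce(`+`, per_pair) / length(per_pair)
  tibble::tibble(
    mock_fraction = fractions,
    mock_called = avg["mock", ],
    genuine_fraction = avg["genuine", ],
    implied_fdr = ifelse(avg["genuine", ] > 0,
                         avg["mock", ] / avg["genuine", ], NA_real_)
  )
}
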