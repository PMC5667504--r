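#' Differential RNA methylation test on a paired IP/input dataset
#'
#' Runs the full quad-negative-binomial pipeline: size factors per sample
#' type, feature-level estimates (abundance, per-condition and pooled
#' methylation rates, expression factors), raw-variance surfaces, and the
#' exact conditional two-sided test of equal methylation rate per feature,
#' with Benjamini-Hochberg adjustment across tested features. Per-feature
#' failures become status flags, never an abort; feature order is preserved.
#'
#' @param dataset A [merip_dataset()], or an IP count data frame / matrix
#'   (in which case `input` and `conditions` must be given and are passed to
#'   [merip_dataset()]).
#' @param input,conditions See [merip_dataset()]; ignored when `dataset`
#'   already is one.
#' @param size_factor_method `"geometric"` (default) or `"total"`; see
#'   [size_factors()].
#' @param mode Raw-variance fitting mode, see [fit_variance_model()].
#' @param smooth Loess span for the variance smoother, see
#'   [fit_variance_model()].
#' @param engine Variance smoothing engine, see [fit_variance_model()].
#' @param p_adjust Multiple-testing adjustment method (any method of
#'   [stats::p.adjust()]); default `"BH"`.
#' @return An object of class `qnb_fit`. `tidy()` returns the per-feature
#'   result tibble (columns `feature_id`, `p_hat_A`, `p_hat_B`, `p_hat_O`,
#'   `q_hat`, `rr`, `log2_rr`, `or`, `p_value`, `p_adjusted`, `status`, with
#'   `A` the first condition level and `B` the control); `glance()` a one-row
#'   summary; `autoplot()` an abundance vs fold-change overview. The fit also
#'   stores the size factors, estimates and variance model.
#' @examples
#' sim <- simulate_merip(n_features = 300, d = 1, seed = 42)
#' fit <- qnb_test(sim$dataset)
#' tidy(fit)
#' glance(fit)
#' @export
qnb_test <- function(dataset, input = NULL, conditions = NULL,
                     size_factor_method = c("geometric", "total"),
                     mode = c("auto", "per-condition", "pooled", "blind"),
                     smooth = 0.7, engine = c("gamma", "loess"),
                     p_adjust = "BH") {
  if (!inherits(dataset, "merip_dataset")) {
    dataset <- merip_dataset(dataset, input, conditions)
  }
  factors <- size_factors(dataset, match.arg(size_factor_method))
  est <- merip_estimates(dataset, factors)
  model <- fit_variance_model(dataset, factors, mode = match.arg(mode),
                              smooth = smooth, engine = match.arg(engine),
                              estimates = est)

  conds <- est$conditions
  # Null raw variances at the pooled rate, vectorised once per group.
  v_null <- lapply(setNames(c("ip", "input"), c("ip", "input")), function(type) {
    lapply(setNames(conds, conds), function(l) {
      raw_variance(model, l, type, at_rate = est$p_hat_O)
    })
  })

  n <- nrow(dataset$ip)
  p_value <- rep(NA_real_, n)
  status <- character(n)
  for (i in seq_len(n)) {
    params <- group_nb_params(dataset, factors, model, i, v_null = v_null)
    out <- qnb_pvalue(params)
    p_value[i] <- out$p_value
    status[i] <- out$status
  }

  tested <- status == "tested"
  p_adjusted <- rep(NA_real_, n)
  p_adjusted[tested] <- p.adjust(p_value[tested], method = p_adjust)

  rr <- risk_ratio(dataset, factors)
  results <- tibble::tibble(
    feature_id = dataset$feature_ids,
    p_hat_A = est$p_hat[, 1L],
    p_hat_B = est$p_hat[, 2L],
    p_hat_O = est$p_hat_O,
    q_hat = est$q_hat,
    rr = rr,
    log2_rr = log2(rr),
    or = odds_ratio(dataset, factors),
    p_value = p_value,
    p_adjusted = p_adjusted,
    status = status
  )

  structure(
    list(results = results, dataset = dataset, factors = factors,
         estimates = est, model = model,
         conditions = conds, p_adjust = p_adjust),
    class = "qnb_fit"
  )
}

#' @export
print.qnb_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<qnb_fit> %d features (%d tested), conditions %s vs %s (control)\n",
    g$n_features, g$n_tested, x$conditions[1L], x$conditions[2L]
  ))
  cat(sprintf("  significant at adjusted p < 0.05: %d\n", g$n_significant))
  cat(sprintf("  variance mode: %s (resolved: %s)\n",
              x$model$mode, x$model$resolved_mode))
  invisible(x)
}

#' @rdname qnb_test
#' @param x A `qnb_fit`.
#' @param ... Unused.
#' @method tidy qnb_fit
#' @export
tidy.qnb_fit <- function(x, ...) x$results

#' @rdname qnb_test
#' @method glance qnb_fit
#' @export
glance.qnb_fit <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    n_features = nrow(r),
    n_tested = sum(r$status == "tested"),
    n_significant = sum(r$p_adjusted < 0.05, na.rm = TRUE),
    size_factor_method = x$factors$method,
    variance_mode = x$model$resolved_mode,
    p_adjust = x$p_adjust
  )
}

#' Write a result table (and optional BED6+ output)
#'
#' Writes the tidy per-feature results as TSV. When the dataset carried a
#' BED6 annotation (see [read_merip()]), a merged BED6+ file with the test
#' columns appended is written next to it.
#'
#' @param fit A [qnb_test()] fit (or its tidy tibble).
#' @param path Output TSV path.
#' @param bed_path Optional output path for the annotated BED.
#' @return Invisibly, `path`.
#' @export
write_results <- function(fit, path, bed_path = NULL) {
  res <- if (inherits(fit, "qnb_fit")) tidy(fit) else fit
  readr::write_tsv(res, path, progress = FALSE)
  ann <- if (inherits(fit, "qnb_fit")) attr(fit$dataset, "annotation") else NULL
  if (!is.null(bed_path) && !is.null(ann)) {
    merged <- dplyr::left_join(ann, res, by = c(name = "feature_id"))
    readr::write_tsv(merged, bed_path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}
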