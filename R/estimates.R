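#' Feature-level estimators of the quad-NB model
#'
#' The model writes the expected IP count of feature i in replicate j as
#' `q_i * p_{i,rho(j)} * e_{i,rho(j)} * s_{t,j}` and the expected input count
#' as `q_i * (1 - p) * e * s_{c,j}`: `q` is the abundance in a standard
#' library, `p` the methylation rate on the common scale, `e` a
#' condition-specific expression factor and `s` the library size factor.
#' These helpers compute the moment estimators of each parameter from the
#' depth-normalised counts. Abundance deliberately pools IP and input reads,
#' which keeps the background estimate usable for lowly expressed features
#' where the input library alone is thin.
#'
#' @param dataset A [merip_dataset()].
#' @param factors A [size_factors()] result (or compatible list with `ip` and
#'   `input` vectors).
#' @param group A condition label, or `"pooled"` for the null common rate
#'   estimated from all replicates of both conditions.
#' @param condition A condition label.
#' @param q_hat Abundance vector from `estimate_abundance()`.
#' @return Numeric vectors (one entry per feature); `NA` where undefined
#'   (zero denominators).
#' @name estimators
NULL

norm_counts <- function(dataset, factors, type = c("ip", "input")) {
  type <- match.arg(type)
  sweep(dataset[[type]], 2L, factors[[type]], "/")
}

#' @rdname estimators
#' @export
estimate_abundance <- function(dataset, factors) {
  rowMeans(norm_counts(dataset, factors, "ip") +
             norm_counts(dataset, factors, "input"))
}

#' @rdname estimators
#' @export
estimate_methylation_rate <- function(dataset, factors, group = "pooled") {
  idx <- if (identical(group, "pooled")) {
    seq_along(dataset$conditions)
  } else {
    group_index(dataset, group)
  }
  ip <- norm_counts(dataset, factors, "ip")[, idx, drop = FALSE]
  tot <- ip + norm_counts(dataset, factors, "input")[, idx, drop = FALSE]
  num <- rowSums(ip)
  den <- rowSums(tot)
  ifelse(den > 0, num / den, NA_real_)
}

#' @rdname estimators
#' @export
estimate_expression_factor <- function(dataset, factors, q_hat, condition) {
  idx <- group_index(dataset, condition)
  tot <- norm_counts(dataset, factors, "ip")[, idx, drop = FALSE] +
    norm_counts(dataset, factors, "input")[, idx, drop = FALSE]
  ifelse(q_hat > 0, rowSums(tot) / (length(idx) * q_hat), NA_real_)
}

group_index <- function(dataset, condition) {
  idx <- which(as.character(dataset$conditions) == as.character(condition))
  if (!length(idx)) {
    abort(sprintf("no replicate has condition label '%s'.", condition))
  }
  idx
}

#' Common-scale replicate variance and its shot-noise bias term
#'
#' For a sample type and replicate group, each count is brought to the common
#' scale by dividing out its size factor and the feature's expression factor;
#' `common_scale_variance()` returns the unbiased sample variance `w_hat` of
#' these rescaled counts across the group's replicates (and their mean
#' `q_bar`). `bias_term()` is the expected shot-noise contribution `z` to
#' `w_hat`, so that `w_hat - z` estimates the raw (extra-Poisson) variance
#' without bias. For the input type the rate enters as its complement
#' `1 - p_hat`.
#'
#' @inheritParams estimators
#' @param e_hat Expression factors for `condition` from
#'   [estimate_expression_factor()].
#' @param sample_type `"ip"` or `"input"`.
#' @param columns Optional explicit column indices overriding `condition`
#'   (used for the "blind" fitting group that pools every replicate).
#' @param p_hat Methylation-rate vector at which the bias term is evaluated.
#' @return `common_scale_variance()`: a list with `w_hat` and `q_bar`;
#'   `bias_term()`: a numeric vector `z`.
#' @export
common_scale_variance <- function(dataset, factors, e_hat, condition = NULL,
                                  sample_type = c("ip", "input"),
                                  columns = NULL) {
  sample_type <- match.arg(sample_type)
  idx <- columns %||% group_index(dataset, condition)
  if (length(idx) < 2L) {
    abort(paste0(
      "the fitting group has a single replicate; a sample variance needs >= 2. ",
      "Use variance mode \"blind\" or \"pooled\"."
    ))
  }
  m <- sweep(dataset[[sample_type]][, idx, drop = FALSE], 2L,
             factors[[sample_type]][idx], "/") / e_hat
  q_bar <- rowMeans(m)
  w_hat <- rowSums((m - q_bar)^2) / (length(idx) - 1L)
  list(w_hat = w_hat, q_bar = q_bar)
}

#' @rdname common_scale_variance
#' @export
bias_term <- function(q_hat, p_hat, factors, e_hat, condition = NULL,
                      sample_type = c("ip", "input"), dataset = NULL,
                      columns = NULL) {
  sample_type <- match.arg(sample_type)
  idx <- columns %||% group_index(dataset, condition)
  rate <- if (sample_type == "ip") p_hat else 1 - p_hat
  q_hat * rate * sum(1 / factors[[sample_type]][idx]) / (length(idx) * e_hat)
}

# All per-feature estimates needed by the variance model and the test.
merip_estimates <- function(dataset, factors) {
  conds <- levels(dataset$conditions)
  q_hat <- estimate_abundance(dataset, factors)
  p_hat <- vapply(conds, function(l) {
    estimate_methylation_rate(dataset, factors, l)
  }, numeric(nrow(dataset$ip)))
  e_hat <- vapply(conds, function(l) {
    estimate_expression_factor(dataset, factors, q_hat, l)
  }, numeric(nrow(dataset$ip)))
  list(
    q_hat = q_hat,
    p_hat = p_hat,
    e_hat = e_hat,
    p_hat_O = estimate_methylation_rate(dataset, factors, "pooled"),
    conditions = conds
  )
}
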