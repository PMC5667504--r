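#' Estimate library size factors per sample type
#'
#' Computes per-replicate sequencing-depth factors separately for the IP and
#' input libraries: the two library types are enriched differently, so their
#' factors are never pooled across types. `"geometric"` is the median-of-ratios
#' estimator of DESeq: within a sample type, the reference for each feature is
#' the geometric mean of its counts across that type's columns (restricted to
#' features positive in all columns) and a sample's factor is the median ratio
#' of its counts to the reference. `"total"` divides each column sum by the
#' mean column sum within its type, so factors are again of order one.
#'
#' @param dataset A [merip_dataset()].
#' @param method `"geometric"` (default) or `"total"`.
#' @return An object of class `merip_size_factors`: list with numeric vectors
#'   `ip` and `input` (strictly positive, one entry per replicate).
#' @examples
#' sim <- simulate_merip(n_features = 200, seed = 1)
#' size_factors(sim$dataset)
#' @export
size_factors <- function(dataset, method = c("geometric", "total")) {
  stopifnot(inherits(dataset, "merip_dataset"))
  method <- match.arg(method)
  f <- switch(method,
    geometric = list(ip = geometric_factors(dataset$ip, "IP"),
                     input = geometric_factors(dataset$input, "input")),
    total = list(ip = total_factors(dataset$ip),
                 input = total_factors(dataset$input))
  )
  structure(c(f, list(method = method)), class = "merip_size_factors")
}

geometric_factors <- function(counts, type) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    abort(sprintf(
      "no feature has positive counts in every %s column; use method = \"total\".",
      type
    ))
  }
  if (sum(pos) < 50) {
    warn(sprintf(
      "only %d features are positive in all %s columns; the geometric reference is fragile, consider method = \"total\".",
      sum(pos), type
    ))
  }
  m <- counts[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(m))) # per-feature geometric mean over the type
  apply(m, 2, function(col) median(col / ref))
}

total_factors <- function(counts) {
  cs <- colSums(counts)
  if (any(cs == 0)) abort("a column has zero total counts; size factors undefined.")
  cs / mean(cs)
}

#' @export
print.merip_size_factors <- function(x, ...) {
  cat(sprintf("<merip_size_factors> method = \"%s\"\n", x$method))
  cat("  IP:    ", paste(sprintf("%.3f", x$ip), collapse = " "), "\n")
  cat("  input: ", paste(sprintf("%.3f", x$input), collapse = " "), "\n")
  invisible(x)
}

#' @rdname size_factors
#' @param x A `merip_size_factors` object.
#' @param ... Unused.
#' @method tidy merip_size_factors
#' @export
tidy.merip_size_factors <- function(x, ...) {
  tibble::tibble(
    sample = rep(seq_along(x$ip), 2L),
    type = rep(c("ip", "input"), each = length(x$ip)),
    size_factor = c(x$ip, x$input)
  )
}
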