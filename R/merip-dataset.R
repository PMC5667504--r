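#' Assemble a paired IP/input MeRIP-seq count dataset
#'
#' Bundles the immunoprecipitation (IP) and input-control count matrices of a
#' MeRIP-seq experiment together with the replicate-to-condition assignment.
#' Every downstream estimator reads from this container. The two matrices must
#' be integer, non-negative, and share dimensions and replicate (column)
#' ordering; exactly two conditions must be present.
#'
#' @param ip,input Count tables, features x replicates. Either numeric
#'   matrices or data frames; a data frame may carry the feature identifiers
#'   in its first non-numeric column (as written by [write_merip()]). Column
#'   names, when present, must agree between `ip` and `input`.
#' @param conditions Character (or factor) vector, one condition label per
#'   replicate column. Exactly two distinct labels; the first label to appear
#'   is treated as the case/treated condition and the second as the control
#'   when effect sizes are reported.
#' @param feature_ids Optional character vector of unique feature identifiers;
#'   defaults to identifiers found in the tables or `feature_1..n`.
#'
#' @return An object of class `merip_dataset`: a list with elements `ip`,
#'   `input` (integer matrices), `conditions` (factor) and `feature_ids`.
#' @examples
#' ip <- matrix(rpois(12, 20), 3, 4)
#' ds <- merip_dataset(ip, ip + 1L, conditions = c("A", "A", "B", "B"))
#' ds
#' @export
merip_dataset <- function(ip, input, conditions, feature_ids = NULL) {
  ip <- as_count_matrix(ip, "ip")
  input <- as_count_matrix(input, "input")
  ids_ip <- attr(ip, "feature_ids")
  ids_in <- attr(input, "feature_ids")
  attr(ip, "feature_ids") <- NULL
  attr(input, "feature_ids") <- NULL

  if (!identical(dim(ip), dim(input))) {
    abort(sprintf(
      "`ip` (%d x %d) and `input` (%d x %d) must have identical dimensions.",
      nrow(ip), ncol(ip), nrow(input), ncol(input)
    ))
  }
  if (!is.null(colnames(ip)) && !is.null(colnames(input)) &&
      !identical(colnames(ip), colnames(input))) {
    abort("replicate columns differ between `ip` and `input` tables.")
  }
  if (length(conditions) != ncol(ip)) {
    abort(sprintf(
      "`conditions` has %d labels but the tables have %d replicate columns.",
      length(conditions), ncol(ip)
    ))
  }
  # a factor keeps its level order (first level = case, second = control);
  # otherwise first appearance decides
  conditions <- if (is.factor(conditions)) {
    droplevels(conditions)
  } else {
    factor(as.character(conditions), levels = unique(as.character(conditions)))
  }
  if (nlevels(conditions) != 2L) {
    abort(sprintf(
      "exactly two distinct condition labels are required, got %d (%s).",
      nlevels(conditions), paste(levels(conditions), collapse = ", ")
    ))
  }

  feature_ids <- feature_ids %||% ids_ip %||% ids_in %||%
    paste0("feature_", seq_len(nrow(ip)))
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != nrow(ip)) {
    abort("`feature_ids` length does not match the number of rows.")
  }
  if (anyDuplicated(feature_ids)) {
    dup <- feature_ids[duplicated(feature_ids)][1L]
    abort(sprintf("duplicated feature ID: '%s'.", dup))
  }
  if (!is.null(ids_ip) && !is.null(ids_in) && !identical(ids_ip, ids_in)) {
    abort("feature IDs differ between the `ip` and `input` tables.")
  }
  rownames(ip) <- rownames(input) <- NULL

  structure(
    list(ip = ip, input = input, conditions = conditions,
         feature_ids = feature_ids),
    class = "merip_dataset"
  )
}

# Coerce a table to a validated integer count matrix; data-frame inputs may
# carry feature IDs in their first non-numeric column.
as_count_matrix <- function(x, what) {
  ids <- NULL
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    if (!num[1L] && all(num[-1L])) {
      ids <- as.character(x[[1L]])
      x <- x[-1L]
    }
    bad <- which(!vapply(x, is.numeric, logical(1)))
    if (length(bad)) {
      abort(sprintf("non-numeric column '%s' in the %s table.",
                    names(x)[bad[1L]], what))
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix or data frame of counts.", what))
  }
  bad <- which(!is.finite(x) | x < 0 | x != round(x))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(x))
    abort(sprintf(
      "%s counts must be non-negative integers; offending cell [row %d, column %d] = %s.",
      what, i[1L], i[2L], format(x[bad[1L]])
    ))
  }
  storage.mode(x) <- "integer"
  attr(x, "feature_ids") <- ids
  x
}

#' Read a paired IP/input dataset from headered count tables
#'
#' Reads two TSV/CSV count tables (first column feature ID, remaining columns
#' replicates, identical headers) and assembles a validated [merip_dataset()].
#' An optional BED6 site annotation keyed by feature ID can be attached; it is
#' carried through to [write_results()] unmodified.
#'
#' @param ip_file,input_file Paths to the IP and input count tables.
#' @param conditions Condition label per replicate column (see
#'   [merip_dataset()]).
#' @param bed_file Optional path to a BED6 file whose name column matches the
#'   feature IDs.
#' @return A `merip_dataset`, with the annotation (if any) stored in the
#'   `annotation` attribute.
#' @export
read_merip <- function(ip_file, input_file, conditions, bed_file = NULL) {
  read_one <- function(path) {
    tbl <- readr::read_delim(path, delim = guess_delim(path),
                             show_col_types = FALSE, progress = FALSE)
    tbl
  }
  ip <- read_one(ip_file)
  input <- read_one(input_file)
  if (!identical(names(ip), names(input))) {
    abort("replicate columns differ between the IP and input tables.")
  }
  ds <- merip_dataset(as.data.frame(ip), as.data.frame(input), conditions)
  if (!is.null(bed_file)) {
    bed <- readr::read_tsv(bed_file, col_names = c(
      "chrom", "start", "end", "name", "score", "strand"
    ), show_col_types = FALSE, progress = FALSE)
    attr(ds, "annotation") <- bed
  }
  ds
}

guess_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Write a dataset back to a pair of count tables
#'
#' @param dataset A [merip_dataset()].
#' @param prefix Output path prefix; writes `<prefix>_ip.tsv`,
#'   `<prefix>_input.tsv` and `<prefix>_conditions.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_merip <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "merip_dataset"))
  cn <- colnames(dataset$ip) %||% paste0("sample_", seq_along(dataset$conditions))
  to_tbl <- function(m) {
    colnames(m) <- cn
    tibble::as_tibble(as.data.frame(m)) |>
      dplyr::mutate(feature_id = dataset$feature_ids, .before = 1L)
  }
  paths <- c(
    ip = paste0(prefix, "_ip.tsv"),
    input = paste0(prefix, "_input.tsv"),
    conditions = paste0(prefix, "_conditions.tsv")
  )
  readr::write_tsv(to_tbl(dataset$ip), paths[["ip"]], progress = FALSE)
  readr::write_tsv(to_tbl(dataset$input), paths[["input"]], progress = FALSE)
  readr::write_tsv(
    tibble::tibble(sample = cn, condition = as.character(dataset$conditions)),
    paths[["conditions"]], progress = FALSE
  )
  invisible(paths)
}

#' @export
print.merip_dataset <- function(x, ...) {
  k <- table(x$conditions)
  cat(sprintf(
    "<merip_dataset> %d features, %d replicates (%s)\n",
    nrow(x$ip), ncol(x$ip),
    paste(sprintf("%s: %d", names(k), k), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.merip_dataset <- function(x) dim(x$ip)

#' Naive per-site methylation rate
#'
#' The single-value methylation-level estimate `t / (t + c)` from one IP count
#' `t` and one input count `c`. Reported for description only: the same 100%
#' is returned for (100, 0) and (1, 0) even though the second carries almost
#' no information, which is why testing works on the counts themselves. When
#' `t + c = 0` the rate is undefined and `NA` is returned (never 0).
#'
#' @param t,c Non-negative counts (vectorised).
#' @return Numeric vector of rates in \[0, 1\], `NA` where `t + c = 0`.
#' @examples
#' naive_methylation_rate(100, 0) # 1: reported as 100% methylation
#' naive_methylation_rate(0, 0)   # NA
#' @export
naive_methylation_rate <- function(t, c) {
  stopifnot(all(t >= 0, na.rm = TRUE), all(c >= 0, na.rm = TRUE))
  n <- t + c
  ifelse(n > 0, t / n, NA_real_)
}

# Column indices of each condition, in level order (case first, control second)
condition_index <- function(dataset) {
  lapply(levels(dataset$conditions),
         function(l) which(dataset$conditions == l)) |>
    setNames(levels(dataset$conditions))
}
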