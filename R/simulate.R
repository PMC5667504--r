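#' Simulate a MeRIP-seq count dataset with ground truth
#'
#' Generates paired IP/input count matrices from the quad-NB generative
#' model. Per feature: log abundance `log(q)` uniform on `log_q_range`;
#' methylation rate `p_A` uniform on (0, 1), with `p_B = p_A` for
#' non-differential features and redrawn independently otherwise; per
#' condition a lognormal expression factor `e`; per sample lognormal size
#' factors `s_t`, `s_c`. Counts are drawn from NB laws with mean
#' `q * p * e * s_t` (IP) or `q * (1 - p) * e * s_c` (input) and variance
#' `mean + (e * s)^2 * v`, where the raw variance is `v = d / (e * s)` so a
#' single constant `d` tunes the over-dispersion (Poisson at `d = 0`). The
#' defaults mirror a typical 20,000-site, 3 + 3 replicate experiment with
#' half the sites truly differential.
#'
#' @param n_features Number of features (default 20000).
#' @param reps_per_condition Biological replicates per condition (default 3;
#'   a length-2 vector allows unbalanced designs).
#' @param d Over-dispersion constant, `>= 0` (default 1).
#' @param frac_diff Fraction of truly differential features (default 0.5).
#' @param log_q_range Range of `log(q)` (natural log), default
#'   `log(c(10, 1e4))`.
#' @param sd_log_e,sd_log_s Standard deviations of `log(e)` and `log(s)`
#'   (default 0.25 each).
#' @param conditions Two condition labels, default `c("A", "B")`.
#' @param seed Optional integer seed; fixes all randomness (the caller's RNG
#'   state is untouched).
#' @return A list with `dataset` (a [merip_dataset()]) and `truth`, a tibble
#'   of the generating parameters per feature (`q`, `p_A`, `p_B`, `e_A`,
#'   `e_B`, `is_differential`) with per-sample true size factors in the
#'   `size_factors` attribute.
#' @examples
#' sim <- simulate_merip(n_features = 100, d = 0, seed = 7)
#' sim$dataset
#' mean(sim$truth$is_differential)
#' @export
simulate_merip <- function(n_features = 20000, reps_per_condition = 3,
                           d = 1, frac_diff = 0.5,
                           log_q_range = log(c(10, 1e4)),
                           sd_log_e = 0.25, sd_log_s = 0.25,
                           conditions = c("A", "B"), seed = NULL) {
  stopifnot(n_features >= 1, d >= 0, frac_diff >= 0, frac_diff <= 1,
            length(log_q_range) == 2L, log_q_range[1L] < log_q_range[2L],
            sd_log_e >= 0, sd_log_s >= 0, length(conditions) == 2L)
  reps <- rep_len(as.integer(reps_per_condition), 2L)
  stopifnot(all(reps >= 1L))
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_merip(
      n_features, reps_per_condition, d, frac_diff, log_q_range,
      sd_log_e, sd_log_s, conditions, seed = NULL
    )))
  }

  n_samples <- sum(reps)
  cond_of <- rep(conditions, reps)

  q <- exp(runif(n_features, log_q_range[1L], log_q_range[2L]))
  p_a <- runif(n_features)
  n_diff <- round(frac_diff * n_features)
  is_diff <- seq_len(n_features) <= n_diff # fixed count, order then irrelevant
  p_b <- p_a
  if (n_diff > 0) {
    repeat {
      redraw <- is_diff & p_b == p_a
      if (!any(redraw)) break
      p_b[redraw] <- runif(sum(redraw))
    }
  }
  e <- matrix(exp(rnorm(2L * n_features, 0, sd_log_e)), n_features, 2L,
              dimnames = list(NULL, conditions))
  s_t <- exp(rnorm(n_samples, 0, sd_log_s))
  s_c <- exp(rnorm(n_samples, 0, sd_log_s))

  p_mat <- cbind(p_a, p_b)[, match(cond_of, conditions), drop = FALSE]
  e_mat <- e[, match(cond_of, conditions), drop = FALSE]

  draw <- function(rate_mat, s, d) {
    m <- matrix(0L, n_features, n_samples)
    for (j in seq_len(n_samples)) {
      mu <- q * rate_mat[, j] * e_mat[, j] * s[j]
      # variance = mu + (e s)^2 * v with v = d / (e s)  =>  mu + d e s
      extra <- d * e_mat[, j] * s[j]
      m[, j] <- rnb_mean_var(n_features, mu, mu + extra)
    }
    m
  }
  ip <- draw(p_mat, s_t, d)
  input <- draw(1 - p_mat, s_c, d)
  colnames(ip) <- colnames(input) <- paste0(
    rep(conditions, reps), "_rep", unlist(lapply(reps, seq_len))
  )

  dataset <- merip_dataset(ip, input, cond_of)
  truth <- tibble::tibble(
    feature_id = dataset$feature_ids,
    q = q, p_A = p_a, p_B = p_b,
    e_A = e[, 1L], e_B = e[, 2L],
    is_differential = is_diff
  )
  attr(truth, "size_factors") <- tibble::tibble(
    sample = colnames(ip), condition = cond_of, s_t = s_t, s_c = s_c
  )
  structure(list(dataset = dataset, truth = truth),
            config = list(d = d, frac_diff = frac_diff,
                          log_q_range = log_q_range,
                          sd_log_e = sd_log_e, sd_log_s = sd_log_s),
            class = "merip_simulation")
}

#' @export
print.merip_simulation <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<merip_simulation> d = %g, %.0f%% differential\n",
              cfg$d, 100 * cfg$frac_diff))
  print(x$dataset)
  invisible(x)
}

# NB draw in mean/variance form; Poisson when variance <= mean. Same
# (mean, variance) -> (size, mu) conversion as nb_pmf(), so the simulator and
# the test share one model.
rnb_mean_var <- function(n, mean, variance) {
  out <- integer(n)
  pois <- variance <= mean | mean <= 0
  if (any(pois)) out[pois] <- rpois(sum(pois), pmax(mean[pois], 0))
  if (any(!pois)) {
    m <- mean[!pois]
    out[!pois] <- rnbinom(sum(!pois), size = m^2 / (variance[!pois] - m), mu = m)
  }
  out
}

#' Compare simulated counts with their generative moments
#'
#' Validation aid for the simulator: one row per feature x sample with the
#' observed count and the theoretical mean and variance of its generative NB
#' law (`variance = mean + d * e * s`). Pooling standardized residuals over
#' many features checks the moment structure: at `d = 0` the pooled
#' variance/mean ratio is 1 (Poisson), and it grows with `d`.
#'
#' @param sim A [simulate_merip()] result.
#' @return A tibble with columns `feature_id`, `sample`, `sample_type`,
#'   `condition`, `is_differential`, `theoretical_mean`,
#'   `theoretical_variance`, `count`.
#' @examples
#' mom <- empirical_moments(simulate_merip(n_features = 2000, d = 0, seed = 1))
#' # pooled variance/mean ratio near 1 at d = 0:
#' with(mom, mean((count - theoretical_mean)^2) / mean(theoretical_mean))
#' @export
empirical_moments <- function(sim) {
  stopifnot(inherits(sim, "merip_simulation"))
  ds <- sim$dataset
  truth <- sim$truth
  d <- attr(sim, "config")$d
  sf <- attr(truth, "size_factors")
  conds <- levels(ds$conditions)
  p_mat <- cbind(truth$p_A, truth$p_B)
  e_mat <- cbind(truth$e_A, truth$e_B)
  rows <- list()
  for (type in c("ip", "input")) {
    s <- if (type == "ip") sf$s_t else sf$s_c
    for (j in seq_along(ds$conditions)) {
      ci <- match(as.character(ds$conditions[j]), conds)
      rate <- if (type == "ip") p_mat[, ci] else 1 - p_mat[, ci]
      mu <- truth$q * rate * e_mat[, ci] * s[j]
      rows[[paste(type, j)]] <- tibble::tibble(
        feature_id = truth$feature_id,
        sample = sf$sample[j], sample_type = type,
        condition = as.character(ds$conditions[j]),
        is_differential = truth$is_differential,
        theoretical_mean = mu,
        theoretical_variance = mu + d * e_mat[, ci] * s[j],
        count = ds[[type]][, j]
      )
    }
  }
  dplyr::bind_rows(rows)
}
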