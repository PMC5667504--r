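# Independent oracles used across tests. These re-derive quantities from
# first principles (direct sums, enumeration) and must stay independent of
# the package's own code paths.

# Median-of-ratios size factors, computed feature-by-feature.
oracle_median_of_ratios <- function(counts) {
  keep <- apply(counts > 0, 1, all)
  m <- counts[keep, , drop = FALSE]
  ref <- apply(m, 1, function(r) exp(mean(log(r))))
  apply(m, 2, function(col) median(col / ref))
}

# NB pmf in (mean, variance) form via the size/prob parameterisation.
oracle_nb_pmf <- function(k, m, v) {
  if (m <= 0) return(as.numeric(k == 0))
  if (v <= m) return(dpois(k, m))
  r <- m^2 / (v - m)
  dnbinom(k, size = r, prob = r / (r + m))
}

# Exhaustive two-sided conditional p-value from four (mean, variance) laws
# and observed group sums. Brute force over every valid split.
oracle_pvalue <- function(mu, sig2, t_obs, t_i, n_a, n_b) {
  lo <- max(0, t_i - n_b)
  hi <- min(t_i, n_a)
  ts <- lo:hi
  probs <- vapply(ts, function(t) {
    oracle_nb_pmf(t, mu[["ip_a"]], sig2[["ip_a"]]) *
      oracle_nb_pmf(t_i - t, mu[["ip_b"]], sig2[["ip_b"]]) *
      oracle_nb_pmf(n_a - t, mu[["in_a"]], sig2[["in_a"]]) *
      oracle_nb_pmf(n_b - t_i + t, mu[["in_b"]], sig2[["in_b"]])
  }, numeric(1))
  p_obs <- probs[match(t_obs, ts)]
  sum(probs[probs <= p_obs * (1 + 1e-8)]) / sum(probs)
}

# All-pairs concordance AUC (positives should have smaller p-values).
oracle_auc <- function(p, truth) {
  pos <- which(truth)
  neg <- which(!truth)
  s <- 0
  for (i in pos) {
    for (j in neg) {
      s <- s + (p[i] < p[j]) + 0.5 * (p[i] == p[j])
    }
  }
  s / (length(pos) * length(neg))
}

# Small deterministic dataset used by several estimator tests.
toy_dataset <- function() {
  ip <- matrix(c(
    6L, 12L, 3L, 9L,
    8L, 10L, 4L, 6L,
    0L, 0L, 0L, 0L
  ), nrow = 3, byrow = TRUE)
  input <- matrix(c(
    4L, 8L, 7L, 1L,
    2L, 6L, 6L, 4L,
    0L, 0L, 0L, 0L
  ), nrow = 3, byrow = TRUE)
  merip_dataset(ip, input, conditions = c("A", "A", "B", "B"))
}

unit_factors <- function(n) {
  structure(list(ip = rep(1, n), input = rep(1, n), method = "unit"),
            class = "merip_size_factors")
}

# Hand-assembled group-parameter object for direct p-value tests.
make_params <- function(mu, sig2, t_obs, t_i, n_a, n_b) {
  structure(list(
    status = "tested",
    groups = list(
      ip_A = list(mean = mu[["ip_a"]], variance = sig2[["ip_a"]],
                  observed = t_obs),
      ip_B = list(mean = mu[["ip_b"]], variance = sig2[["ip_b"]],
                  observed = t_i - t_obs),
      input_A = list(mean = mu[["in_a"]], variance = sig2[["in_a"]],
                     observed = n_a - t_obs),
      input_B = list(mean = mu[["in_b"]], variance = sig2[["in_b"]],
                     observed = n_b - t_i + t_obs)
    ),
    conditions = c("A", "B"),
    t = c(A = t_obs, B = t_i - t_obs),
    c = c(A = n_a - t_obs, B = n_b - t_i + t_obs),
    t_i = t_i, n = c(A = n_a, B = n_b), p_hat_O = NA_real_
  ), class = "qnb_group_params")
}
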