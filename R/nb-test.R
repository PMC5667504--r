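#' Negative-binomial probability mass in mean/variance form
#'
#' Density of the NB distribution parameterised by its mean and variance:
#' size `r = mean^2 / (variance - mean)` and `mu = mean`. At
#' `variance <= mean` the Poisson limit is used (the NB is undefined there),
#' and a zero mean puts all mass on zero. Negative `k` has probability 0.
#'
#' @param k Non-negative integer count(s).
#' @param mean Positive mean.
#' @param variance Variance, `>= mean` after the under-dispersion guard.
#' @param log Return log-probabilities?
#' @return Probability mass (or its log) at `k`.
#' @examples
#' nb_pmf(0, mean = 2, variance = 2) # exp(-2), the Poisson limit
#' @export
nb_pmf <- function(k, mean, variance, log = FALSE) {
  stopifnot(length(mean) == 1L, length(variance) == 1L)
  lp <- if (mean <= 0) {
    ifelse(k == 0, 0, -Inf)
  } else if (variance <= mean) {
    dpois(k, lambda = mean, log = TRUE)
  } else {
    dnbinom(k, size = mean^2 / (variance - mean), mu = mean, log = TRUE)
  }
  lp[k < 0] <- -Inf
  if (log) lp else exp(lp)
}

#' Group-level NB parameters for one feature
#'
#' Under the null hypothesis of one common methylation rate, the summed IP and
#' input counts of each condition follow four negative binomial laws. The
#' mean of the IP-A group is `p_O * q * e_A * sum(s_t over A)` and its
#' variance adds the raw-variance term
#' `v_A(p_O, q) * e_A^2 * sum(s_t^2 over A)` to that shot noise; the other
#' three groups are symmetric, with the input groups using the complement
#' rate `1 - p_O` and the input size factors. Groups whose variance falls at
#' or below the mean are treated as Poisson.
#'
#' @param dataset,factors,model The dataset, size factors and fitted
#'   [fit_variance_model()].
#' @param feature Feature index (row) to parameterise.
#' @param v_null Optional precomputed null raw variances (internal fast path):
#'   a list `v_null[[sample_type]][[condition]]`, each a per-feature vector of
#'   [raw_variance()] evaluated at the pooled rate.
#' @return A list of class `qnb_group_params`: per group (`ip_A`, `ip_B`,
#'   `input_A`, `input_B` with the dataset's own condition labels) the mean,
#'   variance and observed raw count sum, plus the totals `t_i`, `n_A`, `n_B`
#'   and the feature's `p_hat_O`. `NULL` fields and a `"skipped-zero"` status
#'   mark degenerate features (no reads at all, or `q_hat = 0`).
#' @export
group_nb_params <- function(dataset, factors, model, feature, v_null = NULL) {
  est <- model$estimates
  conds <- est$conditions
  idx <- condition_index(dataset)

  t_sum <- vapply(conds, function(l) sum(dataset$ip[feature, idx[[l]]]), numeric(1))
  c_sum <- vapply(conds, function(l) sum(dataset$input[feature, idx[[l]]]), numeric(1))
  n_sum <- t_sum + c_sum
  t_i <- sum(t_sum)

  q <- est$q_hat[feature]
  p_O <- est$p_hat_O[feature]
  if (t_i + sum(c_sum) == 0 || !is.finite(q) || q <= 0 || !is.finite(p_O)) {
    return(structure(list(status = "skipped-zero", t = t_sum, c = c_sum,
                          t_i = t_i, n = n_sum), class = "qnb_group_params"))
  }

  groups <- list()
  for (l in conds) {
    e <- est$e_hat[feature, l]
    for (type in c("ip", "input")) {
      s <- factors[[type]][idx[[l]]]
      rate <- if (type == "ip") p_O else 1 - p_O
      mu <- rate * q * e * sum(s)
      v_raw <- if (is.null(v_null)) {
        raw_variance(model, l, type, at_rate = p_O, features = feature)
      } else {
        v_null[[type]][[l]][feature]
      }
      sig2 <- mu + v_raw * e^2 * sum(s^2)
      if (!is.finite(sig2) || sig2 < mu) sig2 <- mu # Poisson guard
      obs <- if (type == "ip") t_sum[[l]] else c_sum[[l]]
      groups[[paste(type, l, sep = "_")]] <-
        list(mean = unname(mu), variance = unname(sig2), observed = obs)
    }
  }
  structure(
    list(status = "tested", groups = groups, conditions = conds,
         t = t_sum, c = c_sum, t_i = t_i, n = n_sum, p_hat_O = p_O),
    class = "qnb_group_params"
  )
}

# Valid support of the conditioned IP-A count: all four arguments of the
# joint probability must be non-negative.
support_range <- function(params) {
  c(max(0, params$t_i - params$n[[2L]]),
    min(params$t_i, params$n[[1L]]))
}

#' Joint conditional probability of an IP-count split
#'
#' Probability that condition A's summed IP count equals `t`, conditional on
#' the total methylation count `t_i` and the per-condition totals `n_A`,
#' `n_B`: the product of the four group NB masses at `t`, `t_i - t`,
#' `n_A - t` and `n_B - t_i + t`. Zero outside the valid range.
#'
#' @param params A [group_nb_params()] result with status `"tested"`.
#' @param t Integer value(s) of the condition-A IP sum.
#' @param log Return log-probabilities?
#' @return Probability (or log-probability) per value of `t`.
#' @export
joint_conditional_probability <- function(params, t, log = FALSE) {
  stopifnot(inherits(params, "qnb_group_params"),
            identical(params$status, "tested"))
  g <- params$groups
  conds <- params$conditions
  lp <- nb_pmf(t, g[[paste0("ip_", conds[1L])]]$mean,
               g[[paste0("ip_", conds[1L])]]$variance, log = TRUE) +
    nb_pmf(params$t_i - t, g[[paste0("ip_", conds[2L])]]$mean,
           g[[paste0("ip_", conds[2L])]]$variance, log = TRUE) +
    nb_pmf(params$n[[1L]] - t, g[[paste0("input_", conds[1L])]]$mean,
           g[[paste0("input_", conds[1L])]]$variance, log = TRUE) +
    nb_pmf(params$n[[2L]] - params$t_i + t,
           g[[paste0("input_", conds[2L])]]$mean,
           g[[paste0("input_", conds[2L])]]$variance, log = TRUE)
  rng <- support_range(params)
  lp[t < rng[1L] | t > rng[2L]] <- -Inf
  if (log) lp else exp(lp)
}

#' Two-sided exact conditional p-value
#'
#' Sums the conditional law over its full (bounded) support and reports the
#' fraction of mass on splits no more probable than the observed one:
#' `p = sum over {t : P(t) <= P(t_obs)} of P(t) / sum over all t of P(t)`.
#' The comparison uses a relative tolerance of `1e-8` so that floating-point
#' ties are included (slightly conservative). Computation is done on the log
#' scale, so extreme observations do not underflow.
#'
#' @param params A [group_nb_params()] result.
#' @return A list with `p_value` and `status` (`"tested"`,
#'   `"skipped-zero"`, or `"skipped-degenerate"` when the law has no
#'   numerically positive mass, in which case `p_value = 1`).
#' @export
qnb_pvalue <- function(params) {
  if (!identical(params$status, "tested")) {
    return(list(p_value = NA_real_, status = params$status))
  }
  rng <- support_range(params)
  ts <- seq.int(rng[1L], rng[2L])
  lp <- joint_conditional_probability(params, ts, log = TRUE)
  m <- max(lp)
  if (!is.finite(m)) {
    return(list(p_value = 1, status = "skipped-degenerate"))
  }
  w <- exp(lp - m)
  lp_obs <- lp[match(params$t[[1L]], ts)]
  keep <- lp <= lp_obs + log1p(1e-8)
  list(p_value = min(1, sum(w[keep]) / sum(w)), status = "tested")
}

#' Risk ratio and odds ratio of methylation between conditions
#'
#' `risk_ratio()` is the ratio of the estimated common-scale methylation
#' rates, case over control (the second condition label is the control).
#' `odds_ratio()` compares the depth-normalised IP/input odds of the two
#' conditions. Both return `NA` (never infinity) where a denominator is zero.
#'
#' @param dataset,factors Dataset and size factors.
#' @return Numeric vector, one entry per feature.
#' @export
risk_ratio <- function(dataset, factors) {
  conds <- levels(dataset$conditions)
  p_a <- estimate_methylation_rate(dataset, factors, conds[1L])
  p_b <- estimate_methylation_rate(dataset, factors, conds[2L])
  ifelse(is.finite(p_b) & p_b > 0, p_a / p_b, NA_real_)
}

#' @rdname risk_ratio
#' @export
odds_ratio <- function(dataset, factors) {
  idx <- condition_index(dataset)
  ip <- norm_counts(dataset, factors, "ip")
  input <- norm_counts(dataset, factors, "input")
  g <- function(m, i) rowSums(m[, i, drop = FALSE])
  t_a <- g(ip, idx[[1L]]); c_a <- g(input, idx[[1L]])
  t_b <- g(ip, idx[[2L]]); c_b <- g(input, idx[[2L]])
  ok <- c_a > 0 & t_b > 0 & c_b > 0
  ifelse(ok, (t_a / c_a) / (t_b / c_b), NA_real_)
}
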