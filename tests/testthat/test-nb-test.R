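# Exact conditional test: pmf building blocks, the conditional law, the
# two-sided p-value against brute-force enumeration, and effect sizes.

test_that("nb_pmf reduces to Poisson at variance = mean and normalises", {
  mu <- 7
  expect_equal(nb_pmf(0, mu, mu), exp(-mu))
  expect_equal(nb_pmf(0:30, mu, mu), dpois(0:30, mu))

  for (v in c(10, 30)) {
    k_max <- ceiling(10 + 50 * sqrt(v))
    total <- sum(nb_pmf(0:k_max, 10, v))
    expect_lt(abs(1 - total), 1e-12)
    # moment recovery by direct summation
    k <- 0:k_max
    pmf <- nb_pmf(k, 10, v)
    expect_equal(sum(k * pmf), 10, tolerance = 1e-8)
    expect_equal(sum((k - 10)^2 * pmf), v, tolerance = 1e-8)
  }
  expect_identical(nb_pmf(-1, 10, 30), 0)
  expect_identical(nb_pmf(-1, 10, 10), 0)
})

test_that("joint conditional probability vanishes off-support and is symmetric", {
  mu <- c(ip_a = 5, ip_b = 5, in_a = 4, in_b = 4)
  s2 <- mu * 1.8
  params <- make_params(mu, s2, t_obs = 3, t_i = 6, n_a = 5, n_b = 5)
  expect_identical(joint_conditional_probability(params, -1), 0)
  expect_identical(joint_conditional_probability(params, 7), 0)
  expect_identical(joint_conditional_probability(params, 6), 0) # n_a - t < 0

  # identical A/B laws and n_a = n_b: P(t) = P(t_i - t)
  ts <- 1:5
  pr <- joint_conditional_probability(params, ts)
  expect_equal(pr, rev(joint_conditional_probability(params, 6 - ts)))

  # matches the direct four-pmf product at every valid t
  direct <- vapply(ts, function(t) {
    oracle_nb_pmf(t, mu[["ip_a"]], s2[["ip_a"]]) *
      oracle_nb_pmf(6 - t, mu[["ip_b"]], s2[["ip_b"]]) *
      oracle_nb_pmf(5 - t, mu[["in_a"]], s2[["in_a"]]) *
      oracle_nb_pmf(5 - 6 + t, mu[["in_b"]], s2[["in_b"]])
  }, numeric(1))
  expect_equal(pr, direct, tolerance = 1e-12)
})

test_that("p-value definition: unique minimum and modal observation", {
  mu <- c(ip_a = 2, ip_b = 8, in_a = 8, in_b = 2)
  s2 <- mu * 1.5
  # observed at the edge of the support: typically the unique minimum
  params <- make_params(mu, s2, t_obs = 10, t_i = 10, n_a = 10, n_b = 10)
  pr <- joint_conditional_probability(params, 0:10)
  expect_true(pr[11] == min(pr[pr > 0]))
  expect_equal(qnb_pvalue(params)$p_value, pr[11] / sum(pr))

  # observed at the mode: every mass is <= P(mode), so p = 1
  mode_t <- which.max(pr) - 1
  params_mode <- make_params(mu, s2, t_obs = mode_t, t_i = 10,
                             n_a = 10, n_b = 10)
  expect_equal(qnb_pvalue(params_mode)$p_value, 1)
})

test_that("p-values equal exhaustive enumeration on random small instances", {
  set.seed(17)
  for (rep in 1:200) {
    t_i <- sample(0:50, 1)
    n_a <- sample(0:50, 1)
    n_b <- sample(max(0, t_i - n_a):50, 1) # ensure support non-empty
    lo <- max(0, t_i - n_b); hi <- min(t_i, n_a)
    t_obs <- sample(lo:hi, 1)
    mu <- c(ip_a = runif(1, .5, 20), ip_b = runif(1, .5, 20),
            in_a = runif(1, .5, 20), in_b = runif(1, .5, 20))
    s2 <- mu * runif(4, 1, 4)
    params <- make_params(mu, s2, t_obs, t_i, n_a, n_b)
    expect_equal(qnb_pvalue(params)$p_value,
                 oracle_pvalue(mu, s2, t_obs, t_i, n_a, n_b),
                 tolerance = 1e-10)
  }
})

test_that("risk and odds ratios match hand arithmetic and direct formulas", {
  f <- unit_factors(2)
  ds_same <- merip_dataset(cbind(5L, 5L), cbind(3L, 3L), c("A", "B"))
  expect_equal(risk_ratio(ds_same, f), 1)
  expect_equal(odds_ratio(ds_same, f), 1)

  # p_A = 0.6, p_B = 0.3 => RR = 2
  ds_rr <- merip_dataset(cbind(6L, 3L), cbind(4L, 7L), c("A", "B"))
  expect_equal(risk_ratio(ds_rr, f), 2)

  # A: t=4, c=1; B: t=1, c=4 => OR = (4/1)/(1/4) = 16
  ds_or <- merip_dataset(cbind(4L, 1L), cbind(1L, 4L), c("A", "B"))
  expect_equal(odds_ratio(ds_or, f), 16)

  # zero control rate => missing, not infinite
  ds_zero <- merip_dataset(cbind(4L, 0L), cbind(1L, 4L), c("A", "B"))
  expect_true(is.na(risk_ratio(ds_zero, f)))
  expect_true(is.na(odds_ratio(ds_zero, f)))

  sim <- simulate_merip(n_features = 500, d = 1, seed = 7)
  ds <- sim$dataset
  fs <- size_factors(ds)
  pA <- estimate_methylation_rate(ds, fs, "A")
  pB <- estimate_methylation_rate(ds, fs, "B")
  rr <- risk_ratio(ds, fs)
  expect_identical(is.na(rr), !(pB > 0)) # zero control rate -> missing
  ok <- !is.na(rr)
  expect_equal(rr[ok], (pA / pB)[ok], tolerance = 1e-12)
  jA <- which(ds$conditions == "A"); jB <- which(ds$conditions == "B")
  or_direct <- (rowSums(sweep(ds$ip[, jA], 2, fs$ip[jA], "/")) /
                  rowSums(sweep(ds$input[, jA], 2, fs$input[jA], "/"))) /
    (rowSums(sweep(ds$ip[, jB], 2, fs$ip[jB], "/")) /
       rowSums(sweep(ds$input[, jB], 2, fs$input[jB], "/")))
  or_est <- odds_ratio(ds, fs)
  # missing whenever any denominator sum is zero (never 0/Inf coercions)
  zero_denom <- rowSums(ds$input[, jA]) == 0 | rowSums(ds$ip[, jB]) == 0 |
    rowSums(ds$input[, jB]) == 0
  expect_identical(is.na(or_est), zero_denom)
  ok <- !is.na(or_est)
  expect_equal(or_est[ok], or_direct[ok], tolerance = 1e-12)
})

test_that("group NB parameters follow the mean/variance formulas and scale with factors", {
  sim <- simulate_merip(n_features = 100, d = 1, seed = 13)
  ds <- sim$dataset
  f <- size_factors(ds)
  m <- fit_variance_model(ds, f)
  est <- m$estimates
  i <- 13L
  params <- group_nb_params(ds, f, m, i)
  expect_identical(params$status, "tested")
  jA <- which(ds$conditions == "A")
  mu_direct <- unname(est$p_hat_O[i] * est$q_hat[i] * est$e_hat[i, "A"] *
                        sum(f$ip[jA]))
  expect_equal(params$groups$ip_A$mean, mu_direct, tolerance = 1e-12)
  v <- raw_variance(m, "A", "ip", at_rate = est$p_hat_O[i], features = i)
  sig_direct <- mu_direct + v * est$e_hat[i, "A"]^2 * sum(f$ip[jA]^2)
  expect_equal(params$groups$ip_A$variance, unname(max(sig_direct, mu_direct)),
               tolerance = 1e-12)
  inp_direct <- (1 - est$p_hat_O[i]) * est$q_hat[i] * est$e_hat[i, "B"] *
    sum(f$input[ds$conditions == "B"])
  expect_equal(params$groups$input_B$mean, unname(inp_direct),
               tolerance = 1e-12)
  # observed sums are the raw (unnormalised) integers
  obs <- params$groups$ip_A$observed
  expect_equal(obs, sum(ds$ip[i, jA]))
  expect_identical(obs, round(obs))

  # doubling the size factors (estimates held fixed) doubles every group mean
  f2 <- f; f2$ip <- f$ip * 2; f2$input <- f$input * 2
  params2 <- group_nb_params(ds, f2, m, i)
  for (g in names(params$groups)) {
    expect_equal(params2$groups[[g]]$mean, 2 * params$groups[[g]]$mean,
                 tolerance = 1e-12)
  }
})

test_that("a zero-dispersion surface gives the Poisson limit of the group laws", {
  sim <- simulate_merip(n_features = 100, d = 0, seed = 3)
  ds <- sim$dataset
  f <- unit_factors(ncol(ds$ip))
  m <- fit_variance_model(ds, f)
  for (type in c("ip", "input")) {
    for (g in names(m[[type]])) {
      m[[type]][[g]]$surface$predict <- function(p, q) rep(0, length(p))
    }
  }
  params <- group_nb_params(ds, f, m, 5L)
  for (g in params$groups) expect_equal(g$variance, g$mean)
})

test_that("the full pipeline returns a complete, order-stable, bounded result table", {
  sim <- simulate_merip(n_features = 600, d = 1, seed = 19)
  fit <- qnb_test(sim$dataset)
  res <- tidy(fit)
  expect_identical(nrow(res), 600L)
  tested <- res$status == "tested"
  expect_true(all(res$p_value[tested] >= 0 & res$p_value[tested] <= 1))
  expect_true(all(res$p_adjusted[tested] >= res$p_value[tested] - 1e-12))
  expect_identical(res$feature_id, sim$dataset$feature_ids)
  g <- glance(fit)
  expect_identical(g$n_features, 600L)
})

test_that("swapping condition labels preserves p-values and inverts RR/OR", {
  sim <- simulate_merip(n_features = 300, d = 1, seed = 23)
  ds <- sim$dataset
  labels <- as.character(ds$conditions)
  # same labels, but condition B designated as the case via the level order
  ds_sw <- merip_dataset(ds$ip, ds$input, factor(labels, levels = c("B", "A")),
                         feature_ids = ds$feature_ids)
  fit <- qnb_test(ds)
  fit_sw <- qnb_test(ds_sw)
  r <- tidy(fit); rs <- tidy(fit_sw)
  expect_equal(rs$p_value, r$p_value, tolerance = 1e-9)
  ok <- !is.na(r$rr) & !is.na(rs$rr)
  expect_equal(rs$rr[ok], 1 / r$rr[ok], tolerance = 1e-9)
  ok2 <- !is.na(r$or) & !is.na(rs$or)
  expect_equal(rs$or[ok2], 1 / r$or[ok2], tolerance = 1e-9)
})

test_that("rate estimates are invariant to consistent count/factor rescaling", {
  sim <- simulate_merip(n_features = 100, d = 1, seed = 29)
  ds <- sim$dataset
  f <- size_factors(ds)
  k <- 3L
  ds_k <- merip_dataset(ds$ip * k, ds$input * k,
                        as.character(ds$conditions))
  f_k <- f; f_k$ip <- f$ip * k; f_k$input <- f$input * k
  for (g in c("A", "B", "pooled")) {
    expect_equal(estimate_methylation_rate(ds_k, f_k, g),
                 estimate_methylation_rate(ds, f, g), tolerance = 1e-12)
  }
})

test_that("mean p-value decreases as the methylation-rate difference grows", {
  # fixed abundance and dispersion; cells differ only in |p_A - p_B|
  set.seed(59)
  deltas <- c(0, 0.1, 0.2, 0.3)
  n_cell <- 500; reps <- 3; q <- 300; v0 <- 60
  blocks <- lapply(deltas, function(delta) {
    # balanced effect directions, so depth normalisation stays neutral
    p_a <- runif(n_cell, 0.35, 0.6)
    p_b <- p_a + sample(c(-1, 1), n_cell, replace = TRUE) * delta
    draw <- function(p) {
      m <- outer(q * p, rep(1, reps))
      matrix(rnbinom(length(m), size = (q * p)^2 / v0, mu = m), n_cell, reps)
    }
    list(ip = cbind(draw(p_a), draw(p_b)),
         input = cbind(draw(1 - p_a), draw(1 - p_b)))
  })
  ds <- merip_dataset(
    do.call(rbind, lapply(blocks, `[[`, "ip")),
    do.call(rbind, lapply(blocks, `[[`, "input")),
    rep(c("A", "B"), each = reps)
  )
  fit <- qnb_test(ds)
  cell <- rep(deltas, each = n_cell)
  mean_p <- tapply(tidy(fit)$p_value, cell, mean, na.rm = TRUE)
  expect_true(all(diff(mean_p) < 0))
})

test_that("permuting feature rows permutes results identically", {
  sim <- simulate_merip(n_features = 200, d = 1, seed = 31)
  ds <- sim$dataset
  fit <- qnb_test(ds)
  set.seed(1); perm <- sample(200)
  ds_p <- merip_dataset(ds$ip[perm, ], ds$input[perm, ],
                        as.character(ds$conditions),
                        feature_ids = ds$feature_ids[perm])
  fit_p <- qnb_test(ds_p)
  expect_equal(tidy(fit_p)$p_value, tidy(fit)$p_value[perm], tolerance = 1e-8)
})

test_that("a conditional law with no numerically positive mass degrades to p = 1", {
  # both IP group means zero but a positive observed total: every split has
  # probability zero
  mu <- c(ip_a = 0, ip_b = 0, in_a = 5, in_b = 5)
  s2 <- c(ip_a = 0, ip_b = 0, in_a = 8, in_b = 8)
  params <- make_params(mu, s2, t_obs = 2, t_i = 4, n_a = 6, n_b = 6)
  out <- qnb_pvalue(params)
  expect_identical(out$status, "skipped-degenerate")
  expect_identical(out$p_value, 1)
})
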