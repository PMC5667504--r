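#' Fit the raw-variance surfaces
#'
#' The raw (extra-Poisson) variance of each feature is assumed to be a smooth
#' function of its methylation rate and abundance. For each sample type (IP,
#' input) and fitting group, the common-scale replicate variance `w_hat` is
#' smoothed over `(p_hat, log q_hat)` with a gamma-family model: by default a
#' penalized tensor-product spline with log link (`engine = "gamma"`, fitted
#' with [mgcv::gam()]), which keeps predictions positive and tolerates the
#' right-skewed residuals of a squared-deviation response; alternatively a
#' loess of `log(w_hat + eps)` exponentiated at evaluation
#' (`engine = "loess"`), whose nearest-neighbour span is the `smooth`
#' argument. If the gamma fit fails the loess engine is used and recorded in
#' the diagnostics. Zero responses (identical replicates) are floored at
#' `eps = 1e-8`, and evaluation clamps covariates to the fitted range rather
#' than extrapolating.
#'
#' Fitting groups by `mode`:
#' * `"per-condition"`: one surface per condition (each needs >= 2
#'   replicates) — the most sensitive choice;
#' * `"pooled"`: one surface per sample type from the stacked per-condition
#'   points of all replicated conditions, applied to both conditions;
#' * `"blind"`: all replicates of a sample type treated as one condition
#'   (rate = the pooled rate), usable even without biological replicates but
#'   conservative because between-condition signal inflates the variance;
#' * `"auto"` (default): `"per-condition"` when every condition has >= 2
#'   replicates, else `"blind"`.
#'
#' @param dataset A [merip_dataset()].
#' @param factors A [size_factors()] result.
#' @param mode One of `"auto"`, `"per-condition"`, `"pooled"`, `"blind"`.
#' @param smooth Nearest-neighbour span of the loess engine, in (0, 1\];
#'   default 0.7.
#' @param engine `"gamma"` (default) or `"loess"`.
#' @param estimates Optional precomputed estimate list (internal reuse).
#' @return An object of class `qnb_variance_model` carrying, per sample type
#'   and fitting group, the fitted surface, the group composition needed to
#'   recompute the bias term, and diagnostics (group sizes, engine used).
#' @examples
#' sim <- simulate_merip(n_features = 500, seed = 1)
#' sf <- size_factors(sim$dataset)
#' fit_variance_model(sim$dataset, sf, mode = "auto")
#' @export
fit_variance_model <- function(dataset, factors,
                               mode = c("auto", "per-condition", "pooled", "blind"),
                               smooth = 0.7, engine = c("gamma", "loess"),
                               estimates = NULL) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  stopifnot(smooth > 0, smooth <= 1)
  est <- estimates %||% merip_estimates(dataset, factors)
  conds <- est$conditions
  idx <- condition_index(dataset)
  reps <- lengths(idx)

  resolved <- mode
  if (mode == "auto") {
    resolved <- if (all(reps >= 2L)) "per-condition" else "blind"
  }
  replicated <- conds[reps >= 2L]
  if (resolved == "per-condition" && length(replicated) < length(conds)) {
    abort("mode \"per-condition\" requires >= 2 replicates in every condition; use \"blind\" or \"pooled\".")
  }
  if (resolved == "pooled" && !length(replicated)) {
    abort("mode \"pooled\" requires at least one condition with >= 2 replicates; use \"blind\".")
  }

  # A fitting group: columns used, the per-feature (p, e) at which w was
  # computed, and everything needed to re-evaluate the bias term later.
  make_group <- function(columns, p_fit, e_fit) {
    list(columns = columns, p_fit = p_fit, e_fit = e_fit,
         k = length(columns))
  }
  groups <- switch(resolved,
    "per-condition" = lapply(setNames(conds, conds), function(l) {
      make_group(idx[[l]], est$p_hat[, l], est$e_hat[, l])
    }),
    "pooled" = lapply(setNames(replicated, replicated), function(l) {
      make_group(idx[[l]], est$p_hat[, l], est$e_hat[, l])
    }),
    "blind" = {
      e_blind <- ifelse(est$q_hat > 0,
                        rowSums(norm_counts(dataset, factors, "ip") +
                                  norm_counts(dataset, factors, "input")) /
                          (length(dataset$conditions) * est$q_hat),
                        NA_real_)
      list(blind = make_group(seq_along(dataset$conditions),
                              est$p_hat_O, e_blind))
    }
  )

  # Map each condition to the fitting group evaluated for it.
  map <- switch(resolved,
    "per-condition" = setNames(conds, conds),
    "pooled" = setNames(rep("pooled", length(conds)), conds),
    "blind" = setNames(rep("blind", length(conds)), conds)
  )

  fit_type <- function(type) {
    fit_groups <- lapply(groups, function(g) {
      v <- common_scale_variance(dataset, factors, g$e_fit,
                                 sample_type = type, columns = g$columns)
      list(group = g, w_hat = v$w_hat, p = g$p_fit)
    })
    if (resolved == "pooled") {
      pts <- list(
        p = unlist(lapply(fit_groups, `[[`, "p"), use.names = FALSE),
        q = rep(est$q_hat, length(fit_groups)),
        w = unlist(lapply(fit_groups, `[[`, "w_hat"), use.names = FALSE)
      )
      surf <- fit_surface(pts$p, pts$q, pts$w, engine, smooth)
      out <- lapply(fit_groups, function(fg) {
        list(group = fg$group, surface = surf, w_hat = fg$w_hat)
      })
      # one shared surface, but group metadata per replicated condition; the
      # bias term uses the union of replicated columns weighted per group --
      # evaluation picks the first group's composition for each condition via
      # `map`, so store a combined pooled group too.
      comb <- list(
        columns = unlist(lapply(groups, `[[`, "columns"), use.names = FALSE),
        k = sum(vapply(groups, `[[`, integer(1), "k"))
      )
      out$pooled <- list(group = NULL, surface = surf,
                         subgroups = fit_groups, combined = comb)
      out
    } else {
      lapply(fit_groups, function(fg) {
        list(group = fg$group,
             surface = fit_surface(fg$p, est$q_hat, fg$w_hat, engine, smooth),
             w_hat = fg$w_hat)
      })
    }
  }

  model <- structure(
    list(
      mode = mode, resolved_mode = resolved, map = map,
      smooth = smooth,
      ip = fit_type("ip"), input = fit_type("input"),
      estimates = est, factors = factors,
      group_sizes = reps
    ),
    class = "qnb_variance_model"
  )
  model
}

# Smooth w over (p, log q). Returns a closure predict(p, q) >= 0 with
# clamped covariates, plus metadata.
fit_surface <- function(p, q, w, engine, smooth, eps = 1e-8, min_features = 30L) {
  ok <- is.finite(p) & is.finite(q) & is.finite(w) & q > 0
  if (sum(ok) < min_features) {
    abort(sprintf(
      "insufficient features for variance smoothing (%d usable, need >= %d).",
      sum(ok), min_features
    ))
  }
  dat <- data.frame(p = p[ok], lq = log(q[ok]), w = pmax(w[ok], eps))
  rng_p <- range(dat$p)
  rng_lq <- range(dat$lq)

  used <- engine
  fit <- NULL
  if (engine == "gamma") {
    kp <- max(3L, min(5L, floor(sqrt(nrow(dat)) / 2)))
    kq <- max(3L, min(8L, floor(sqrt(nrow(dat)))))
    fit <- tryCatch(
      mgcv::gam(w ~ te(p, lq, k = c(kp, kq)),
                family = stats::Gamma(link = "log"),
                data = dat, method = "REML"),
      error = function(e) NULL
    )
    if (is.null(fit)) used <- "loess"
  }
  if (used == "loess") {
    fit <- loess(log(w) ~ p + lq, data = dat, span = smooth,
                 degree = 1L, family = "symmetric",
                 control = stats::loess.control(surface = "direct"))
  }

  predict_fn <- function(p_new, q_new) {
    nd <- data.frame(
      p = pmin(pmax(p_new, rng_p[1L]), rng_p[2L]),
      lq = pmin(pmax(log(pmax(q_new, .Machine$double.xmin)),
                     rng_lq[1L]), rng_lq[2L])
    )
    out <- rep(NA_real_, nrow(nd))
    ok_new <- is.finite(nd$p) & is.finite(nd$lq)
    if (any(ok_new)) {
      pred <- if (used == "gamma") {
        as.numeric(predict(fit, newdata = nd[ok_new, , drop = FALSE],
                           type = "response"))
      } else {
        exp(as.numeric(predict(fit, newdata = nd[ok_new, , drop = FALSE])))
      }
      out[ok_new] <- pmax(pred, 0)
    }
    out
  }
  list(predict = predict_fn, engine = used, n = nrow(dat),
       range_p = rng_p, range_lq = rng_lq)
}

#' Evaluate the raw-variance estimate for a condition
#'
#' Evaluates the smoothed common-scale variance surface at a given methylation
#' rate and the feature abundances, subtracts the shot-noise bias term
#' (recomputed at that rate with the fitting group's composition), and clamps
#' the result at zero: before clamping the unbiased estimator may be negative,
#' but a variance below shot noise is not meaningful at evaluation time.
#'
#' @param model A fitted [fit_variance_model()].
#' @param condition Condition label whose surface mapping to use.
#' @param sample_type `"ip"` or `"input"`.
#' @param at_rate Methylation rate(s) at which to evaluate: the per-condition
#'   estimate for description, the pooled null rate for testing. Recycled to
#'   the number of features evaluated.
#' @param features Feature indices to evaluate (default: all features the
#'   model was fitted to).
#' @return Numeric vector of raw-variance estimates (>= 0, `NA` where
#'   undefined).
#' @export
raw_variance <- function(model, condition, sample_type = c("ip", "input"),
                         at_rate, features = NULL) {
  stopifnot(inherits(model, "qnb_variance_model"))
  sample_type <- match.arg(sample_type)
  est <- model$estimates
  features <- features %||% seq_along(est$q_hat)
  q_hat <- est$q_hat[features]
  at_rate <- rep_len(at_rate, length(features))

  gname <- model$map[[as.character(condition)]]
  entry <- model[[sample_type]][[gname]]
  w_pred <- entry$surface$predict(at_rate, q_hat)

  z <- eval_bias(model, entry, sample_type, at_rate, features)
  v <- pmax(w_pred - z, 0)
  v[!is.finite(v)] <- NA_real_
  v
}

# Bias term for a fitting-group entry; for the pooled shared surface the
# subgroup bias terms are averaged (each subgroup's w contributed equally).
eval_bias <- function(model, entry, sample_type, at_rate, features) {
  f <- model$factors[[sample_type]]
  q_hat <- model$estimates$q_hat[features]
  rate <- if (sample_type == "ip") at_rate else 1 - at_rate
  one <- function(g) {
    q_hat * rate * sum(1 / f[g$columns]) / (g$k * g$e_fit[features])
  }
  if (!is.null(entry$group)) {
    one(entry$group)
  } else {
    zs <- vapply(entry$subgroups, function(fg) one(fg$group),
                 numeric(length(features)))
    rowMeans(matrix(zs, nrow = length(features)))
  }
}

#' @export
print.qnb_variance_model <- function(x, ...) {
  eng <- unique(c(
    vapply(x$ip, function(e) e$surface$engine, character(1)),
    vapply(x$input, function(e) e$surface$engine, character(1))
  ))
  cat(sprintf(
    "<qnb_variance_model> mode = \"%s\" (resolved: \"%s\"), engine: %s\n",
    x$mode, x$resolved_mode, paste(eng, collapse = "/")
  ))
  cat(sprintf("  replicates per condition: %s\n",
              paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

#' Per-feature variance diagnostics table
#'
#' Exports the scatter the surfaces were fitted to: per feature and fitting
#' group, the rate and abundance covariates, the common-scale variance
#' `w_hat`, the bias term `z` at the fitted rate, and the clamped raw-variance
#' estimate.
#'
#' @param x A `qnb_variance_model`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `sample_type`, `group`, `p_hat`,
#'   `q_hat`, `w_hat`, `z`, `v_hat`.
#' @method tidy qnb_variance_model
#' @export
tidy.qnb_variance_model <- function(x, ...) {
  est <- x$estimates
  rows <- list()
  for (type in c("ip", "input")) {
    for (gname in names(x[[type]])) {
      entry <- x[[type]][[gname]]
      if (is.null(entry$group)) next # pooled shared-surface bookkeeping entry
      g <- entry$group
      z <- eval_bias(x, entry, type, g$p_fit, seq_along(est$q_hat))
      w_pred <- entry$surface$predict(g$p_fit, est$q_hat)
      rows[[paste(type, gname)]] <- tibble::tibble(
        feature = seq_along(est$q_hat),
        sample_type = type, group = gname,
        p_hat = g$p_fit, q_hat = est$q_hat,
        w_hat = entry$w_hat, z = z,
        v_hat = pmax(w_pred - z, 0)
      )
    }
  }
  dplyr::bind_rows(rows)
}
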