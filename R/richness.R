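#' Incidence frequency counts
#'
#' Reduces an incidence matrix to the sufficient statistics of sample-based
#' richness estimation: the number of sampling units `T`, the per-GCF
#' occupancy counts `Y` (in how many units each family occurs), the observed
#' richness `S_obs`, and the unique/duplicate counts `Q1` (families seen in
#' exactly one unit) and `Q2` (exactly two).
#'
#' @param x an `incidence_matrix`.
#' @return an `incidence_freqs` list with fields `T`, `Y`, `S_obs`, `Q1`, `Q2`.
#' @export
incidence_freqs <- function(x) {
  stopifnot(inherits(x, "incidence_matrix"))
  Y <- as.integer(colSums(x))
  new_incidence_freqs(nrow(x), Y)
}

new_incidence_freqs <- function(T, Y) {
  T <- stopifnot_count(T, "T", min = 1)
  Y <- as.integer(Y)
  if (length(Y) < 1L || any(Y < 1L) || any(Y > T)) {
    stop("occupancy counts must lie in 1..T and S_obs must be >= 1",
         call. = FALSE)
  }
  structure(
    list(T = T, Y = Y, S_obs = length(Y),
         Q1 = sum(Y == 1L), Q2 = sum(Y == 2L)),
    class = "incidence_freqs"
  )
}

#' @export
print.incidence_freqs <- function(x, ...) {
  cat(sprintf("Incidence frequencies: T = %d units, S_obs = %d, Q1 = %d, Q2 = %d\n",
              x$T, x$S_obs, x$Q1, x$Q2))
  invisible(x)
}

as_freqs <- function(x) {
  if (inherits(x, "incidence_freqs")) x
  else if (inherits(x, "incidence_matrix")) incidence_freqs(x)
  else stop("expected an incidence_matrix or incidence_freqs object",
            call. = FALSE)
}

#' Sample-based rarefaction
#'
#' Expected GCF richness in a random subsample of `t` of the `T` observed
#' sampling units: the exact hypergeometric expectation
#' \deqn{E[S(t)] = S_{obs} - \sum_i \binom{T - Y_i}{t} / \binom{T}{t},}
#' evaluated in log space so that large `T` does not overflow.  Deterministic;
#' no resampling is involved.
#'
#' @param freqs an `incidence_freqs` object (or an `incidence_matrix`).
#' @param t integer vector of subsample sizes, each in 1..T.
#' @return numeric vector of expected richness values, one per `t`.
#' @export
rarefy_incidence <- function(freqs, t) {
  f <- as_freqs(freqs)
  if (length(t) < 1L || any(is.na(t)) || any(t < 1) || any(t > f$T) ||
      any(t != floor(t))) {
    stop("'t' must be integer(s) in 1..T (use extrapolate_richness beyond T)",
         call. = FALSE)
  }
  vapply(as.integer(t), function(ti) {
    f$S_obs - sum(exp(lchoose(f$T - f$Y, ti) - lchoose(f$T, ti)))
  }, numeric(1))
}

#' Chao2 undetected-richness estimate
#'
#' Nonparametric lower-bound estimator of total GCF richness from incidence
#' frequencies, with the small-sample correction:
#' \deqn{\hat{Q}_0 = \frac{T-1}{T} \frac{Q_1^2}{2 Q_2}} when `Q2 > 0`, and the
#' bias-corrected form \deqn{\hat{Q}_0 = \frac{T-1}{T} \frac{Q_1 (Q_1-1)}{2}}
#' when `Q2 = 0`.  The estimate of total richness is `S_est = S_obs + Q0_hat`.
#'
#' @param freqs an `incidence_freqs` object (or an `incidence_matrix`).
#' @return a `richness_estimate` list with fields `S_obs`, `Q0_hat`, `S_est`,
#'   and (NA until filled by a bootstrap) `se`, `ci_low`, `ci_high`.
#' @export
chao2 <- function(freqs) {
  f <- as_freqs(freqs)
  if (f$T < 2L) stop("Chao2 requires at least 2 sampling units", call. = FALSE)
  k <- (f$T - 1) / f$T
  Q0 <- if (f$Q2 > 0L) {
    k * f$Q1^2 / (2 * f$Q2)
  } else {
    k * f$Q1 * (f$Q1 - 1) / 2
  }
  structure(
    list(S_obs = f$S_obs, Q0_hat = Q0, S_est = f$S_obs + Q0,
         se = NA_real_, ci_low = NA_real_, ci_high = NA_real_),
    class = "richness_estimate"
  )
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("Richness estimate: S_obs = %d, undetected Q0 = %.1f, S_est = %.1f\n",
              x$S_obs, x$Q0_hat, x$S_est))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  95%% CI: [%.1f, %.1f]\n", x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Extrapolated richness beyond the observed sample
#'
#' Expected GCF richness at `T + t_star` sampling units, using the standard
#' incidence-based extrapolation anchored on the Chao2 undetected-richness
#' estimate:
#' \deqn{S(T + t^*) = S_{obs} + \hat{Q}_0
#'   \left[1 - \left(1 - \frac{Q_1}{Q_1 + T \hat{Q}_0}\right)^{t^*}\right].}
#' Continuous with rarefaction at `t_star = 0` and bounded above by
#' `S_obs + Q0_hat`.  When `Q1 = 0` the curve is flat at `S_obs`.
#'
#' @param freqs an `incidence_freqs` object (or an `incidence_matrix`).
#' @param t_star non-negative number(s) of additional sampling units.
#' @param estimate optionally a precomputed [chao2()] estimate.
#' @return numeric vector of expected richness values, one per `t_star`.
#' @export
extrapolate_richness <- function(freqs, t_star, estimate = NULL) {
  f <- as_freqs(freqs)
  if (any(is.na(t_star)) || any(t_star < 0)) {
    stop("'t_star' must be non-negative", call. = FALSE)
  }
  est <- estimate %||% chao2(f)
  Q0 <- est$Q0_hat
  if (f$Q1 == 0L || Q0 <= 0) {
    return(rep(as.numeric(f$S_obs), length(t_star)))
  }
  rate <- 1 - f$Q1 / (f$Q1 + f$T * Q0)
  f$S_obs + Q0 * (1 - rate^t_star)
}

#' Fit a rarefaction/extrapolation curve with bootstrap confidence intervals
#'
#' The package's central estimator.  From a species-by-GCF incidence matrix it
#' computes (i) the interpolated (rarefied) expected richness for t <= T,
#' (ii) the Chao2 estimate of undetected richness, (iii) the extrapolated
#' expected richness for t > T, and (iv) pointwise 95% percentile-bootstrap
#' confidence bands obtained by resampling the T sampling units with
#' replacement and recomputing the whole curve for each replicate.
#'
#' @param x an `incidence_matrix`.
#' @param t_grid sorted positive integer vector of sample sizes at which to
#'   evaluate the curve.  Default: every size from 1 to `t_max`.
#' @param t_max largest sample size when `t_grid` is NULL (default `3 * T`,
#'   a conventional limit beyond which incidence extrapolation is unreliable).
#' @param n_boot number of bootstrap replicates (default 200).
#' @param seed integer seed; required because the confidence bands are
#'   stochastic.  Identical inputs and seed give identical curves.
#' @param conf confidence level for the percentile interval (default 0.95).
#' @return a `gcf_rarefaction` object: list with `freqs`, `estimate` (Chao2
#'   with bootstrap CI attached), `curve` (data.frame `t`, `richness`,
#'   `ci_low`, `ci_high`, `regime`), `n_boot`, `seed`, `conf`, `call`.
#' @examples
#' sim <- gen_incidence(incidence_model(n_units = 20, s_true = 80, seed = 7))
#' fit <- gcf_rarefaction(sim$matrix, n_boot = 50, seed = 1)
#' fit
#' predict(fit, t = c(10, 20, 40))
#' @export
gcf_rarefaction <- function(x, t_grid = NULL, t_max = NULL, n_boot = 200,
                            seed, conf = 0.95) {
  stopifnot(inherits(x, "incidence_matrix"))
  n_boot <- stopifnot_count(n_boot, "n_boot", min = 1)
  stopifnot_prob(conf, "conf")
  f <- incidence_freqs(x)
  if (is.null(t_grid)) {
    t_max <- t_max %||% (3L * f$T)
    t_grid <- seq_len(t_max)
  }
  t_grid <- as.integer(t_grid)
  if (is.unsorted(t_grid, strictly = TRUE) || any(t_grid < 1L)) {
    stop("'t_grid' must be strictly increasing positive integers",
         call. = FALSE)
  }
  est <- chao2(f)
  point <- curve_at(f, t_grid, est)

  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(f$T, f$T, replace = TRUE)
      Yb <- colSums(x[idx, , drop = FALSE])
      fb <- new_incidence_freqs(f$T, Yb[Yb > 0L])
      eb <- chao2(fb)
      c(curve_at(fb, t_grid, eb), eb$S_est)
    }, numeric(length(t_grid) + 1L))
  })
  boot <- matrix(boot, nrow = length(t_grid) + 1L)
  s_est_boot <- boot[nrow(boot), ]
  boot <- boot[-nrow(boot), , drop = FALSE]
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 7)
  ci <- matrix(ci, nrow = 2L)
  est$se <- stats::sd(s_est_boot)
  est_ci <- stats::quantile(s_est_boot, c(alpha, 1 - alpha), names = FALSE)
  est$ci_low <- min(est_ci[1], est$S_est)
  est$ci_high <- max(est_ci[2], est$S_est)

  curve <- data.frame(
    t = t_grid,
    richness = point,
    ci_low = ci[1, ],
    ci_high = ci[2, ],
    regime = ifelse(t_grid < f$T, "interpolated",
                    ifelse(t_grid == f$T, "observed", "extrapolated")),
    stringsAsFactors = FALSE
  )
  structure(
    list(freqs = f, estimate = est, curve = curve, n_boot = n_boot,
         seed = seed, conf = conf, call = match.call()),
    class = "gcf_rarefaction"
  )
}

# Point curve on a fixed grid: rarefied below T, observed at T, extrapolated
# above (sizes beyond T are measured as t_star = t - T extra units).
curve_at <- function(f, t_grid, est) {
  out <- numeric(length(t_grid))
  lo <- t_grid <= f$T
  if (any(lo)) out[lo] <- rarefy_incidence(f, t_grid[lo])
  if (any(!lo)) {
    out[!lo] <- extrapolate_richness(f, t_grid[!lo] - f$T, estimate = est)
  }
  out
}

#' @export
print.gcf_rarefaction <- function(x, ...) {
  cat("GCF rarefaction/extrapolation fit\n")
  cat(sprintf("  sampling units: %d   observed GCFs: %d   (Q1 = %d, Q2 = %d)\n",
              x$freqs$T, x$freqs$S_obs, x$freqs$Q1, x$freqs$Q2))
  cat(sprintf("  Chao2 total richness: %.0f   95%% CI [%.0f, %.0f]   (%d bootstrap reps)\n",
              x$estimate$S_est, x$estimate$ci_low, x$estimate$ci_high,
              x$n_boot))
  cat(sprintf("  curve evaluated at %d sizes, t = %d..%d\n",
              nrow(x$curve), min(x$curve$t), max(x$curve$t)))
  invisible(x)
}

#' @export
summary.gcf_rarefaction <- function(object, ...) {
  print(object)
  cat("\nCurve endpoints:\n")
  cv <- object$curve
  show <- cv[cv$t %in% c(min(cv$t), object$freqs$T, max(cv$t)), ]
  print(show, row.names = FALSE, digits = 4)
  invisible(object)
}

#' Predict expected richness at new sample sizes
#'
#' Evaluates the fitted curve analytically at arbitrary sizes (they need not
#' belong to the fitted grid): rarefaction for `t <= T`, extrapolation beyond.
#'
#' @param object a `gcf_rarefaction` fit.
#' @param t positive integer vector of sample sizes.
#' @param ... unused.
#' @return numeric vector of expected richness values.
#' @export
predict.gcf_rarefaction <- function(object, t, ...) {
  curve_at(object$freqs, as.integer(t), object$estimate)
}

#' Plot a rarefaction/extrapolation curve
#'
#' Solid line: interpolated richness up to the observed sample size (marked
#' with a point); dashed line: extrapolation; shaded band: bootstrap
#' confidence interval.
#'
#' @param x a `gcf_rarefaction` fit.
#' @param col curve colour.
#' @param ... passed to [plot()].
#' @export
plot.gcf_rarefaction <- function(x, col = "purple4", ...) {
  cv <- x$curve
  graphics::plot(cv$t, cv$richness, type = "n",
                 xlab = "Sampling units", ylab = "GCF richness",
                 ylim = range(cv$ci_low, cv$ci_high), ...)
  graphics::polygon(c(cv$t, rev(cv$t)), c(cv$ci_low, rev(cv$ci_high)),
                    col = grDevices::adjustcolor(col, alpha.f = 0.2),
                    border = NA)
  lo <- cv$t <= x$freqs$T
  graphics::lines(cv$t[lo], cv$richness[lo], col = col, lwd = 2)
  graphics::lines(cv$t[!lo], cv$richness[!lo], col = col, lwd = 2, lty = 2)
  graphics::points(x$freqs$T, x$freqs$S_obs, pch = 19, col = col)
  invisible(x)
}

#' Richness estimate at a target number of sampling units
#'
#' Extrapolates observed incidence to `n_target >= T` units and attaches a
#' percentile-bootstrap confidence interval (units resampled with
#' replacement, the extrapolation recomputed per replicate).
#'
#' @param x an `incidence_matrix`.
#' @param n_target target number of sampling units (>= T; for fewer units use
#'   [rarefy_incidence()]).
#' @param n_boot bootstrap replicates (default 200).
#' @param seed integer seed for the bootstrap.
#' @return a `richness_estimate` whose `S_est` is the expected richness at
#'   `n_target`, with `se`, `ci_low`, `ci_high` filled in.
#' @export
richness_at <- function(x, n_target, n_boot = 200, seed) {
  stopifnot(inherits(x, "incidence_matrix"))
  f <- incidence_freqs(x)
  n_target <- stopifnot_count(n_target, "n_target", min = 1)
  if (n_target < f$T) {
    stop("n_target < T: use rarefy_incidence() for subsampled richness",
         call. = FALSE)
  }
  n_boot <- stopifnot_count(n_boot, "n_boot", min = 1)
  est <- chao2(f)
  point <- extrapolate_richness(f, n_target - f$T, estimate = est)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(f$T, f$T, replace = TRUE)
      Yb <- colSums(x[idx, , drop = FALSE])
      fb <- new_incidence_freqs(f$T, Yb[Yb > 0L])
      extrapolate_richness(fb, n_target - fb$T, estimate = chao2(fb))
    }, numeric(1))
  })
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  structure(
    list(S_obs = f$S_obs, Q0_hat = est$Q0_hat, S_est = point,
         se = stats::sd(reps),
         ci_low = min(ci[1], point), ci_high = max(ci[2], point)),
    class = "richness_estimate"
  )
}

#' Write a fitted curve as TSV
#'
#' @param fit a `gcf_rarefaction` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(fit, path) {
  stopifnot(inherits(fit, "gcf_rarefaction"))
  utils::write.table(fit$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
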