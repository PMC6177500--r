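#' Spearman rank correlation between two maps
#'
#' Pearson correlation of mid-ranks (average ranks for ties), computed over
#' pairwise-complete entries.  Undefined correlations (fewer than 3
#' complete pairs, or zero rank variance in either vector) are returned as
#' `NA` with a `reason` attribute rather than an error, so degenerate
#' vertices/subjects propagate as missing.
#'
#' @param a,b numeric vectors of equal length (`NA` allowed).
#' @return Spearman's rho, or `NA` with a `reason` attribute.
#' @export
spearman_rho <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("vectors must have equal length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L)
    return(structure(NA_real_, reason = "fewer than 3 complete pairs"))
  ra <- rank(a[ok]); rb <- rank(b[ok])
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    return(structure(NA_real_, reason = "zero variance in ranked vector"))
  stats::cor(ra, rb)
}

#' Fisher z-test on per-subject correlations
#'
#' Applies the Fisher z-transformation z = atanh(rho) to normalise the
#' per-subject correlation coefficients and performs a two-sided one-sample
#' Student's t-test of the z values against 0.  The reported mean and SD
#' are of the raw rho values (matching the conventional "rho = -0.24 +-
#' 0.18" reporting style); the p value comes from the z scale.
#'
#' @param rhos numeric vector of per-subject correlations (`NA` dropped;
#'   values with |rho| = 1 are clipped with a warning).
#' @return list with `mean_rho`, `sd_rho`, `p_value`, `t`, `df`, `n`.
#' @export
fisher_z_test <- function(rhos) {
  rhos <- as.numeric(rhos)
  rhos <- rhos[!is.na(rhos)]
  if (length(rhos) < 2L) stop("need at least 2 finite correlations")
  if (any(abs(rhos) >= 1)) {
    warning("correlations with |rho| >= 1 clipped for the z-transform")
    rhos <- pmin(pmax(rhos, -(1 - 1e-12)), 1 - 1e-12)
  }
  z <- atanh(rhos)
  if (stats::sd(z) == 0) {
    p <- if (all(z == 0)) 1 else 0
    return(list(mean_rho = mean(rhos), sd_rho = stats::sd(rhos),
                p_value = p, t = if (all(z == 0)) 0 else Inf,
                df = length(z) - 1L, n = length(z)))
  }
  tt <- stats::t.test(z, mu = 0)
  list(mean_rho = mean(rhos), sd_rho = stats::sd(rhos),
       p_value = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), n = length(z))
}

#' Draw bootstrap subject multisets
#'
#' One call defines the resampling plan shared by
#' [bootstrap_correlations()] and [fit_bootstrap_regressions()]: `B` rows
#' of `n_subjects` subject indices drawn with replacement.
#'
#' @param n_subjects cohort size.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @return B x n_subjects integer matrix.
#' @export
bootstrap_multisets <- function(n_subjects, B, seed) {
  stopifnot(n_subjects >= 2L, B >= 1L)
  set.seed(as.integer(seed))
  matrix(sample.int(n_subjects, B * n_subjects, replace = TRUE),
         nrow = B, ncol = n_subjects)
}

MAP_PAIRS <- list(wt_wss = c("wt", "wss"), wt_d = c("wt", "d"),
                  wss_d = c("wss", "d"))

#' Bootstrap correlations between cohort-averaged maps
#'
#' For each replicate, subjects are drawn with replacement, each quantity is
#' averaged over the multiset on the shared geometry, and Spearman's rho is
#' computed between the averaged maps over the complete-vertex analysis
#' set.  A pair is significant when the percentile 95% confidence interval
#' (2.5th-97.5th) of the B rho values does not contain 0.
#'
#' @param set a [build_cohort_maps()] result.
#' @param pairs subset of `"wt_wss"`, `"wt_d"`, `"wss_d"`.
#' @param B bootstrap size (study default 1000).
#' @param seed integer seed (replicates are identical for a fixed seed).
#' @param multisets optional pre-drawn [bootstrap_multisets()] matrix (to
#'   share the resampling plan with the bootstrap regressions); overrides
#'   `B` and `seed`.
#' @return named list of `bootstrap_result` objects: `pair`, `B`,
#'   `rho_per_bootstrap`, `mean_rho`, `ci95`, `significant`, `seed`.
#' @export
bootstrap_correlations <- function(set, pairs = c("wt_wss", "wt_d", "wss_d"),
                                   B = 1000L, seed = 1L, multisets = NULL) {
  pairs <- match.arg(pairs, names(MAP_PAIRS), several.ok = TRUE)
  n <- nrow(set$matrices[[1L]])
  if (is.null(multisets)) multisets <- bootstrap_multisets(n, B, seed)
  B <- nrow(multisets)
  cv <- set$complete_vertices
  if (!any(cv)) stop("no atlas vertex is covered by all subjects")
  quantities <- unique(unlist(MAP_PAIRS[pairs]))
  avg <- function(q, ms) average_maps(set, ms, q)[cv]
  rho <- matrix(NA_real_, B, length(pairs), dimnames = list(NULL, pairs))
  for (b in seq_len(B)) {
    ms <- multisets[b, ]
    am <- lapply(quantities, avg, ms = ms)
    names(am) <- quantities
    for (p in pairs) {
      qq <- MAP_PAIRS[[p]]
      rho[b, p] <- spearman_rho(am[[qq[1]]], am[[qq[2]]])
    }
  }
  out <- lapply(pairs, function(p) {
    r <- unname(rho[, p])
    ci <- unname(stats::quantile(r, c(0.025, 0.975), na.rm = TRUE))
    structure(list(pair = p, B = B, rho_per_bootstrap = r,
                   mean_rho = mean(r, na.rm = TRUE), ci95 = ci,
                   significant = ci[1] > 0 || ci[2] < 0, seed = seed),
              class = "bootstrap_result")
  })
  names(out) <- pairs
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result %s: mean rho %.3f [%.3f, %.3f] over B=%d%s\n",
              x$pair, x$mean_rho, x$ci95[1], x$ci95[2], x$B,
              if (x$significant) " *" else " (ns)"))
  invisible(x)
}

#' Lack-of-fit check for a simple linear relationship
#'
#' Compares the straight-line fit of `y` on `x` against a decile-binned
#' means model with an F-test: a significant F (p < alpha) means the
#' binned means explain systematically more than the line, i.e. the linear
#' model is inadequate.
#'
#' @param x,y numeric vectors.
#' @param n_bins number of quantile bins (default deciles).
#' @param alpha significance level.
#' @return list with `adequate` (logical), `statistic`, `p_value`, `df`;
#'   `adequate = NA` with a reason when there are too few distinct bins.
#' @export
linearity_check <- function(x, y, n_bins = 10L, alpha = 0.05) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  brks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(brks) < 4L)
    return(list(adequate = NA, statistic = NA_real_, p_value = NA_real_,
                reason = "too few distinct x deciles"))
  bin <- cut(x, brks, include.lowest = TRUE)
  k <- nlevels(droplevels(bin))
  n <- length(y)
  fit_lin <- stats::lm.fit(cbind(1, x), y)
  rss_lin <- sum(fit_lin$residuals^2)
  mu <- tapply(y, bin, mean)
  rss_bin <- sum((y - mu[bin])^2)
  df1 <- k - 2L; df2 <- n - k
  if (df1 < 1L || df2 < 1L)
    return(list(adequate = NA, statistic = NA_real_, p_value = NA_real_,
                reason = "insufficient degrees of freedom"))
  if (rss_bin <= .Machine$double.eps * max(1, sum(y^2)))
    return(list(adequate = rss_lin <= .Machine$double.eps * max(1, sum(y^2)),
                statistic = NA_real_, p_value = NA_real_, df = c(df1, df2)))
  f <- ((rss_lin - rss_bin) / df1) / (rss_bin / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(adequate = p >= alpha, statistic = f, p_value = p, df = c(df1, df2))
}

#' Per-subject correlations with Fisher z-test summary
#'
#' Convenience wrapper computing, for each subject, Spearman's rho between
#' two native-mesh maps, and summarising across the cohort with
#' [fisher_z_test()].
#'
#' @param maps_a,maps_b lists of per-subject [scalar_map()]s (aligned).
#' @return list with `per_subject_rho`, `mean_rho`, `sd_rho`, `p_value`.
#' @export
individual_correlations <- function(maps_a, maps_b) {
  stopifnot(length(maps_a) == length(maps_b))
  rhos <- vapply(seq_along(maps_a),
                 function(i) as.numeric(spearman_rho(maps_a[[i]], maps_b[[i]])),
                 numeric(1))
  fz <- fisher_z_test(rhos)
  list(per_subject_rho = rhos, mean_rho = fz$mean_rho, sd_rho = fz$sd_rho,
       p_value = fz$p_value)
}
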