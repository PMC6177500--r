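WT_TERMS <- c("wss", "d", "wss_d")

wt_design <- function(wss, d, terms) {
  cols <- list(`(Intercept)` = rep(1, length(wss)))
  if ("wss" %in% terms) cols$wss <- wss
  if ("d" %in% terms) cols$d <- d
  if ("wss_d" %in% terms) cols$wss_d <- wss * d
  do.call(cbind, cols)
}

#' Fit the wall-thickness regression model
#'
#' Ordinary least squares with intercept for the vertex-wise model
#' WT = b0 + b1*WSS + b2*D + b3*WSS*D + eps (the full model), or any
#' reduced model containing only WSS, only D or only the interaction term.
#'
#' @param wt,wss,d aligned per-vertex value vectors (or [scalar_map()]s);
#'   vertices with any missing value are dropped.
#' @param terms character subset of `c("wss", "d", "wss_d")`; the default
#'   is the full model.
#' @param source label recorded on the fit (e.g. a subject id or
#'   `"bootstrap"`).
#' @return an object of class `wt_fit`: `beta` (named coefficients),
#'   `residuals` (full-length vertex vector, `NA` where input was missing),
#'   `fitted`, `r_squared`, `terms`, `n`, `source`.
#' @export
fit_wt_regression <- function(wt, wss, d, terms = WT_TERMS,
                              source = "individual") {
  terms <- match.arg(terms, WT_TERMS, several.ok = TRUE)
  wt <- as.numeric(wt); wss <- as.numeric(wss); d <- as.numeric(d)
  n_all <- length(wt)
  if (length(wss) != n_all || length(d) != n_all)
    stop("wt, wss and d must be aligned vectors of equal length")
  ok <- !is.na(wt) & !is.na(wss) & !is.na(d)
  if (sum(ok) < length(terms) + 2L)
    stop("need at least ", length(terms) + 2L, " complete vertices")
  X <- wt_design(wss[ok], d[ok], terms)
  y <- wt[ok]
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    bad <- colnames(X)[is.na(fit$coefficients)]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  res <- rep(NA_real_, n_all); res[ok] <- fit$residuals
  fitted <- rep(NA_real_, n_all); fitted[ok] <- fit$fitted.values
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else NA_real_
  structure(list(beta = fit$coefficients, residuals = res, fitted = fitted,
                 r_squared = r2, terms = terms, n = sum(ok),
                 sigma = sqrt(sum(fit$residuals^2) / max(1, sum(ok) - ncol(X))),
                 source = source,
                 data = list(wt = wt, wss = wss, d = d)),
            class = "wt_fit")
}

#' @export
print.wt_fit <- function(x, digits = 4, ...) {
  cat("wt_fit (", paste(x$terms, collapse = " + "), ") [", x$source, "]\n", sep = "")
  print(round(x$beta, digits))
  cat(sprintf("R-squared %.3f on %d vertices\n", x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.wt_fit <- function(object, ...) object$beta

#' @export
residuals.wt_fit <- function(object, ...) object$residuals

#' @export
summary.wt_fit <- function(object, ...) {
  out <- list(beta = object$beta, r_squared = object$r_squared,
              n = object$n, sigma = object$sigma, terms = object$terms,
              source = object$source,
              residual_range = range(object$residuals, na.rm = TRUE))
  class(out) <- "summary.wt_fit"
  out
}

#' @export
print.summary.wt_fit <- function(x, ...) {
  cat("Wall-thickness regression (", paste(x$terms, collapse = " + "),
      ") [", x$source, "]\n", sep = "")
  print(x$beta)
  cat(sprintf("R-squared %.4f, residual SD %.4f mm, n = %d\n",
              x$r_squared, x$sigma, x$n))
  cat(sprintf("residual range [%.3f, %.3f] mm\n",
              x$residual_range[1], x$residual_range[2]))
  invisible(x)
}

#' @export
predict.wt_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- list(wss = object$data$wss, d = object$data$d)
  predict_wt_values(newdata$wss, newdata$d, object$beta, object$terms)
}

#' @export
simulate.wt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  out <- replicate(nsim, mu + stats::rnorm(length(mu), 0, object$sigma),
                   simplify = FALSE)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.wt_fit <- function(x, ...) {
  graphics::plot(x$fitted, x$residuals, xlab = "fitted WT (mm)",
                 ylab = "residual (mm)",
                 main = paste("wt_fit:", paste(x$terms, collapse = " + ")), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

predict_wt_values <- function(wss, d, beta, terms) {
  wss <- as.numeric(wss); d <- as.numeric(d)
  X <- wt_design(wss, d, terms)
  keep <- intersect(colnames(X), names(beta))
  if (!setequal(keep, names(beta)))
    stop("beta names do not match the requested terms")
  as.numeric(X[, keep, drop = FALSE] %*% beta[keep])
}

#' Predict an individual 3D wall-thickness map
#'
#' Applies regression coefficients (individual or cohort-averaged) to a
#' subject's WSS and diameter maps: WT-hat = b0 + b1*WSS + b2*D +
#' b3*WSS*D restricted to the active terms.  Negative predictions are kept
#' (the linear model's raw output) and counted; `clip = TRUE` floors them
#' at zero for display.
#'
#' @param wss,d subject map vectors or [scalar_map()]s.
#' @param beta named coefficient vector (as returned by [coef.wt_fit()] or
#'   a [fit_bootstrap_regressions()] ensemble mean).
#' @param terms active model terms.
#' @param mesh optional [vessel_mesh()]; when given, the result is a
#'   [scalar_map()] of kind `"predicted_wt"`.
#' @param clip floor predictions at 0 (display only).
#' @return predicted WT values (vector or scalar map) with attribute
#'   `n_negative`.
#' @export
predict_wt_map <- function(wss, d, beta, terms = WT_TERMS, mesh = NULL,
                           clip = FALSE) {
  if (any(!is.finite(beta))) stop("beta must be finite")
  vals <- predict_wt_values(wss, d, beta, terms)
  n_neg <- sum(vals < 0, na.rm = TRUE)
  if (clip) vals <- pmax(vals, 0)
  out <- if (!is.null(mesh)) scalar_map(vals, mesh, "predicted_wt") else vals
  attr(out, "n_negative") <- n_neg
  out
}

#' Bootstrap cohort-averaged regressions
#'
#' Fits the wall-thickness regression to every bootstrapped cohort-averaged
#' map triple: per replicate, subjects are drawn with replacement, WT, WSS
#' and D are averaged over the multiset on the shared geometry, and OLS is
#' run over the complete-vertex set.  When `multisets` is supplied (drawn
#' once via [bootstrap_multisets()]) the replicates are identical to the
#' ones used by [bootstrap_correlations()].
#'
#' @param set a [build_cohort_maps()] result with `wt`, `wss`, `d`.
#' @param B bootstrap size (study default 1000).
#' @param seed integer seed.
#' @param terms active model terms.
#' @param multisets optional pre-drawn multiset matrix (overrides B/seed).
#' @return an object of class `beta_ensemble`: `beta` (B x p matrix),
#'   `mean_beta`, `ci95` (2 x p percentile bounds), `r_squared` (per
#'   replicate), `terms`, `B`, `seed`.
#' @export
fit_bootstrap_regressions <- function(set, B = 1000L, seed = 1L,
                                      terms = WT_TERMS, multisets = NULL) {
  n <- nrow(set$matrices[[1L]])
  if (is.null(multisets)) multisets <- bootstrap_multisets(n, B, seed)
  B <- nrow(multisets)
  cv <- set$complete_vertices
  if (!any(cv)) stop("no atlas vertex is covered by all subjects")
  p <- length(terms) + 1L
  beta <- matrix(NA_real_, B, p)
  r2 <- numeric(B)
  for (b in seq_len(B)) {
    ms <- multisets[b, ]
    fit <- fit_wt_regression(average_maps(set, ms, "wt")[cv],
                             average_maps(set, ms, "wss")[cv],
                             average_maps(set, ms, "d")[cv],
                             terms = terms, source = "bootstrap")
    beta[b, ] <- fit$beta
    r2[b] <- fit$r_squared
  }
  colnames(beta) <- names(coef(fit))
  ci <- apply(beta, 2, stats::quantile, probs = c(0.025, 0.975))
  structure(list(beta = beta, mean_beta = colMeans(beta), ci95 = ci,
                 r_squared = r2, terms = terms, B = B, seed = seed),
            class = "beta_ensemble")
}

#' @export
print.beta_ensemble <- function(x, digits = 4, ...) {
  cat("beta_ensemble over B =", x$B, "bootstraps (",
      paste(x$terms, collapse = " + "), ")\n")
  tab <- rbind(mean = x$mean_beta, x$ci95)
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.beta_ensemble <- function(object, ...) object$mean_beta

#' @export
summary.beta_ensemble <- function(object, ...) {
  data.frame(coefficient = names(object$mean_beta),
             mean = unname(object$mean_beta),
             ci_lo = unname(object$ci95[1, ]),
             ci_hi = unname(object$ci95[2, ]),
             row.names = NULL)
}

#' Agreement between an original and a predicted wall-thickness map
#'
#' Spearman's rho over all vertices, Bland-Altman mean difference and
#' limits of agreement (1.96 x SD of the paired differences,
#' predicted - original), and the maximum WT of each map defined as the
#' mean of the top 5% of values (set size ceiling(0.05 n)).
#'
#' @param original,predicted aligned map vectors or [scalar_map()]s.
#' @return an object of class `prediction_eval`: `spearman_rho`,
#'   `mean_difference`, `loa`, `max_wt_original`, `max_wt_predicted`, `n`.
#' @export
evaluate_prediction <- function(original, predicted) {
  o <- as.numeric(original); p <- as.numeric(predicted)
  if (length(o) != length(p)) stop("maps must be aligned")
  ok <- !is.na(o) & !is.na(p)
  o <- o[ok]; p <- p[ok]
  diffs <- p - o
  top_mean <- function(v) {
    k <- max(1L, ceiling(0.05 * length(v)))
    mean(sort(v, decreasing = TRUE)[seq_len(k)])
  }
  structure(list(
    spearman_rho = as.numeric(spearman_rho(o, p)),
    mean_difference = mean(diffs),
    loa = 1.96 * stats::sd(diffs),
    max_wt_original = top_mean(o),
    max_wt_predicted = top_mean(p),
    n = length(o)
  ), class = "prediction_eval")
}

#' @export
print.prediction_eval <- function(x, ...) {
  cat(sprintf(paste0("prediction_eval: rho %.3f | Bland-Altman mean diff ",
                     "%.3f mm, LOA %.3f mm | max WT %.2f -> %.2f mm (n=%d)\n"),
              x$spearman_rho, x$mean_difference, x$loa,
              x$max_wt_original, x$max_wt_predicted, x$n))
  invisible(x)
}
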