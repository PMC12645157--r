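#' Plot a cross-validated AUC vs feature-count curve
#'
#' Mean AUC with its 95% band against the number of included variables;
#' the smallest-argmax N is marked.
#'
#' @param curve a `cv_curve`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the curve.
#' @export
plot_cv_curve <- function(curve, ...) {
  cv <- curve$curve
  plot(cv$n_features, cv$mean_auc, type = "l", ylim = range(cv$ci_low, cv$ci_high),
       xlab = "number of variables", ylab = "mean CV AUC", ...)
  polygon(c(cv$n_features, rev(cv$n_features)), c(cv$ci_low, rev(cv$ci_high)),
          col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  lines(cv$n_features, cv$mean_auc, lwd = 2)
  abline(v = select_optimal_n(curve), lty = 2)
  invisible(curve)
}

#' Forest plot of association records
#'
#' Estimates with 95% CI whiskers, one row per variable; logistic records
#' are drawn on a log odds-ratio axis with a reference line at OR = 1,
#' linear (age) records on a linear axis with a line at 0. Flagged
#' records are drawn without estimates but keep their row.
#'
#' @param records association records data.frame.
#' @param top plot only the `top` smallest-p records (default 20).
#' @return Invisibly, the plotted subset.
#' @export
plot_forest <- function(records, top = 20L) {
  rec <- records[order(records$p), , drop = FALSE]
  rec <- utils::head(rec, top)
  logistic <- rec$model[1] == "logistic_disease"
  est <- if (logistic) log(rec$estimate) else rec$estimate
  lo <- if (logistic) log(rec$ci_low) else rec$ci_low
  hi <- if (logistic) log(rec$ci_high) else rec$ci_high
  n <- nrow(rec)
  rng <- range(c(lo, hi, 0), na.rm = TRUE)
  plot(NA, xlim = rng, ylim = c(0.5, n + 0.5), yaxt = "n",
       xlab = if (logistic) "log odds ratio" else "beta (per SD age)",
       ylab = "")
  axis(2, at = rev(seq_len(n)), labels = rec$variable, las = 2, cex.axis = 0.6)
  abline(v = 0, lty = 3)
  ys <- rev(seq_len(n))
  segments(lo, ys, hi, ys)
  points(est, ys, pch = 16)
  invisible(rec)
}

#' PCA biplot with group colouring and marker arrows
#'
#' @param embedding a [pca_embed()] result.
#' @param labels group labels for colouring.
#' @param arrows optional output of [biplot_projection()].
#' @return Invisibly, the embedding.
#' @export
plot_pca <- function(embedding, labels, arrows = NULL) {
  sc <- embedding$scores
  y <- .as_case(labels)
  plot(sc[, 1], sc[, 2], col = ifelse(y == 1, "firebrick", "steelblue"),
       pch = 16, cex = 0.7,
       xlab = sprintf("PC1 (%.1f%%)", 100 * embedding$var_share[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * embedding$var_share[2]))
  if (!is.null(arrows)) {
    sfac <- 0.8 * max(abs(sc[, 1:2])) / max(sqrt(arrows$pc1^2 + arrows$pc2^2))
    arrows(0, 0, arrows$pc1 * sfac, arrows$pc2 * sfac, length = 0.08)
    text(arrows$pc1 * sfac, arrows$pc2 * sfac, arrows$marker, cex = 0.6, pos = 3)
  }
  invisible(embedding)
}
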