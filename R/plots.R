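# Base-graphics plotting helpers.

#' Plot observed vs expected tract-length decay
#'
#' Log-scale counts of tract lengths per ancestry: points for the observed
#' spectrum, lines for the model expectation.
#'
#' @param observed,expected [TractSpectrum-class] objects on the same bins.
#' @param cols Colors per ancestry.
#' @export
plotTractSpectrum <- function(observed, expected = NULL,
                              cols = c("steelblue", "forestgreen", "darkorange",
                                       "purple")) {
  ed <- observed@edges
  mids <- (head(ed, -1) + pmin(tail(ed, -1), max(ed[is.finite(ed)]) * 1.1)) / 2
  anc <- rownames(observed@counts)
  cnt <- observed@counts
  ymax <- max(cnt, if (!is.null(expected)) expected@counts, 1)
  plot(NA, xlim = range(mids), ylim = c(0.5, ymax * 1.5), log = "y",
       xlab = "tract length (cM)", ylab = "tract count",
       main = "Ancestry tract length spectrum")
  for (i in seq_along(anc)) {
    y <- cnt[i, ]
    points(mids[y > 0], y[y > 0], col = cols[(i - 1) %% length(cols) + 1], pch = 16)
    if (!is.null(expected)) {
      ye <- expected@counts[anc[i], ]
      lines(mids[ye > 0.1], ye[ye > 0.1], col = cols[(i - 1) %% length(cols) + 1])
    }
  }
  legend("topright", legend = anc, col = cols[seq_along(anc)], pch = 16, bty = "n")
  invisible(NULL)
}

#' Histogram of simulated null likelihood gains
#'
#' The calibration picture behind the model-selection test: simulated
#' delta-log-likelihoods under the fitted null, the 95% rejection threshold,
#' and the observed gain.
#'
#' @param comparison A [ModelComparison-class].
#' @export
plotNullDeltas <- function(comparison) {
  d <- comparison@simDeltas
  hist(d, breaks = 30, col = "grey80", border = "white",
       xlab = expression(Delta ~ "log-likelihood"),
       main = sprintf("Null-calibrated likelihood gains (p = %.3g)",
                      comparison@pValue),
       xlim = range(c(d, comparison@observedDelta)))
  abline(v = quantile(d, 0.95, type = 1), lty = 2)
  abline(v = comparison@observedDelta, col = "red", lwd = 2)
  invisible(NULL)
}

#' Scatter plot of ancestry-specific PCA coordinates
#'
#' Reference haplotypes as letters (population initials), admixed haplotypes
#' as grey points.
#'
#' @param result An [ASPCAResult-class].
#' @param comps Which two components to show.
#' @export
plotASPCA <- function(result, comps = c(1, 2)) {
  sc <- result@scores[, comps, drop = FALSE]
  isref <- result@isReference
  plot(sc, type = "n",
       xlab = sprintf("ASPC%d (%.1f%%)", comps[1], 100 * result@varShare[comps[1]]),
       ylab = sprintf("ASPC%d (%.1f%%)", comps[2], 100 * result@varShare[comps[2]]),
       main = "Ancestry-specific PCA")
  points(sc[!isref, , drop = FALSE], col = "grey60", pch = 16, cex = 0.6)
  if (any(isref)) {
    pops <- factor(result@labels[isref])
    text(sc[isref, , drop = FALSE], labels = substr(as.character(pops), 1, 3),
         col = as.integer(pops) + 1, cex = 0.7)
  }
  invisible(NULL)
}
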