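#' Fit a pulse-migration model to an observed tract-length spectrum
#'
#' Maximizes the Poisson composite log-likelihood of the binned tract counts
#' over the model's free parameters (admixture times, and pulse magnitude for
#' the 4-parameter models) by multi-start bounded Nelder-Mead search. Pulse
#' magnitudes other than the free one, and the founding split, are pinned to
#' the observed ancestry proportions (see [buildMigrationSchedule()]).
#' Expectations inside the optimizer use the fast memoryless (depth-0) lineage
#' kernel; the simulation-calibrated model comparison
#' ([compareModels()]) is the guard against its approximation error.
#'
#' Bounds: times in (2, 25) generations, magnitude in (0.001, 0.999), pulses
#' at least one generation after founding; violations are handled by an
#' infeasibility penalty.
#'
#' @param observed A [TractSpectrum-class] (type "observed") whose ancestry
#'   rows can be matched to \code{names(proportions)}.
#' @param model "BASE", "EUR_PULSE" or "AFR_PULSE".
#' @param proportions Named length-3 vector (European-like, Native-like,
#'   African) of observed ancestry fractions from
#'   [ancestryProportions()] over the same cohort.
#' @param nStarts Number of Latin-hypercube optimizer starts.
#' @param seed Seed for the start draws.
#' @param maxit,tol Nelder-Mead iteration cap and log-likelihood tolerance.
#' @param extraStarts Optional matrix (parameters x starts) of additional
#'   start points, e.g. warm starts from a previous fit.
#' @return A [TractModelFit-class].
#' @export
fitTractModel <- function(observed, model = DEMOGRAPHIC_MODELS, proportions,
                          nStarts = 10, seed = 1, maxit = 500, tol = 1e-6,
                          extraStarts = NULL) {
  model <- match.arg(model)
  stopifnot(is(observed, "TractSpectrum"))
  if (sum(observed@counts) + sum(observed@full) == 0)
    stop("empty spectrum: no tracts to fit")
  if (length(proportions) != 3 || is.null(names(proportions)))
    stop("proportions must be a named length-3 vector")
  anc <- names(proportions)
  if (!all(anc %in% rownames(observed@counts)))
    stop("spectrum lacks ancestries: ",
         paste(setdiff(anc, rownames(observed@counts)), collapse = ", "))
  obs_counts <- observed@counts[anc, , drop = FALSE]
  obs_full <- observed@full[anc, , drop = FALSE]
  k <- if (model == "BASE") 2L else 4L
  starts <- .lhs_starts(model, nStarts, seed)
  if (!is.null(extraStarts)) {
    if (nrow(extraStarts) != k) stop("extraStarts must have ", k, " rows")
    starts <- cbind(extraStarts, starts)
  }
  fit <- fit_model_cpp(.model_code(model), as.numeric(proportions),
                       chromLengths(observed@chroms), observed@edges,
                       obs_counts, obs_full, observed@nHaplotypes, starts,
                       as.integer(maxit), tol)
  if (!isTRUE(fit$converged))
    stop("all ", ncol(starts), " starts infeasible for model ", model,
         "; check proportions and bounds")
  par <- as.numeric(fit$par)
  names(par) <- .model_param_names(model)
  sched <- buildMigrationSchedule(model, par, proportions)
  mu <- expected_spectrum_markov_cpp(migrationMatrix(sched),
                                     chromLengths(observed@chroms),
                                     observed@edges)
  expd <- new("TractSpectrum",
              counts = mu$counts * observed@nHaplotypes,
              full = mu$full * observed@nHaplotypes,
              edges = observed@edges, chroms = observed@chroms,
              nHaplotypes = observed@nHaplotypes, type = "expected",
              lengthMass = NULL)
  dimnames(expd@counts) <- dimnames(obs_counts)
  dimnames(expd@full) <- dimnames(obs_full)
  new("TractModelFit", model = model, params = par,
      proportions = as.numeric(proportions), logLik = fit$logLik,
      converged = TRUE, nStarts = ncol(starts), expected = expd,
      startLogLik = as.numeric(fit$start_logLik))
}

# Latin-hypercube draws over the feasible box; times scaled so pulses stay
# below the founding time.
.lhs_starts <- function(model, nStarts, seed) {
  k <- if (model == "BASE") 2L else 4L
  set.seed(as.integer(seed))
  u <- vapply(seq_len(k), function(i) (sample(nStarts) - runif(nStarts)) / nStarts,
              numeric(nStarts))
  u <- matrix(u, nrow = nStarts)
  t0 <- 4 + u[, 1] * 18                 # (4, 22)
  tafr <- 2 + u[, 2] * (t0 - 3.2)       # (2, t0 - 1.2)
  out <- rbind(t0, tafr)
  if (k == 4) {
    tp <- 2 + u[, 3] * (t0 - 3.2)
    mp <- 0.01 + u[, 4] * 0.45
    out <- rbind(out, tp, mp)
  }
  unname(out)
}

#' Serialize a fitted model to JSON
#'
#' Parameters, proportions, log-likelihood and convergence metadata.
#' @param fit A [TractModelFit-class].
#' @param path Output file.
#' @export
writeTractModelFit <- function(fit, path) {
  jsonlite::write_json(list(model = fit@model, params = as.list(fit@params),
                            proportions = fit@proportions,
                            logLik = fit@logLik, converged = fit@converged,
                            nStarts = fit@nStarts, BIC = BIC(fit)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an observed/expected spectrum table
#'
#' TSV with ancestry, bin_lo, bin_hi, observed and (when given) expected
#' counts — the table behind tract-length decay plots. Whole-chromosome
#' categories appear as rows with bin_lo = chromosome length.
#'
#' @param observed A [TractSpectrum-class].
#' @param expected Optional matching expected spectrum.
#' @param path Output file.
#' @export
writeSpectrumTSV <- function(observed, path, expected = NULL) {
  ed <- observed@edges
  nb <- length(ed) - 1
  anc <- rownames(observed@counts)
  rows <- data.frame(ancestry = rep(anc, each = nb),
                     bin_lo = rep(ed[-length(ed)], length(anc)),
                     bin_hi = rep(ed[-1], length(anc)),
                     observed = as.vector(t(observed@counts)))
  L <- chromLengths(observed@chroms)
  fulls <- data.frame(ancestry = rep(anc, each = length(L)),
                      bin_lo = rep(unname(L), length(anc)),
                      bin_hi = rep(unname(L), length(anc)),
                      observed = as.vector(t(observed@full)))
  out <- rbind(rows, fulls)
  if (!is.null(expected)) {
    stopifnot(identical(dim(expected@counts), dim(observed@counts)))
    out$expected <- c(as.vector(t(expected@counts[anc, , drop = FALSE])),
                      as.vector(t(expected@full[anc, , drop = FALSE])))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
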