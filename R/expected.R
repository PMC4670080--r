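# Analytic expected tract-length spectra.
#
# The ancestry state of a sampled haplotype along the genome is modelled by a
# continuous-state process whose state is the (entry generation, source) of the
# lineage's most recent migrant ancestor. A crossover at meiosis level s
# (uniform over the t-2 switch-capable meioses of a state with entry t; the
# topmost meiosis connects to the migrant itself and never changes ancestry)
# replaces the lineage above level s+1 with a fresh draw entering at
# generation >= s+2. Because each meiosis toggles between the SAME two parental
# chromosomes, a flip can resume a previously shelved lineage with its frozen
# ancestry: the chain therefore augments the current state with a LIFO stack of
# shelved lineages (configurable depth; depth 0 recovers the memoryless Markov
# approximation used for fast likelihood fitting).

# enumerate the stack chain for a schedule matrix; returns generator + stationary
.stack_chain <- function(m, depth = 2, maxStates = 4000) {
  T0 <- nrow(m); P <- ncol(m)
  M <- rowSums(m)
  a <- .entry_probs_R(m)
  base <- which(a > 1e-12, arr.ind = TRUE)
  K <- nrow(base); tt <- base[, 1]; pp <- base[, 2]
  pref <- cumprod(c(1, 1 - M))            # pref[g+1] = prod_{j<=g} (1-M_j)
  Cf <- function(i, j) if (i > j) 1 else pref[j + 1] / pref[i]
  gd <- lapply(seq_len(max(tt)), function(i) {
    w <- numeric(K)
    for (y in seq_len(K)) if (tt[y] >= i + 2) w[y] <- m[tt[y], pp[y]] * Cf(i + 2, tt[y] - 1)
    w
  })
  skey <- function(x, st) paste(x, paste(unlist(st), collapse = "."), sep = "|")
  ids <- new.env(hash = TRUE); states <- vector("list", 256); nS <- 0
  queue_head <- 0
  push_state <- function(x, st) {
    k <- skey(x, st)
    id <- ids[[k]]
    if (is.null(id)) {
      nS <<- nS + 1
      if (nS > maxStates) stop("stack chain exceeds maxStates; lower depth")
      if (nS > length(states)) states[[2 * nS]] <<- NULL
      ids[[k]] <- nS
      states[[nS]] <<- list(x = x, st = st)
      id <- nS
    }
    id
  }
  for (x in seq_len(K)) push_state(x, list())
  ti <- tj <- tv <- numeric(0)
  add <- function(i, j, r) { ti[[length(ti) + 1]] <<- i; tj[[length(tj) + 1]] <<- j
                             tv[[length(tv) + 1]] <<- r }
  while (queue_head < nS) {
    queue_head <- queue_head + 1
    s <- states[[queue_head]]
    x <- s$x; st <- s$st; t <- tt[x]
    jlev <- vapply(st, function(e) e[2], 0)
    if (t >= 3) for (i in seq_len(t - 2)) {
      r <- match(i, jlev)
      if (!is.na(r)) {
        ns <- if (r > 1) st[seq_len(r - 1)] else list()
        add(queue_head, push_state(st[[r]][1], ns), 1)
      } else {
        g <- gd[[i]]
        keep <- st[jlev < i]
        ns <- c(keep, list(c(x, i)))
        if (length(ns) > depth) ns <- ns[-1]
        if (depth == 0) ns <- list()
        for (z in which(g > 0)) add(queue_head, push_state(z, ns), g[z])
      }
    }
    if (length(st)) for (r in seq_along(st)) {
      y <- st[[r]][1]; j <- st[[r]][2]
      if (tt[y] - 2 >= j + 1) for (i in (j + 1):(tt[y] - 2)) {
        g <- gd[[i]]
        for (z in which(g > 0)) {
          ns <- st; ns[[r]] <- c(z, j)
          add(queue_head, push_state(x, ns), g[z])
        }
      }
    }
  }
  Q <- matrix(0, nS, nS)
  for (k in seq_along(ti)) Q[ti[k], tj[k]] <- Q[ti[k], tj[k]] + tv[k]
  diag(Q) <- diag(Q) - rowSums(Q)
  # stationary distribution. States with entry generation 2 are absorbing
  # (no switch-capable meiosis, an infinite tract) and unreachable from the
  # rest of the chain: they carry exactly their lineage entry mass a_{2,p}.
  # The main communicating class is solved as the null vector of t(Q) with a
  # normalization row substituted in; length conservation of the spectra
  # depends on pi Q = 0 holding to machine precision.
  pi_st <- numeric(nS)
  absorbing <- seq_len(K)[tt == 2]
  pi_st[absorbing] <- a[cbind(tt[absorbing], pp[absorbing])]
  main <- setdiff(seq_len(nS), absorbing)
  if (length(main)) {
    Qm <- Q[main, main, drop = FALSE]
    nm <- length(main)
    M <- t(Qm); M[1, ] <- 1
    b <- c(1, rep(0, nm - 1))
    pm <- tryCatch(as.numeric(solve(M, b)), error = function(e) NULL)
    resid <- function(p) if (is.null(p) || any(!is.finite(p))) Inf else
      max(abs(p %*% Qm)) + max(0, -min(p))
    if (resid(pm) > 1e-9) {
      sv <- svd(t(Qm))
      pm <- as.numeric(sv$v[, nm])
      pm <- pm / sum(pm)
      if (resid(pm) > 1e-8)
        warning("stationary solve residual ", format(resid(pm)))
    }
    pm[pm < 0 & pm > -1e-12] <- 0
    pi_st[main] <- pm / sum(pm) * (1 - sum(pi_st[absorbing]))
  }
  cur <- vapply(states[seq_len(nS)], function(s) pp[s$x], 0)
  list(Q = Q, pi = pi_st, cur = cur, aq = colSums(a), nS = nS)
}

.entry_probs_R <- function(m) {
  T0 <- nrow(m); M <- rowSums(m)
  a <- matrix(0, T0, ncol(m))
  surv <- 1
  for (t in 2:T0) { a[t, ] <- m[t, ] * surv; surv <- surv * (1 - M[t]) }
  a
}

# Per-ancestry phase-type engine on the (sub)chain, evaluated by
# uniformization: exp(T u) v = sum_k dpois(k, Lambda u) P^k v with
# P = I + T / Lambda substochastic. All weights are nonnegative, so the
# evaluation is unconditionally stable (an eigenbasis representation loses
# catastrophically when shelf states make the sub-generator nearly
# defective). Moment integrals use incomplete-gamma weights:
#   int_0^d u   e^(-Lu) (Lu)^k / k! du = (k+1)        / L^2 pgamma(Ld, k+2)
#   int_0^d u^2 e^(-Lu) (Lu)^k / k! du = (k+1)(k+2)   / L^3 pgamma(Ld, k+3)
.anc_engine <- function(chain, q, umax) {
  inq <- chain$cur == q
  if (!any(inq) || chain$aq[q] <= 1e-12) return(NULL)
  Tm <- chain$Q[inq, inq, drop = FALSE]
  sc <- chain$aq[q] / sum(chain$pi[inq])    # pin marginal to exact proportions
  beta <- chain$pi[inq] * sc
  lam <- if (any(!inq))
    colSums(chain$pi[!inq] * chain$Q[!inq, inq, drop = FALSE]) * sc
  else rep(0, sum(inq))
  one <- rep(1, ncol(Tm))
  evec <- as.vector(-Tm %*% one)
  Lam <- max(-diag(Tm), 0)
  if (Lam <= 0) {
    # no activity inside this ancestry: single eternal tract mass
    return(list(Lam = 0, b1 = sum(beta), be = 0, l1 = sum(lam), le = 0))
  }
  P <- Tm / Lam
  diag(P) <- diag(P) + 1
  Kmax <- ceiling(Lam * umax + 12 * sqrt(Lam * umax + 1) + 25)
  b1 <- be <- l1 <- le <- numeric(Kmax + 1)
  vb <- beta; vl <- lam
  for (k in 0:Kmax) {
    b1[k + 1] <- sum(vb)
    be[k + 1] <- sum(vb * evec)
    l1[k + 1] <- sum(vl)
    le[k + 1] <- sum(vl * evec)
    if (k < Kmax) { vb <- as.vector(vb %*% P); vl <- as.vector(vl %*% P) }
  }
  list(Lam = Lam, b1 = b1, be = be, l1 = l1, le = le, Kmax = Kmax)
}

# pointwise sums: f(u) = sum_k dpois(k, Lam u) w_k
.u_point <- function(e, w, u) {
  if (e$Lam == 0) return(w[1] * (u >= 0))
  sum(stats::dpois(0:e$Kmax, e$Lam * u) * w)
}
# integral weights over [a, b]: int u^m dpois-density du, m = 0, 1, 2
.u_int <- function(e, w, a, b, m = 0) {
  if (e$Lam == 0) return(if (m == 0) w[1] * (b - a) else
                         if (m == 1) w[1] * (b^2 - a^2) / 2 else
                         w[1] * (b^3 - a^3) / 3)
  k <- 0:e$Kmax
  cw <- if (m == 0) (stats::pgamma(e$Lam * b, k + 1) -
                     stats::pgamma(e$Lam * a, k + 1)) / e$Lam
        else if (m == 1) (k + 1) / e$Lam^2 *
          (stats::pgamma(e$Lam * b, k + 2) - stats::pgamma(e$Lam * a, k + 2))
        else (k + 1) * (k + 2) / e$Lam^3 *
          (stats::pgamma(e$Lam * b, k + 3) - stats::pgamma(e$Lam * a, k + 3))
  sum(cw * w)
}

#' Expected tract-length spectrum under a migration schedule
#'
#' Deterministic expectation of the binned tract-length counts for a cohort of
#' \code{nHaplotypes} haplotypes on the given chromosomes, under the lineage
#' process described in the package vignette. End-truncated tracts are counted
#' in the bin of their observed length and tracts covering a whole chromosome
#' in a separate per-chromosome category, mirroring
#' [tractLengthSpectrum()].
#'
#' \code{depth} controls how many shelved lineages the chain remembers.
#' Depth 0 is the memoryless Markov approximation (what the fast fitting
#' engine uses); depth 2 (default) additionally captures crossovers that
#' toggle back to a previously visited parental chromosome, which measurably
#' sharpens agreement with forward pedigree simulation.
#'
#' @param schedule A [MigrationSchedule-class].
#' @param chroms A [ChromosomeSet-class].
#' @param edges Bin edges in cM (last may be Inf); at least one bin.
#' @param nHaplotypes Cohort size the expectation is scaled to.
#' @param depth Shelf-stack depth (0, 1 or 2).
#' @param maxStates Cap on chain size; exceeded caps raise an error suggesting
#'   a lower depth.
#' @return A [TractSpectrum-class] with \code{type = "expected"} and the
#'   per-bin expected total tract length in \code{lengthMass} (final column =
#'   whole-chromosome mass). The length masses satisfy per-ancestry length
#'   conservation: their sum equals ancestry proportion x genome length x
#'   nHaplotypes.
#' @export
expectedTractSpectrum <- function(schedule, chroms, edges = defaultBinEdges(chroms),
                                  nHaplotypes = 1, depth = 2, maxStates = 4000) {
  stopifnot(is(schedule, "MigrationSchedule"), is(chroms, "ChromosomeSet"))
  if (length(edges) < 2) stop("need at least one bin")
  if (is.unsorted(edges, strictly = TRUE)) stop("bin edges must be strictly increasing")
  m <- migrationMatrix(schedule)
  pops <- populations(schedule)
  chain <- NULL
  for (d in seq(depth, 0)) {
    chain <- tryCatch(.stack_chain(m, depth = d, maxStates = maxStates),
                      error = function(e) NULL)
    if (!is.null(chain)) {
      if (d < depth)
        message("shelf depth reduced to ", d, " to respect maxStates")
      break
    }
  }
  if (is.null(chain)) stop("state space exceeds maxStates even at depth 0")
  nb <- length(edges) - 1
  Lall <- chromLengths(chroms) / 100
  ed <- edges / 100
  counts <- matrix(0, length(pops), nb, dimnames = list(pops, NULL))
  full <- matrix(0, length(pops), length(chroms),
                 dimnames = list(pops, chromNames(chroms)))
  lmass <- matrix(0, length(pops), nb + 1,
                  dimnames = list(pops, c(rep("", nb), "full")))
  for (q in seq_along(pops)) {
    e <- .anc_engine(chain, q, umax = max(Lall))
    if (is.null(e)) next
    for (ci in seq_along(Lall)) {
      L <- Lall[ci]
      full[q, ci] <- .u_point(e, e$b1, L)
      lmass[q, nb + 1] <- lmass[q, nb + 1] + L * full[q, ci]
      for (b in seq_len(nb)) {
        l1 <- ed[b]; l2 <- ed[b + 1]
        if (l1 >= L) next
        l2c <- min(l2, L)
        cnt <- .u_point(e, e$b1, l1) - .u_point(e, e$b1, l2c)
        len1 <- if (is.finite(l2) && L > l2) L - l2 else 0
        s1 <- .u_point(e, e$l1, l1)
        if (len1 > 0) cnt <- cnt + len1 * (s1 - .u_point(e, e$l1, l2))
        cnt <- cnt + (l2c - l1) * s1
        counts[q, b] <- counts[q, b] + cnt
        # expected total observed length of tracts falling in this bin:
        # start-censored piece, complete interior tracts, end-censored piece
        lm <- .u_int(e, e$be, l1, l2c, m = 1)
        if (len1 > 0) lm <- lm + len1 * .u_int(e, e$le, l1, l2, m = 1)
        lm <- lm + l2c * .u_int(e, e$le, l1, l2c, m = 1) -
              .u_int(e, e$le, l1, l2c, m = 2) +
              .u_int(e, e$l1, l1, l2c, m = 1)
        lmass[q, b] <- lmass[q, b] + lm
      }
    }
  }
  new("TractSpectrum", counts = counts * nHaplotypes, full = full * nHaplotypes,
      edges = as.numeric(edges), chroms = chroms,
      nHaplotypes = as.numeric(nHaplotypes), type = "expected",
      lengthMass = lmass * nHaplotypes * 100)
}

#' Poisson composite log-likelihood of an observed spectrum
#'
#' \code{sum(o * log(mu) - mu - log(o!))} over all length bins and
#' whole-chromosome categories, with the convention \code{0 * log(0) = 0}; a
#' cell with zero expectation but positive observation yields \code{-Inf}.
#'
#' @param observed,expected [TractSpectrum-class] objects with matching bins,
#'   ancestries and chromosomes.
#' @return Log-likelihood (scalar).
#' @export
poissonLogLik <- function(observed, expected) {
  stopifnot(is(observed, "TractSpectrum"), is(expected, "TractSpectrum"))
  if (!identical(dim(observed@counts), dim(expected@counts)) ||
      !identical(dim(observed@full), dim(expected@full)))
    stop("observed and expected spectra have different shapes")
  eo <- observed@edges; ee <- expected@edges
  same_inf <- identical(is.finite(eo), is.finite(ee))
  if (!same_inf || max(abs(eo[is.finite(eo)] - ee[is.finite(ee)])) > 1e-9)
    stop("observed and expected spectra use different bin edges")
  oc <- observed@counts; of <- observed@full
  if (!is.null(rownames(oc)) && !is.null(rownames(expected@counts))) {
    if (!setequal(rownames(oc), rownames(expected@counts)))
      stop("observed and expected spectra cover different ancestries")
    oc <- oc[rownames(expected@counts), , drop = FALSE]
    of <- of[rownames(expected@full), , drop = FALSE]
  }
  o <- c(oc, of)
  mu <- c(expected@counts, expected@full)
  ll <- numeric(length(o))
  pos <- o > 0
  if (any(pos & mu <= 0)) return(-Inf)
  ll[pos] <- o[pos] * log(mu[pos]) - lgamma(o[pos] + 1)
  sum(ll) - sum(mu)
}
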