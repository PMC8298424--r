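# Two-state negative-binomial HMM peak caller: background vs enriched
# emissions, EM with scaled forward-backward (C++) and posterior-weighted
# method-of-moments NB updates.

.nbLogEmiss <- function(x, mu, alpha) {
  cbind(stats::dnbinom(x, mu = mu[1], size = 1 / max(alpha[1], 1e-8), log = TRUE),
        stats::dnbinom(x, mu = mu[2], size = 1 / max(alpha[2], 1e-8), log = TRUE))
}

# One E-step over all chromosomes; returns pooled statistics.
.hmmEStep <- function(xlist, mu, alpha, trans, initP) {
  gamma <- vector("list", length(xlist))
  xi <- matrix(0, 2, 2)
  init <- c(0, 0)
  ll <- 0
  for (i in seq_along(xlist)) {
    fb <- .fbScaled(.nbLogEmiss(xlist[[i]], mu, alpha), trans, initP)
    gamma[[i]] <- fb$gamma
    xi <- xi + fb$xi
    init <- init + fb$gamma[1, ]
    ll <- ll + fb$logLik
  }
  list(gamma = gamma, xi = xi, init = init / length(xlist), logLik = ll)
}

.hmmMStepEmissions <- function(xlist, gamma) {
  mu <- numeric(2); alpha <- numeric(2)
  for (k in 1:2) {
    wsum <- 0; xsum <- 0
    for (i in seq_along(xlist)) {
      w <- gamma[[i]][, k]
      wsum <- wsum + sum(w)
      xsum <- xsum + sum(w * xlist[[i]])
    }
    m <- xsum / max(wsum, 1e-12)
    vsum <- 0
    for (i in seq_along(xlist))
      vsum <- vsum + sum(gamma[[i]][, k] * (xlist[[i]] - m)^2)
    v <- vsum / max(wsum, 1e-12)
    mu[k] <- max(m, 1e-6)
    alpha[k] <- max((v - m) / m^2, 1e-6)
  }
  list(mu = mu, alpha = alpha)
}

#' Fit a two-state negative-binomial HMM to binned counts
#'
#' EM on a background/enriched two-state hidden Markov model with
#' negative-binomial emissions: scaled forward-backward E-step,
#' posterior-weighted method-of-moments updates for the state means and
#' dispersions, closed-form updates for the transition matrix and initial
#' distribution.  Chromosomes are treated as independent chains sharing
#' parameters.  Iterates until the relative log-likelihood change drops
#' below `tol` or `maxIter` is reached (non-convergence gives a warning
#' and returns the best parameters).  States are ordered so the enriched
#' mean exceeds the background mean; a fit whose two means agree within 5%
#' is flagged degenerate (and yields no peaks downstream).
#'
#' @param x per-strand counts: a [BinnedCounts-class] (with `strand` to
#'   pick one strand), a numeric vector, or a list of per-chromosome
#'   vectors.
#' @param strand which strand of a stranded `BinnedCounts` to fit
#'   (`"+"`, `"-"`, or `"*"` for unstranded input).
#' @param sample column index or name when `x` is multi-sample.
#' @param maxIter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return an [NBHMMFit-class] with the per-bin posterior probability of
#'   the enriched state.
#' @export
fitNbHmm <- function(x, strand = "*", sample = 1L, maxIter = 200L, tol = 1e-4) {
  bins <- GRanges()
  if (is(x, "BinnedCounts")) {
    rr <- rowRanges(x)
    keep <- if (strand == "*") rep(TRUE, length(rr))
            else as.character(BiocGenerics::strand(rr)) == strand
    stopIfNot(any(keep), sprintf("no bins on strand '%s'", strand))
    bins <- rr[keep]
    v <- counts(x)[keep, sample]
    chr <- as.character(seqnames(bins))
    xlist <- split(v, factor(chr, levels = unique(chr)))
  } else if (is.list(x)) {
    xlist <- lapply(x, as.numeric)
  } else {
    xlist <- list(as.numeric(x))
  }
  xlist <- lapply(xlist, function(v) { v[is.na(v)] <- 0; round(v) })
  n <- sum(lengths(xlist))
  stopIfNot(all(unlist(xlist, use.names = FALSE) >= 0),
            "counts must be non-negative")
  allx <- unlist(xlist, use.names = FALSE)
  if (all(allx == 0))
    stop("degenerate input: all-zero track", call. = FALSE)

  # moment-based initialisation
  q75 <- stats::quantile(allx, 0.75)
  q90 <- stats::quantile(allx, 0.9)
  muB <- mean(allx[allx <= q75])
  muE <- if (any(allx > q90)) mean(allx[allx > q90]) else muB * 5 + 1
  if (muE <= muB) muE <- muB * 2 + 1
  mu <- c(max(muB, 1e-3), muE)
  alpha <- c(0.1, 0.1)
  trans <- matrix(c(0.97, 0.03, 0.03, 0.97), 2, 2, byrow = TRUE)
  initP <- c(0.9, 0.1)

  es <- .hmmEStep(xlist, mu, alpha, trans, initP)
  llTrace <- es$logLik
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    em <- .hmmMStepEmissions(xlist, es$gamma)
    newTrans <- es$xi / rowSums(es$xi)
    newTrans[!is.finite(newTrans)] <- 0.5
    newInit <- pmax(es$init, 1e-12); newInit <- newInit / sum(newInit)
    esNew <- .hmmEStep(xlist, em$mu, em$alpha, newTrans, newInit)
    if (esNew$logLik < llTrace[length(llTrace)] - 1e-8 * abs(llTrace[length(llTrace)])) {
      # the moment-based dispersion update is not an exact M-step; if it
      # ever lowers the likelihood, retry keeping the previous dispersions
      esAlt <- .hmmEStep(xlist, em$mu, alpha, newTrans, newInit)
      if (esAlt$logLik >= esNew$logLik) {
        esNew <- esAlt
        em$alpha <- alpha
      }
    }
    mu <- em$mu; alpha <- em$alpha; trans <- newTrans; initP <- newInit
    rel <- abs(esNew$logLik - llTrace[length(llTrace)]) /
      (abs(llTrace[length(llTrace)]) + 1e-10)
    llTrace <- c(llTrace, esNew$logLik)
    es <- esNew
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge within ", maxIter,
            " iterations; returning best parameters")

  # order states so state 2 is enriched
  if (mu[1] > mu[2]) {
    mu <- rev(mu); alpha <- rev(alpha)
    trans <- trans[2:1, 2:1]; initP <- rev(initP)
    es$gamma <- lapply(es$gamma, function(g) g[, 2:1, drop = FALSE])
  }
  degenerate <- abs(mu[2] - mu[1]) <= 0.05 * max(mu[1], 1e-12)
  posterior <- unlist(lapply(es$gamma, function(g) g[, 2]), use.names = FALSE)
  if (degenerate) posterior <- pmin(posterior, 0.5)
  new("NBHMMFit", mu = mu, alpha = alpha, transition = trans,
      initProb = initP, logLik = llTrace, iterations = iter,
      converged = converged, degenerate = degenerate,
      bins = bins, posterior = posterior)
}
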