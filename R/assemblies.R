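## Cell-assembly detection: Marchenko-Pastur eigenvalue bound on the
## correlation matrix of 25 ms-binned, z-scored PYR spike counts, followed
## by independent component analysis in the significant subspace; assembly
## activation strength is reconstructed over time as a projector quadratic
## form on smoothed population activity.

#' Marchenko-Pastur eigenvalue limit
#'
#' Upper edge of the eigenvalue distribution of the correlation matrix of
#' independent random series: l = (1 + sqrt(1/q))^2 with
#' q = nBins / nNeurons. Correlation-matrix eigenvalues above l indicate
#' genuine coactivation structure.
#'
#' @param nBins number of time bins.
#' @param nNeurons number of neurons.
#' @return the eigenvalue limit l.
#' @export
marchenkoPasturLimit <- function(nBins, nNeurons) {
  q <- nBins / nNeurons
  if (q <= 1) stop("requires more time bins than neurons (q > 1)")
  (1 + sqrt(1 / q))^2
}

## Deflation-mode FastICA with the logcosh contrast. X is components x
## samples and must be pre-whitened. Returns the unmixing matrix W
## (nComp x nrow(X)) with orthonormal rows.
fastICADeflation <- function(X, nComp, tol = 1e-4, maxIter = 1000) {
  p <- nrow(X)
  n <- ncol(X)
  W <- matrix(0, nComp, p)
  for (i in seq_len(nComp)) {
    w <- stats::rnorm(p)
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(maxIter)) {
      wx <- drop(w %*% X)
      g <- tanh(wx)
      gPrime <- 1 - g^2
      wNew <- (X %*% g) / n - mean(gPrime) * w
      ## Gram-Schmidt against previously extracted components
      if (i > 1L)
        wNew <- wNew - t(W[seq_len(i - 1L), , drop = FALSE]) %*%
          (W[seq_len(i - 1L), , drop = FALSE] %*% wNew)
      wNew <- drop(wNew) / sqrt(sum(wNew^2))
      conv <- abs(abs(sum(wNew * w)) - 1)
      w <- wNew
      if (conv < tol) break
    }
    W[i, ] <- w
  }
  W
}

#' Detect assembly patterns
#'
#' The binned counts are z-scored per neuron; the number of patterns is the
#' number of correlation-matrix eigenvalues above the Marchenko-Pastur
#' limit, and that many independent components are extracted from the data
#' projected into the significant eigenspace. Each weight vector is scaled
#' to unit length and oriented so its largest-magnitude entry is positive;
#' patterns are ordered by explained variance.
#'
#' @param binned a [BinnedCounts-class] (neurons x bins; 25 ms bins) of the
#'   pyramidal cells, or a plain counts matrix.
#' @param minNeurons minimum number of neurons (default 10).
#' @param seed RNG seed for the ICA initialization.
#' @return list of class `AssemblyPatterns`: `weights` (neurons x k matrix,
#'   possibly 0 columns), `members` (list of integer vectors: weights
#'   exceeding 2 SD of the pattern vector), `eigenvalueLimit`, `eigenvalues`,
#'   `q`, `kept` (indices of non-degenerate neurons).
#' @export
detectPatterns <- function(binned, minNeurons = 10, seed = 1L) {
  M <- if (is(binned, "BinnedCounts")) binned@counts else as.matrix(binned)
  if (nrow(M) < minNeurons)
    stop("need at least ", minNeurons, " neurons for assembly detection")
  vars <- apply(M, 1, stats::var)
  kept <- which(vars > 0)
  if (length(kept) < nrow(M))
    warning(nrow(M) - length(kept), " zero-variance neuron(s) dropped")
  Z <- t(scale(t(M[kept, , drop = FALSE])))
  nN <- nrow(Z)
  nB <- ncol(Z)
  l <- marchenkoPasturLimit(nB, nN)
  C <- tcrossprod(Z) / (nB - 1)
  eig <- eigen(C, symmetric = TRUE)
  k <- sum(eig$values > l)
  weights <- matrix(numeric(), length(vars), 0)
  membersList <- list()
  if (k > 0) {
    set.seed(seed)
    V <- eig$vectors[, seq_len(k), drop = FALSE]
    ## project into the significant subspace and whiten
    Y <- t(V) %*% Z                       # k x bins, rows uncorrelated
    Y <- Y / sqrt(eig$values[seq_len(k)] * (nB - 1) / nB)
    W <- fastICADeflation(Y, k)
    pat <- V %*% t(W)                     # neurons(kept) x k
    ## unit length + orientation
    pat <- apply(pat, 2, function(w) {
      w <- w / sqrt(sum(w^2))
      if (w[which.max(abs(w))] < 0) -w else w
    })
    pat <- matrix(pat, nrow = nN)
    ## order by explained variance of the component projections
    expl <- vapply(seq_len(k), function(j)
      stats::var(drop(t(pat[, j]) %*% Z)), numeric(1))
    pat <- pat[, order(expl, decreasing = TRUE), drop = FALSE]
    ## re-embed into the full neuron set (dropped neurons get weight 0)
    weights <- matrix(0, length(vars), k)
    weights[kept, ] <- pat
    membersList <- lapply(seq_len(k), function(j) {
      w <- weights[, j]
      which(w > 2 * stats::sd(w))
    })
  }
  structure(list(weights = weights, members = membersList,
                 eigenvalueLimit = l, eigenvalues = eig$values,
                 q = nB / nN, kept = kept),
            class = "AssemblyPatterns")
}

#' Assembly activation strength over time
#'
#' Spike trains are binned at `dt`, smoothed with a Gaussian kernel whose
#' variance matches the 25 ms detection bin (SD = 25/sqrt(12) ms), and
#' z-scored; the activation of pattern w at time t is
#' A(t) = Z(t)' P Z(t) with projector P = w w' whose diagonal is zeroed so
#' isolated single-neuron firing contributes nothing.
#'
#' @param patterns an `AssemblyPatterns` object (or a weights matrix).
#' @param trains list of spike-time vectors over the same neuron set as the
#'   patterns.
#' @param duration recording duration, seconds.
#' @param dt sampling step of the trace, seconds (default 0.001).
#' @param kernelSD smoothing SD in seconds (default 0.025/sqrt(12)).
#' @param keepDiagonal keep the diagonal of the projector (default FALSE).
#' @param tStart start of the evaluated interval (default 0).
#' @return list of per-pattern numeric activation traces (class
#'   `ActivationTraces`, attribute `dt`).
#' @export
activationStrength <- function(patterns, trains, duration, dt = 0.001,
                               kernelSD = 0.025 / sqrt(12),
                               keepDiagonal = FALSE, tStart = 0) {
  W <- if (inherits(patterns, "AssemblyPatterns")) patterns$weights
       else as.matrix(patterns)
  if (nrow(W) != length(trains))
    stop("pattern weight length does not match number of spike trains")
  nb <- floor((duration - tStart) / dt)
  Z <- t(vapply(trains, function(tr) {
    t <- spikeTimes(tr) - tStart
    counts <- tabulate(floor(t[t >= 0 & t < nb * dt] / dt) + 1L, nbins = nb)
    convolveReflect(counts, gaussKernel(kernelSD / dt))
  }, numeric(nb)))
  sds <- apply(Z, 1, stats::sd)
  sds[sds == 0] <- 1
  Z <- (Z - rowMeans(Z)) / sds
  traces <- lapply(seq_len(ncol(W)), function(j) {
    w <- W[, j]
    y <- drop(crossprod(Z, w))           # (w . z_t)
    a <- y^2
    if (!keepDiagonal) a <- a - drop(crossprod(Z^2, w^2))
    a
  })
  structure(traces, class = "ActivationTraces", dt = dt)
}

#' Assembly activation events
#'
#' Events are upward crossings of the activation threshold; the mean event
#' strength is the mean activation over all above-threshold samples.
#'
#' @param trace numeric activation trace (one element of
#'   [activationStrength()]'s output).
#' @param threshold activation threshold (default 5).
#' @param dt sample step, seconds (default taken from the trace attribute).
#' @return list with `nEvents`, `eventRate` (events/min),
#'   `meanEventStrength` (NA when never above threshold).
#' @export
activationEvents <- function(trace, threshold = 5, dt = NULL) {
  if (is.null(dt)) dt <- attr(trace, "dt", exact = TRUE)
  if (is.null(dt)) dt <- 0.001
  x <- as.numeric(trace)
  above <- x > threshold
  crossings <- sum(above & !c(FALSE, above[-length(above)]))
  durMin <- length(x) * dt / 60
  list(nEvents = crossings, eventRate = crossings / durMin,
       meanEventStrength = if (any(above)) mean(x[above]) else NA_real_)
}

#' Assembly reactivation strength across recording halves
#'
#' Patterns are detected on the first half of the recording; the ratio of
#' the mean above-threshold activation strength in the second half to that
#' in the first half measures reactivation (1 = stationary expression).
#'
#' @param trains list of PYR spike-time vectors.
#' @param duration recording duration, seconds.
#' @param binWidth detection bin width, seconds (default 0.025).
#' @param threshold activation threshold (default 5).
#' @param seed RNG seed for pattern detection.
#' @param ... passed to [activationStrength()].
#' @return data.frame with one row per pattern: `pattern`, `strengthFirst`,
#'   `strengthSecond`, `ratio` (NA when the pattern never crosses threshold
#'   in the first half).
#' @export
reactivationStrength <- function(trains, duration, binWidth = 0.025,
                                 threshold = 5, seed = 1L, ...) {
  half <- duration / 2
  binned <- binSpikeCounts(trains, binWidth = binWidth, tStart = 0,
                           tEnd = half)
  pats <- detectPatterns(binned, seed = seed)
  k <- ncol(pats$weights)
  if (k == 0)
    return(data.frame(pattern = integer(), strengthFirst = numeric(),
                      strengthSecond = numeric(), ratio = numeric()))
  tr1 <- activationStrength(pats, trains, duration = half, tStart = 0, ...)
  tr2 <- activationStrength(pats, trains, duration = duration,
                            tStart = half, ...)
  do.call(rbind, lapply(seq_len(k), function(j) {
    a1 <- tr1[[j]][tr1[[j]] > threshold]
    a2 <- tr2[[j]][tr2[[j]] > threshold]
    s1 <- if (length(a1)) mean(a1) else NA_real_
    s2 <- if (length(a2)) mean(a2) else 0
    data.frame(pattern = j, strengthFirst = s1, strengthSecond = s2,
               ratio = if (is.na(s1)) NA_real_ else s2 / s1)
  }))
}

#' Member versus non-member co-firing
#'
#' Mean pairwise Pearson correlation of the binned spike counts among a
#' pattern's member neurons, compared with the mean correlation among all
#' other PYR pairs.
#'
#' @param binned a [BinnedCounts-class] or counts matrix (neurons x bins).
#' @param patterns an `AssemblyPatterns` object.
#' @return data.frame with one row per pattern (>= 2 members): `pattern`,
#'   `memberR`, `nonMemberR`.
#' @export
memberCofireCheck <- function(binned, patterns) {
  M <- if (is(binned, "BinnedCounts")) binned@counts else as.matrix(binned)
  C <- suppressWarnings(stats::cor(t(M)))
  n <- nrow(M)
  out <- lapply(seq_along(patterns$members), function(j) {
    mem <- patterns$members[[j]]
    if (length(mem) < 2L) return(NULL)
    other <- setdiff(seq_len(n), mem)
    memPairs <- C[mem, mem][upper.tri(diag(length(mem)))]
    nonPairs <- if (length(other) >= 2L)
      C[other, other][upper.tri(diag(length(other)))] else NA_real_
    data.frame(pattern = j, memberR = mean(memPairs, na.rm = TRUE),
               nonMemberR = mean(nonPairs, na.rm = TRUE))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(pattern = integer(), memberR = numeric(),
                      nonMemberR = numeric()))
  do.call(rbind, out)
}
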