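#' Filter probes by missingness
#'
#' Removes probes whose fraction of missing entries exceeds
#' \code{maxNaFraction} (one half by convention: a probe flagged unreliable
#' in at least half the arrays carries too little information).  Survivor
#' order is preserved.
#'
#' @param x an \linkS4class{ExpressionMatrix} or a numeric matrix.
#' @param maxNaFraction largest tolerated missing fraction.
#' @return object of the same class with offending probes removed.
#' @export
setGeneric("filterProbes", function(x, maxNaFraction = 0.5)
  standardGeneric("filterProbes"))

#' @rdname filterProbes
#' @export
setMethod("filterProbes", "matrix", function(x, maxNaFraction = 0.5) {
  frac <- rowMeans(is.na(x))
  keep <- frac <= maxNaFraction
  if (!any(keep))
    warning("all probes removed by the missingness filter")
  x[keep, , drop = FALSE]
})

#' @rdname filterProbes
#' @export
setMethod("filterProbes", "ExpressionMatrix", function(x,
                                                       maxNaFraction = 0.5) {
  frac <- rowMeans(is.na(exprsValues(x)))
  keep <- frac <= maxNaFraction
  if (!any(keep))
    warning("all probes removed by the missingness filter")
  x[keep, ]
})

#' Quantile normalization
#'
#' Forces every column onto the common distribution obtained by averaging
#' the columns' order statistics: each column's sorted values are replaced
#' by the across-column mean of sorted values at the same rank, preserving
#' within-column rank order.  Ties receive the mean of the tied ranks'
#' reference values.  Columns with missing entries are normalized through
#' their available values: ranks map onto the reference distribution by
#' linear interpolation of quantile position (and the reference itself is
#' then the mean of per-column quantile curves on a common grid).
#'
#' @param x an \linkS4class{ExpressionMatrix} or a numeric matrix.
#' @return object of the same class, normalized.
#' @examples
#' quantileNormalize(cbind(a = c(3, 1, 2), b = c(6, 4, 5)))
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x) {
  if (ncol(x) < 2L) {
    warning("single-column matrix: quantile normalization is the identity")
    return(x)
  }
  n <- nrow(x)
  if (!anyNA(x)) {
    ref <- rowMeans(apply(x, 2L, sort))
    refAt <- function(r) (ref[floor(r)] + ref[ceiling(r)]) / 2
    out <- apply(x, 2L, function(col)
      refAt(rank(col, ties.method = "average")))
  } else {
    grid <- (seq_len(n) - 0.5) / n
    ref <- rowMeans(vapply(seq_len(ncol(x)), function(j)
      quantile(x[, j], probs = grid, na.rm = TRUE, names = FALSE),
      numeric(n)))
    out <- apply(x, 2L, function(col) {
      ok <- !is.na(col)
      k <- sum(ok)
      r <- rank(col[ok], ties.method = "average")
      col[ok] <- approx(grid, ref, xout = (r - 0.5) / k, rule = 2)$y
      col
    })
  }
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "ExpressionMatrix", function(x) {
  SummarizedExperiment::assay(x, "exprs") <-
    quantileNormalize(exprsValues(x))
  x
})

# Per-probe two-class statistics with NA-aware group means and the pooled
# SAM scatter s = sqrt(a * (ss1 + ss2)), a = (1/n1 + 1/n2)/(n1 + n2 - 2).
samProbeStats <- function(x, idx1, idx2) {
  x1 <- x[, idx1, drop = FALSE]
  x2 <- x[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  ss1 <- rowSums((x1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x2 - m2)^2, na.rm = TRUE)
  usable <- n1 >= 2L & n2 >= 2L
  a <- (1 / n1 + 1 / n2) / (n1 + n2 - 2)
  s <- sqrt(a * (ss1 + ss2))
  s[!usable] <- NA_real_
  list(r = ifelse(usable, m1 - m2, NA_real_), s = s, usable = usable)
}

# Tusher-style exchangeability factor: the percentile of the s distribution
# (grid 0..100 by 5) minimizing the coefficient of variation of window-wise
# MADs of d, windows being 1%-quantile slices of s.
chooseS0 <- function(r, s) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- quantile(s, alphas, names = FALSE)
  qs <- unique(quantile(s, seq(0, 1, by = 0.01), names = FALSE))
  win <- cut(s, breaks = qs, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, win, mad)
    v <- v[!is.na(v) & v > 0]
    if (length(v) < 2L) return(Inf)
    sd(v) / mean(v)
  }, numeric(1L))
  cand[which.min(cv)]
}

# All (or a seeded sample of) assignments of n1 columns to group 1.
samPermutations <- function(n, n1, nPermutations, seed) {
  total <- choose(n, n1)
  if (total <= nPermutations) {
    asplit(utils::combn(n, n1), 2L)
  } else {
    withSeed(seed, replicate(nPermutations, sort(sample.int(n, n1)),
                             simplify = FALSE))
  }
}

#' Two-class significance analysis of microarrays (SAM)
#'
#' Moderated d statistic \eqn{d_i = (\bar x_{i1} - \bar x_{i2})/(s_i +
#' s_0)} with the exchangeability factor \eqn{s_0} chosen to minimize the
#' coefficient of variation of \eqn{d}'s spread across the range of
#' \eqn{s}; the null distribution comes from balanced relabelings of the
#' columns (all distinct relabelings when fewer exist than
#' \code{nPermutations}, otherwise a seeded sample).  Probes are called at
#' threshold \code{delta} on the gap between observed and expected order
#' statistics; the FDR estimate is the median number of permuted scores
#' beyond the implied cutpoints, scaled by the estimated null proportion
#' \eqn{\pi_0} (from the central 50\% of the permuted scores) and divided
#' by the number of calls.  Probes with fewer than two usable values in a
#' group, or zero spread when \eqn{s_0 = 0}, are flagged and excluded from
#' calling.
#'
#' @param x an \linkS4class{ExpressionMatrix}, or a numeric matrix with
#'   \code{groups} supplied.
#' @param groups two-level label per column (taken from \code{colData} for
#'   an \linkS4class{ExpressionMatrix}).  The first label in order of
#'   appearance is "group 1" (the minuend of the contrast).
#' @param nPermutations upper bound on permutations.
#' @param delta calling threshold; leave \code{NULL} to tune it to
#'   \code{targetFdr}.
#' @param targetFdr when \code{delta} is \code{NULL}, the smallest
#'   \code{delta} whose FDR estimate is at most this value is used.
#' @param s0 optionally fix the exchangeability factor (e.g. 0 to reproduce
#'   the plain pooled-variance statistic).
#' @param seed RNG seed for permutation sampling.
#' @return a \linkS4class{SamResult}.
#' @export
samTwoClass <- function(x, groups = NULL, nPermutations = 1000L,
                        delta = NULL, targetFdr = 0.07, s0 = NULL,
                        seed = 1L) {
  if (is(x, "ExpressionMatrix")) {
    groups <- sampleGroups(x)
    x <- exprsValues(x)
  }
  if (is.null(groups)) stop("groups must be supplied for a plain matrix")
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two group labels are required")
  idx1 <- which(groups == lv[1L])
  idx2 <- which(groups == lv[2L])
  if (length(idx1) < 2L || length(idx2) < 2L)
    stop("both groups need at least 2 columns")
  if (is.null(rownames(x)))
    rownames(x) <- paste0("probe_", seq_len(nrow(x)))

  obs <- samProbeStats(x, idx1, idx2)
  if (is.null(s0)) s0 <- chooseS0(obs$r[obs$usable], obs$s[obs$usable])
  denomOk <- obs$usable & (obs$s + s0) > 0
  d <- ifelse(denomOk, obs$r / (obs$s + s0), NA_real_)
  names(d) <- rownames(x)
  flagged <- rownames(x)[!denomOk]

  perms <- samPermutations(ncol(x), length(idx1), nPermutations, seed)
  permD <- vapply(perms, function(g1) {
    st <- samProbeStats(x, g1, setdiff(seq_len(ncol(x)), g1))
    ifelse(st$usable & (st$s + s0) > 0, st$r / (st$s + s0), NA_real_)
  }, numeric(nrow(x)))
  if (!is.matrix(permD)) permD <- matrix(permD, nrow = nrow(x))

  dObs <- sort(d[denomOk])
  permSorted <- apply(permD[denomOk, , drop = FALSE], 2L, sort,
                      na.last = TRUE)
  if (!is.matrix(permSorted))
    permSorted <- matrix(permSorted, ncol = length(perms))
  dBar <- rowMeans(permSorted, na.rm = TRUE)
  diffs <- dObs - dBar

  allPerm <- permD[denomOk, , drop = FALSE]
  q2575 <- quantile(allPerm, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  pi0 <- min(1, sum(dObs >= q2575[1L] & dObs <= q2575[2L]) /
                  (0.5 * length(dObs)))

  origin <- which.min(abs(dObs))   # scan outward from d ~ 0
  evalDelta <- function(del) {
    iUp <- which(diffs >= del & seq_along(diffs) >= origin)
    iDn <- which(diffs <= -del & seq_along(diffs) <= origin)
    cutUp <- if (length(iUp)) dObs[min(iUp)] else Inf
    cutLow <- if (length(iDn)) dObs[max(iDn)] else -Inf
    up <- !is.na(d) & d >= cutUp
    down <- !is.na(d) & d <= cutLow & !up
    nCalled <- sum(up) + sum(down)
    if (nCalled == 0L)
      return(list(fdr = NA_real_, up = character(0L), down = character(0L),
                  cutUp = cutUp, cutLow = cutLow, nCalled = 0L))
    falseMed <- median(apply(allPerm, 2L, function(p)
      sum(p >= cutUp, na.rm = TRUE) + sum(p <= cutLow, na.rm = TRUE)))
    list(fdr = min(1, pi0 * falseMed / nCalled),
         up = names(d)[up], down = names(d)[down],
         cutUp = cutUp, cutLow = cutLow, nCalled = nCalled)
  }

  if (is.null(delta)) {
    candidates <- sort(unique(c(0, abs(diffs))))
    if (length(candidates) > 200L)
      candidates <- candidates[unique(round(seq(1L, length(candidates),
                                                length.out = 200L)))]
    delta <- max(candidates) + 1   # fallback: call nothing
    for (del in candidates) {
      res <- evalDelta(del)
      if (res$nCalled > 0L && !is.na(res$fdr) && res$fdr <= targetFdr) {
        delta <- del
        break
      }
    }
  }
  res <- evalDelta(delta)
  new("SamResult", dScores = d, s0 = as.numeric(s0),
      delta = as.numeric(delta),
      fdrEstimate = res$fdr, pi0 = pi0,
      significantUp = res$up, significantDown = res$down,
      cutUp = res$cutUp, cutLow = res$cutLow, flagged = flagged,
      nPermutations = length(perms), seed = as.integer(seed))
}

#' Log2 fold change of two positive means
#'
#' @param meanTreated,meanControl positive group means (linear scale).
#' @return \code{log2(meanTreated / meanControl)}.
#' @export
log2FoldChange <- function(meanTreated, meanControl) {
  if (any(meanTreated <= 0) || any(meanControl <= 0))
    stop("means must be positive")
  log2(meanTreated / meanControl)
}

#' Hypergeometric gene-set overlap enrichment
#'
#' Exact upper-tail probability \eqn{P(X \ge k)} of drawing at least
#' \code{k} annotated genes when \code{n} genes are drawn without
#' replacement from a universe of \code{N} genes of which \code{K} are
#' annotated (e.g. predicted microRNA targets among the differentially
#' expressed set).
#'
#' @param N universe size.
#' @param K annotated genes in the universe.
#' @param n genes drawn (e.g. the DE list).
#' @param k observed overlap.
#' @return p-value in (0, 1].
#' @examples
#' hypergeometricEnrichment(N = 10, K = 5, n = 5, k = 5)  # 1/252
#' @export
hypergeometricEnrichment <- function(N, K, n, k) {
  if (K > N || n > N || k > min(K, n) || k < 0 || N < 0)
    stop("invalid enrichment input: need k <= min(K, n), K <= N, n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Relative quantification by the 2^-ddCt method
#'
#' \deqn{RQ = 2^{-[(Ct_{target,sample} - Ct_{ref,sample}) -
#'   (Ct_{target,calibrator} - Ct_{ref,calibrator})]}}
#' Replicate Ct values are averaged before the formula.
#'
#' @param ctTargetSample,ctRefSample,ctTargetCalibrator,ctRefCalibrator
#'   cycle-threshold values (vectors of replicates are averaged).
#' @return the relative quantity RQ.
#' @examples
#' deltaDeltaCt(20, 18, 24, 19)   # ddCt = -3, RQ = 8
#' @export
deltaDeltaCt <- function(ctTargetSample, ctRefSample,
                         ctTargetCalibrator, ctRefCalibrator) {
  cts <- list(ctTargetSample, ctRefSample, ctTargetCalibrator,
              ctRefCalibrator)
  if (!all(vapply(cts, function(v) all(is.finite(v)), logical(1L))))
    stop("all Ct values must be finite")
  m <- vapply(cts, mean, numeric(1L))
  ddct <- (m[1L] - m[2L]) - (m[3L] - m[4L])
  2^(-ddct)
}

#' @param ctTable a table from \code{\link{simulateQpcrCt}} (columns assay,
#'   condition, ct).
#' @rdname deltaDeltaCt
#' @export
rqFromCtTable <- function(ctTable) {
  cell <- function(a, cond)
    ctTable$ct[ctTable$assay == a & ctTable$condition == cond]
  deltaDeltaCt(cell("target", "sample"), cell("reference", "sample"),
               cell("target", "calibrator"), cell("reference", "calibrator"))
}

#' Background-relative staining intensity
#'
#' \code{100 * (signal - background) / background}, the percentage used for
#' quantifying immunofluorescence against the local background.
#'
#' @param signal,background mean pixel values; \code{background} must be
#'   positive.
#' @return intensity percentage.
#' @export
perIntensity <- function(signal, background) {
  if (any(background <= 0)) stop("background must be positive")
  100 * (signal - background) / background
}

#' Dual-luciferase relative activity
#'
#' Firefly/Renilla ratio normalized to the same ratio in negative-control
#' transfected cells.
#'
#' @param firefly,renilla luminescence readings; \code{renilla} positive.
#' @param controlRatio Firefly/Renilla ratio of the negative control.
#' @return relative activity (1 = no effect).
#' @export
luciferaseRelativeActivity <- function(firefly, renilla, controlRatio) {
  if (any(renilla <= 0) || any(controlRatio <= 0))
    stop("renilla and controlRatio must be positive")
  (firefly / renilla) / controlRatio
}

#' Read/write a tab-delimited expression matrix
#'
#' First column carries the probe id, the header row the sample labels,
#' missing values are the literal string \code{NA}.  Group labels default
#' to the sample labels with a trailing \code{_<n>} replicate suffix
#' stripped.
#'
#' @param path file path.
#' @param groups optional explicit group label per sample column.
#' @return \code{readExpressionMatrix}: an \linkS4class{ExpressionMatrix}.
#' @export
readExpressionMatrix <- function(path, groups = NULL) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- as.character(df[[1L]])
  if (is.null(groups)) groups <- sub("_[0-9]+$", "", colnames(vals))
  ExpressionMatrix(vals, groups = groups)
}

#' @param x an \linkS4class{ExpressionMatrix}.
#' @rdname readExpressionMatrix
#' @export
writeExpressionMatrix <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), exprsValues(x),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predicted-target gene list
#'
#' Plain text, one gene id per line; blank lines and \code{#} comments are
#' ignored.
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
readTargetList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
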