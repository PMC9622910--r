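# Significance Analysis of Microarrays: two-class permutation d-statistic
# with a coefficient-of-variation fudge factor, expected order statistics
# from label permutations, and delta-threshold FDR estimation.

# Per-permutation class means and pooled scatters, fully vectorised:
# X is features x samples, P a samples x B indicator matrix of class-2
# membership.  Returns list(r = mean2 - mean1, s = pooled scatter).
.samStats <- function(X, P) {
  n <- ncol(X)
  n2 <- colSums(P)
  n1 <- n - n2
  S2 <- X %*% P                 # class-2 per-feature sums
  S1 <- rowSums(X) - S2
  Q2 <- (X * X) %*% P
  Q1 <- rowSums(X * X) - Q2
  m1 <- sweep(S1, 2, n1, "/")
  m2 <- sweep(S2, 2, n2, "/")
  ss <- (Q1 - sweep(S1^2, 2, n1, "/")) + (Q2 - sweep(S2^2, 2, n2, "/"))
  a <- (1 / n1 + 1 / n2) / (n - 2)
  s <- sqrt(sweep(ss, 2, a, "*"))
  list(r = m2 - m1, s = s)
}

# Tusher CV-minimisation: candidate s0 values are percentiles of s; choose
# the one minimising the coefficient of variation of the d-spread across
# s-quantile windows.
.chooseS0 <- function(r, s) {
  cand <- unique(quantile(s, seq(0, 1, by = 0.05), names = FALSE))
  nbin <- if (length(s) >= 500) 100L else max(2L, length(s) %/% 10L)
  binIdx <- cut(rank(s, ties.method = "first"), breaks = nbin,
                labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, binIdx, mad)
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

# All distinct two-class label assignments if their number is <= nPerm,
# else nPerm random label permutations.  Returns samples x B indicator
# matrix (class-2 membership); first column is the observed labelling.
.permMatrix <- function(isClass2, nPerm) {
  n <- length(isClass2)
  n2 <- sum(isClass2)
  nDistinct <- choose(n, n2)
  if (nDistinct <= nPerm) {
    combs <- combn(n, n2)
    P <- matrix(0, n, ncol(combs))
    P[cbind(as.vector(combs),
            rep(seq_len(ncol(combs)), each = n2))] <- 1
    exact <- TRUE
  } else {
    P <- vapply(seq_len(nPerm), function(b)
      as.numeric(seq_len(n) %in% sample.int(n, n2)), numeric(n))
    exact <- FALSE
  }
  attr(P, "exact") <- exact
  P
}

#' SAM two-class permutation test
#'
#' Computes the SAM relative difference
#' \eqn{d_i = (\bar x_{i2} - \bar x_{i1}) / (s_i + s_0)} with the Tusher
#' pooled scatter \eqn{s_i} and a fudge factor \eqn{s_0} chosen by the
#' coefficient-of-variation criterion over percentiles of \eqn{s}.  The
#' null distribution of ordered \eqn{d} values comes from class-label
#' permutations (all distinct assignments when fewer than `nPerm` exist).
#' The threshold `delta` is the smallest value whose estimated FDR (median
#' permutation false calls divided by observed calls) is at or below
#' `fdrTarget`.
#'
#' @param X Feature-by-sample numeric matrix.
#' @param labels Two-class vector (factor or character), one per sample;
#'   the first level is class 1, `d > 0` means higher in class 2.
#' @param nPerm Maximum number of permutations (default 5000).
#' @param fdrTarget Target FDR for the delta threshold (default 0.05).
#' @param seed RNG seed for permutation sampling.
#' @return A [SamResult-class].
#' @references Tusher, Tibshirani & Chu (2001) PNAS 98:5116-5121.
#' @export
samTwoClass <- function(X, labels, nPerm = 5000L, fdrTarget = 0.05,
                        seed = NULL) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("samTwoClass needs exactly two classes")
  if (any(table(labels) < 2L)) stop("each class needs at least 2 samples")
  if (is.null(rownames(X))) rownames(X) <- sprintf("f%05d", seq_len(nrow(X)))
  isClass2 <- labels == levels(labels)[2L]

  P <- withSeed(seed, .permMatrix(isClass2, nPerm))
  obs <- .samStats(X, matrix(as.numeric(isClass2), ncol = 1))
  r <- obs$r[, 1]; s <- obs$s[, 1]
  s0 <- .chooseS0(r, s)
  d <- r / (s + s0)

  perm <- .samStats(X, P)
  D <- perm$r / (perm$s + s0)          # features x B
  Dsort <- apply(D, 2, sort)
  dbar <- rowMeans(Dsort)
  ord <- order(d)
  dord <- d[ord]

  # candidate deltas from the observed deviations around the expected
  # order statistics
  diffs <- dord - dbar
  deltas <- sort(unique(c(0, abs(diffs))))
  # cap the grid so delta selection stays O(few hundred) FDR evaluations
  if (length(deltas) > 400L)
    deltas <- sort(unique(c(0, quantile(abs(diffs),
                                        seq(0, 1, length.out = 400L),
                                        names = FALSE))))
  best <- NULL
  for (delta in deltas) {
    upIdx <- which(diffs >= delta & dbar >= 0)
    loIdx <- which(-diffs >= delta & dbar <= 0)
    cutup <- if (length(upIdx)) dord[min(upIdx)] else Inf
    cutlow <- if (length(loIdx)) dord[max(loIdx)] else -Inf
    called <- sum(d >= cutup | d <= cutlow)
    if (called == 0) next
    falseCalls <- colSums(D >= cutup) + colSums(D <= cutlow)
    fdr <- median(falseCalls) / called
    if (fdr <= fdrTarget) {
      best <- list(delta = delta, fdr = fdr, cutup = cutup,
                   cutlow = cutlow)
      break
    }
  }
  if (is.null(best))
    best <- list(delta = Inf, fdr = NA_real_, cutup = Inf, cutlow = -Inf)

  sigIdx <- which(d >= best$cutup | d <= best$cutlow)
  sig <- data.frame(feature = rownames(X)[sigIdx], d = d[sigIdx],
                    direction = ifelse(d[sigIdx] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  new("SamResult", d = setNames(d, rownames(X)),
      s = setNames(s, rownames(X)),
      s0 = s0, dbar = dbar, delta = best$delta, fdr = best$fdr,
      cutlow = best$cutlow, cutup = best$cutup, significant = sig,
      nPerm = ncol(P), seed = if (is.null(seed)) NA_integer_
                             else as.integer(seed))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement (a thin, validated
#' wrapper around [stats::p.adjust]).
#'
#' @param p Numeric p-values in \eqn{[0,1]}.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}
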