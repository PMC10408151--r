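# Independent brute-force oracles used to check the package's
# implementations on small inputs.

# Affine-gap local alignment score by Gotoh dynamic programming, with
# the first gap residue costing `open` and each further one `extend`
# (the convention of the reconciliation scoring). Returns the optimal
# local score.
oracleLocalAlignScore <- function(a, b, match = 5, mismatch = -4,
                                  open = -4, extend = -0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  M <- matrix(-Inf, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(0, M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] + open, Ix[i, j + 1] + extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] + open, Iy[i + 1, j] + extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Score of the local alignment induced by a projectToQuery column map
# (canonical position -> isoform position over covered columns), under
# the same affine convention. Consecutive mapped pairs contribute their
# substitution scores; skipped residues on either side contribute one
# affine gap each.
inducedAlignScore <- function(map, isoform, canonical, match = 5,
                              mismatch = -4, open = -4, extend = -0.5) {
  covered <- which(!is.na(map))
  if (!length(covered)) return(0)
  A <- strsplit(isoform, "")[[1]]
  B <- strsplit(canonical, "")[[1]]
  pen <- function(k) if (k <= 0) 0 else open + (k - 1) * extend
  total <- 0
  for (idx in seq_along(covered)) {
    cPos <- covered[idx]
    pPos <- map[cPos]
    total <- total +
      (if (A[pPos] == B[cPos]) match else mismatch)
    if (idx > 1) {
      total <- total + pen(cPos - covered[idx - 1] - 1) +
        pen(pPos - map[covered[idx - 1]] - 1)
    }
  }
  total
}

# Pairwise pair-counting AUROC with half-credit ties.
oracleAuc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos)
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Threshold-sweep specificity at sensitivity: scan all candidate score
# cutoffs, keep the largest one classifying >= s of pathogenic variants
# as pathogenic (score >= cutoff), return the benign fraction below it.
oracleSpecAtSens <- function(labels, scores, s) {
  path <- scores[labels == 1]
  ben <- scores[labels == 0]
  best <- NA_real_
  for (t in sort(unique(scores), decreasing = TRUE)) {
    if (mean(path >= t) >= s) {
      best <- mean(ben < t)
      break
    }
  }
  best
}

# Brute-force window choice: among covering windows holding a score,
# the minimal |position - center| with earlier-window tie-break.
oracleStitch <- function(windows, perWindowScores, position) {
  bestScore <- NA_real_
  bestDist <- Inf
  for (k in seq_len(nrow(windows))) {
    if (is.na(perWindowScores[k])) next
    if (position < windows$start[k] || position > windows$end[k]) next
    d <- abs(position - (windows$start[k] + windows$end[k]) / 2)
    if (d < bestDist) {
      bestDist <- d
      bestScore <- perWindowScores[k]
    }
  }
  bestScore
}

# Exhaustive-sort weighted-KNN imputation of one target column in a
# plain feature matrix: rank helpers by |Spearman| with the target,
# standardise and weight them, then for each missing cell sort all
# reference rows by the dimension-rescaled Euclidean distance and
# average the ten nearest target values.
oracleKnnImpute <- function(X, target, nNeighbors = 10,
                            nHelpers = 5) {
  y <- X[, target]
  others <- setdiff(colnames(X), target)
  rho <- sapply(others, function(cn) {
    ok <- !is.na(X[, cn]) & !is.na(y)
    if (sum(ok) < 3) return(0)
    if (sd(X[ok, cn]) == 0 || sd(y[ok]) == 0) return(0)
    suppressWarnings(cor(X[ok, cn], y[ok], method = "spearman"))
  })
  ord <- order(-abs(rho), seq_along(others))
  helpers <- others[ord][seq_len(min(nHelpers, length(others)))]
  weights <- abs(rho[helpers])
  helpers <- helpers[weights > 0]
  weights <- weights[weights > 0]
  std <- function(v) {
    s <- sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) s <- 1
    (v - mean(v, na.rm = TRUE)) / s
  }
  W <- sapply(helpers, function(cn) std(X[, cn]) * weights[cn])
  if (length(helpers) <= 1)
    W <- matrix(W, ncol = length(helpers))
  obs <- which(!is.na(y))
  ty <- std(y)
  refW <- cbind(W[obs, , drop = FALSE], ty[obs])
  out <- y
  total <- ncol(refW)
  if (!length(helpers)) {
    k <- min(nNeighbors, length(obs))
    out[is.na(y)] <- mean(y[obs][seq_len(k)])
    return(out)
  }
  for (i in which(is.na(y))) {
    q <- c(W[i, ], NA)
    d <- apply(refW, 1, function(r) {
      ok <- !is.na(q) & !is.na(r)
      if (!sum(ok)) return(NA_real_)
      sqrt(total / sum(ok) * sum((q[ok] - r[ok])^2))
    })
    nb <- order(d, seq_along(d), na.last = TRUE)
    nb <- nb[!is.na(d[nb])]
    if (!length(nb)) next
    k <- min(nNeighbors, length(nb))
    out[i] <- mean(y[obs][nb[seq_len(k)]])
  }
  out
}

# Hand enumeration of conditioned frequencies: keep rows matching the
# query amino acid at every conditioning column, then count.
oracleConditioned <- function(rows, query, position, wt, mut,
                              conditioning, minRows = 1) {
  keep <- rep(TRUE, length(rows))
  for (cpos in conditioning) {
    qa <- substr(query, cpos, cpos)
    keep <- keep & (substr(rows, cpos, cpos) == qa)
  }
  col <- substr(rows[keep], position, position)
  if (length(col) < minRows)
    return(c(NA_real_, NA_real_))
  c(log1p(mean(col == wt)), log1p(mean(col == mut)))
}
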