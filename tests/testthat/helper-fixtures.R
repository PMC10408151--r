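# Small fixture builders shared across test files.

makeMsa <- function(rows, gene = "G1", source = "vert100") {
  AnchoredMSA(gene = gene, rows = rows, source = source)
}

# Random anchored MSA over the standard alphabet (plus gaps in
# non-query rows).
randomMsa <- function(L = 8, depth = 6, gene = "G1", source = "deep",
                      gapRate = 0.1) {
  query <- paste(sample(AA_STANDARD, L, replace = TRUE), collapse = "")
  rows <- c(query, replicate(depth - 1, {
    cells <- sample(c(AA_STANDARD, "-"), L, replace = TRUE,
                    prob = c(rep((1 - gapRate) / 20, 20), gapRate))
    paste(cells, collapse = "")
  }))
  makeMsa(rows, gene = gene, source = source)
}

# Correlated random feature matrix with controlled missingness in the
# target column (and optionally elsewhere); guarantees at least
# minObserved observed target values.
randomImputeTable <- function(n, p, missFrac, minObserved = 12) {
  latent <- rnorm(n)
  X <- sapply(seq_len(p), function(j)
    0.8 * latent + rnorm(n, 0, runif(1, 0.3, 1.5)))
  colnames(X) <- paste0("f", seq_len(p))
  for (j in seq_len(p)) {
    nMiss <- rbinom(1, n, missFrac)
    if (j == 1) nMiss <- min(nMiss, n - minObserved)
    if (nMiss > 0)
      X[sample(n, nMiss), j] <- NA
  }
  if (all(is.na(X[, 1]))) X[seq_len(minObserved), 1] <- rnorm(minObserved)
  X
}

asFeatureTable <- function(X, gene = "G1") {
  n <- nrow(X)
  wt <- sample(AA_STANDARD, n, replace = TRUE)
  mut <- vapply(wt, function(a) sample(setdiff(AA_STANDARD, a), 1), "")
  keys <- data.frame(gene = gene, position = seq_len(n), wt = wt,
                     mut = unname(mut), stringsAsFactors = FALSE)
  FeatureTable(keys, X)
}

# A minimal PDB file with one CA and one CB atom per residue.
writeToyPDB <- function(path, bfactors, cbOffset = 1.5,
                        spacing = 3.8, dropBfactor = FALSE) {
  lines <- character(0)
  serial <- 1
  for (i in seq_along(bfactors)) {
    x <- (i - 1) * spacing
    for (atom in c("CA", "CB")) {
      y <- if (atom == "CB") cbOffset else 0
      line <- sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
        serial, atom, i, x, y, 0, bfactors[i])
      if (dropBfactor) line <- substr(line, 1, 54)
      lines <- c(lines, line)
      serial <- serial + 1
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# Feature tables + DMS datasets with a planted linear signal and
# per-gene affine batch effects; used for model and selection tests.
plantedFamily <- function(nGenes = 4, n = 120, coef = NULL,
                          noiseSd = 0, seed = 42) {
  withr::with_seed(seed, {
    featNames <- names(coef)
    tables <- list()
    dms <- list()
    for (k in seq_len(nGenes)) {
      g <- sprintf("P%d", k)
      X <- matrix(rnorm(n * length(featNames)), n,
                  dimnames = list(NULL, featNames))
      latent <- drop(X %*% coef)
      a <- rnorm(1)
      b <- runif(1, 0.8, 1.4)
      score <- a + b * latent + rnorm(n, 0, noiseSd)
      tables[[g]] <- asFeatureTable(X, gene = g)
      dms[[g]] <- DMSDataset(g, data.frame(
        tables[[g]]@keys[, c("position", "wt", "mut")], score = score))
    }
    list(tables = tables, dms = dms)
  })
}
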