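test_that("helper selection ranks by absolute rank correlation", {
  withr::with_seed(51, {
    n <- 30
    y <- rnorm(n)
    X <- cbind(target = y,
               up = y,              # rho = +1
               down = -y,           # rho = -1
               noise = sample(y),   # |rho| small
               flat = rep(2, n))    # undefined rho -> 0, excluded
    X[sample(n, 6), "target"] <- NA
    ft <- asFeatureTable(X)
    imp <- fitWeightedKnn(ft, "target",
                          imputerSpec(nHelperFeatures = 2))
    expect_setequal(imp$helpers, c("up", "down"))
    expect_equal(unname(imp$weights[imp$helpers == "up"]), 1)
    imp4 <- fitWeightedKnn(ft, "target",
                           imputerSpec(nHelperFeatures = 4))
    expect_false("flat" %in% imp4$helpers)  # zero-variance excluded
  })
})

test_that("too few observed targets signals the cross-gene fallback", {
  X <- matrix(rnorm(40), 10, dimnames = list(NULL, paste0("f", 1:4)))
  X[1:5, 1] <- NA
  ft <- asFeatureTable(X)
  expect_error(fitWeightedKnn(ft, "f1"), class = "cptTooFewObserved")
})

test_that("within-gene imputation averages the nearest reference rows", {
  withr::with_seed(52, {
    # constant reference target: every imputed value equals it
    X <- cbind(t = c(rep(3.5, 12), NA, NA), h = rnorm(14))
    colnames(X) <- c("t", "h")
    ft <- asFeatureTable(X)
    imp <- fitWeightedKnn(ft, "t")
    out <- imputeWithinGene(imp, ft)
    expect_equal(out[13:14], c(3.5, 3.5))
    expect_equal(out[1:12], X[1:12, "t"])  # observed cells untouched

    # no missing cells: identity
    X2 <- matrix(rnorm(48), 12, dimnames = list(NULL, c("a", "b", "c", "d")))
    ft2 <- asFeatureTable(X2)
    imp2 <- fitWeightedKnn(ft2, "a")
    expect_identical(imputeWithinGene(imp2, ft2), X2[, "a"])
  })
})

test_that("a 12-row toy gene matches the exhaustive-sort oracle", {
  withr::with_seed(53, {
    X <- randomImputeTable(12, 4, missFrac = 0)
    X[7, 1] <- NA
    ft <- asFeatureTable(X)
    imp <- fitWeightedKnn(ft, "f1")
    expect_equal(imputeWithinGene(imp, ft),
                 oracleKnnImpute(X, "f1"))
  })
})

test_that("imputed values stay inside the observed target range", {
  withr::with_seed(54, {
    for (rep in 1:10) {
      X <- randomImputeTable(sample(25:50, 1), sample(3:6, 1), 0.2)
      ft <- asFeatureTable(X)
      imp <- fitWeightedKnn(ft, "f1")
      out <- suppressWarnings(imputeWithinGene(imp, ft))
      filled <- out[is.na(X[, "f1"]) & !is.na(out)]
      if (length(filled)) {
        expect_true(all(filled >= min(X[, "f1"], na.rm = TRUE)))
        expect_true(all(filled <= max(X[, "f1"], na.rm = TRUE)))
      }
    }
  })
})

test_that("row order does not change imputed values", {
  withr::with_seed(55, {
    X <- randomImputeTable(30, 5, 0.15)
    ft <- asFeatureTable(X)
    out <- suppressWarnings(
      imputeWithinGene(fitWeightedKnn(ft, "f1"), ft))
    perm <- sample(nrow(X))
    Xp <- X[perm, ]
    ftp <- asFeatureTable(Xp)
    outp <- suppressWarnings(
      imputeWithinGene(fitWeightedKnn(ftp, "f1"), ftp))
    expect_equal(outp[order(perm)], out, tolerance = 1e-12)
  })
})

test_that("cross-gene imputation averages the per-gene predictions", {
  withr::with_seed(56, {
    imps <- lapply(1:5, function(k) {
      X <- randomImputeTable(30, 4, 0)
      fitWeightedKnn(asFeatureTable(X, gene = paste0("T", k)), "f1")
    })
    Xnew <- randomImputeTable(15, 4, 0)
    Xnew[, "f1"] <- NA
    ftNew <- asFeatureTable(Xnew, gene = "NEW")
    out <- imputeCrossGene(imps, ftNew)
    perImp <- sapply(imps, function(im)
      sapply(seq_len(nrow(Xnew)), function(i)
        cptransfer:::.knnPredictRow(im, featureMatrix(ftNew)[i, ])))
    expect_equal(out, rowMeans(perImp))
    # order of the imputers is irrelevant
    expect_equal(imputeCrossGene(rev(imps), ftNew), out)

    # an imputer whose helpers are absent is skipped with a warning
    Xodd <- randomImputeTable(30, 4, 0)
    colnames(Xodd) <- c("f1", "g2", "g3", "g4")
    imps2 <- c(imps[1:4],
               list(fitWeightedKnn(asFeatureTable(Xodd, "T5"), "f1")))
    expect_warning(out2 <- imputeCrossGene(imps2, ftNew), "skipped")
    expect_equal(out2, rowMeans(perImp[, 1:4]))
  })
})

test_that("degenerate cross-gene predictions behave arithmetically", {
  # five imputers all built on identical data predict identically
  withr::with_seed(57, {
    X <- randomImputeTable(25, 4, 0)
    imp <- fitWeightedKnn(asFeatureTable(X), "f1")
    Xnew <- randomImputeTable(8, 4, 0)
    Xnew[, "f1"] <- NA
    ftNew <- asFeatureTable(Xnew, "NEW")
    single <- imputeCrossGene(list(imp), ftNew)
    five <- imputeCrossGene(rep(list(imp), 5), ftNew)
    expect_equal(five, single)
  })
})

test_that("family-level completion removes all missingness it can", {
  withr::with_seed(58, {
    tabs <- lapply(1:3, function(k) {
      X <- randomImputeTable(40, 5, 0.1)
      asFeatureTable(X, gene = paste0("P", k))
    })
    names(tabs) <- paste0("P", 1:3)
    # one gene entirely missing a column: cross-gene route
    m <- featureMatrix(tabs$P2)
    m[, "f2"] <- NA
    tabs$P2@features <- m
    done <- suppressWarnings(completeFeatures(tabs))
    expect_false(anyNA(featureMatrix(done$P2)[, "f2"]))
  })
})
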