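toyDMS <- function(scores, gene = "G1") {
  n <- length(scores)
  DMSDataset(gene, data.frame(position = seq_len(n), wt = "A",
                              mut = rep_len(c("V", "W", "Y"), n),
                              score = scores))
}

test_that("percentile binarisation labels the score tails", {
  lab <- binarizeDMS(toyDMS(1:10))
  expect_equal(lab$label[match(1:4, lab$position)], rep(1, 4))
  expect_equal(lab$label[match(7:10, lab$position)], rep(0, 4))
  expect_false(any(c(5, 6) %in% lab$position))

  lab5 <- binarizeDMS(toyDMS(c(5, 1, 3, 2, 4, 9, 8, 7, 6, 10)))
  expect_equal(sum(lab5$label == 1), 4)
  expect_equal(sum(lab5$label == 0), 4)
  expect_error(binarizeDMS(toyDMS(1:9)), "too few")
})

test_that("tied scores split by stable input order with exact counts", {
  lab <- binarizeDMS(toyDMS(rep(1, 10)))
  expect_equal(sum(lab$label == 1), 4)
  expect_equal(sum(lab$label == 0), 4)
  # stable order: earliest records become the bottom band
  expect_equal(lab$position[lab$label == 1], 1:4)
  expect_equal(lab$position[lab$label == 0], 7:10)
})

test_that("binarisation counts are exactly floor(0.4 n) in a sweep", {
  withr::with_seed(61, {
    for (n in c(10, 11, 17, 25, 52, 103)) {
      lab <- binarizeDMS(toyDMS(rnorm(n)))
      expect_equal(sum(lab$label == 1), floor(0.4 * n))
      expect_equal(sum(lab$label == 0), floor(0.4 * n))
    }
  })
})

test_that("rescaling uses protein-reweighted standard deviations", {
  X <- cbind(f1 = c(1, 3, 5, 7), f2 = rep(2, 4))  # sd(f1) pop = sqrt(5)
  ft <- asFeatureTable(X)
  expect_warning(sc <- fitRescaler(list(G1 = ft)), "zero weighted sd")
  expect_equal(unname(sc["f1"]), 1 / sqrt(5))
  expect_equal(unname(sc["f2"]), 1)

  # a feature with per-row weights 1/n_p: std 2 -> scale 0.5
  X2 <- cbind(f1 = c(-2, 2, -2, 2))
  sc2 <- fitRescaler(list(G1 = asFeatureTable(X2)))
  expect_equal(unname(sc2["f1"]), 0.5)
})

test_that("duplicating a protein's rows leaves the scales unchanged", {
  withr::with_seed(62, {
    tabs <- list(P1 = asFeatureTable(matrix(rnorm(60), 20,
                                            dimnames = list(NULL, c("a", "b", "c"))),
                                     "P1"),
                 P2 = asFeatureTable(matrix(rnorm(30), 10,
                                            dimnames = list(NULL, c("a", "b", "c"))),
                                     "P2"))
    sc <- fitRescaler(tabs)
    dupX <- rbind(featureMatrix(tabs$P2), featureMatrix(tabs$P2))
    tabs2 <- list(P1 = tabs$P1, P2 = asFeatureTable(dupX, "P2"))
    expect_equal(fitRescaler(tabs2), sc, tolerance = 1e-12)
  })
})

test_that("frequency-flagged columns keep scale exactly one", {
  X <- cbind(vert100_wt_freq_log = runif(12, 0, log(2)),
             other = rnorm(12, sd = 4))
  keys <- asFeatureTable(X)@keys
  ft <- FeatureTable(keys, X, frequency = "vert100_wt_freq_log")
  sc <- fitRescaler(list(G1 = ft))
  expect_identical(unname(sc["vert100_wt_freq_log"]), 1)
  expect_false(sc["other"] == 1)
})

test_that("noise-free regression recovers the generative coefficients", {
  fam <- plantedFamily(nGenes = 2, n = 60, coef = c(x1 = 2, x2 = -1))
  model <- fitCPT(fam$tables, fam$dms, c("x1", "x2"),
                  trainingConfig(task = "regression", l2 = 0))
  for (g in names(model@perProteinModels)) {
    beta <- model@perProteinModels[[g]]$coefficients
    # coefficients act on the scaled space: unscale and remove the
    # per-protein batch factor via the ratio
    raw <- beta * model@scale
    expect_equal(unname(raw["x1"] / raw["x2"]), -2, tolerance = 1e-8)
    expect_gt(raw["x1"], 0)
    expect_lt(raw["x2"], 0)
  }
})

test_that("separable classification orients its boundary correctly", {
  n <- 40
  x <- c(seq(-2, -0.5, length.out = n / 2), seq(0.5, 2, length.out = n / 2))
  X <- cbind(x1 = x)
  tabs <- list(P1 = asFeatureTable(X, "P1"))
  # low assay score (abnormal, label 1) at low x1
  dms <- list(P1 = DMSDataset("P1", data.frame(
    tabs$P1@keys[, c("position", "wt", "mut")], score = x)))
  model <- fitCPT(tabs, dms, "x1", trainingConfig())
  beta <- model@perProteinModels$P1$coefficients
  expect_lt(beta[["x1"]], 0)  # high x1 = high fitness = low abnormality
  preds <- predictEnsemble(model, tabs$P1)
  expect_gt(mean(preds[x < 0]), mean(preds[x > 0]))
})

test_that("identical training proteins yield identical sub-models", {
  fam <- plantedFamily(nGenes = 1, n = 50, coef = c(x1 = 1, x2 = 0.5))
  tabs <- list(A = fam$tables[[1]], B = fam$tables[[1]])
  dms <- list(A = fam$dms[[1]], B = fam$dms[[1]])
  model <- fitCPT(tabs, dms, c("x1", "x2"),
                  trainingConfig(task = "regression"))
  expect_equal(model@perProteinModels$A, model@perProteinModels$B)
})

test_that("ensembles average sub-model predictions", {
  scale <- c(x1 = 1)
  m <- new("CPTModel", selectedFeatures = "x1", scale = scale,
           perProteinModels = list(
             A = list(coefficients = c(x1 = 0), intercept = qlogis(0.2)),
             B = list(coefficients = c(x1 = 0), intercept = qlogis(0.6))),
           task = "classification", config = list())
  ft <- asFeatureTable(cbind(x1 = c(0, 1)))
  expect_equal(predictEnsemble(m, ft), c(0.4, 0.4))
  mSwap <- m
  mSwap@perProteinModels <- m@perProteinModels[c("B", "A")]
  expect_equal(predictEnsemble(mSwap, ft), predictEnsemble(m, ft))

  ftNA <- asFeatureTable(cbind(x1 = c(0, NA)))
  expect_error(predictEnsemble(m, ftNA), "imputation")
})

test_that("predictions are monotone in a shared-sign feature", {
  fam <- plantedFamily(nGenes = 3, n = 80, coef = c(x1 = 1.5, x2 = -0.5))
  model <- fitCPT(fam$tables, fam$dms, c("x1", "x2"),
                  trainingConfig(task = "regression"))
  signs <- sapply(model@perProteinModels, function(m)
    sign(m$coefficients[["x1"]]))
  expect_true(all(signs == signs[1]))
  grid <- asFeatureTable(cbind(x1 = seq(-2, 2, length.out = 11),
                               x2 = rep(0, 11)))
  preds <- predictEnsemble(model, grid)
  expect_true(all(diff(preds) * signs[1] > 0))
})

test_that("leave-one-protein-out folds partition the validation role", {
  folds <- lopoFolds(paste0("P", 1:5))
  expect_length(folds, 5)
  vals <- vapply(folds, `[[`, "", "validation")
  expect_setequal(vals, paste0("P", 1:5))
  for (f in folds) {
    expect_length(f$train, 4)
    expect_false(f$validation %in% f$train)
  }
  expect_length(lopoFolds(c("A", "B")), 2)
  expect_error(lopoFolds("A"), "at least 2")
})

test_that("feature selection keeps homology first and finds planted signal", {
  coef <- c(h1 = 1, h2 = 0.8, v_sig = 1.2, m_sig = -1, i_sig = 0.7,
            c_sig = 0.9, d_sig = 1.1,
            v_n1 = 0, v_n2 = 0, m_n1 = 0, i_n1 = 0, c_n1 = 0,
            d_n1 = 0, d_n2 = 0)
  fam <- plantedFamily(nGenes = 4, n = 100, coef = coef, seed = 63)
  candidates <- list(homology = c("h1", "h2"),
                     vert100 = c("v_sig", "v_n1", "v_n2"),
                     mamm30 = c("m_sig", "m_n1"),
                     inverse_folding = c("i_sig", "i_n1"),
                     conditioned = c("c_sig", "c_n1"),
                     descriptor = c("d_n1", "d_sig", "d_n2"))
  sel <- selectFeatures(fam$tables, fam$dms, candidates,
                        trainingConfig(task = "regression"))
  expect_equal(sel$selected[1:2], c("h1", "h2"))
  expect_true(all(c("v_sig", "m_sig", "i_sig", "c_sig", "d_sig") %in%
                    sel$selected))
  # deterministic: identical rerun gives the identical selection
  sel2 <- selectFeatures(fam$tables, fam$dms, candidates,
                         trainingConfig(task = "regression"))
  expect_identical(sel$selected, sel2$selected)
  expect_identical(sel$trace, sel2$trace)
})
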