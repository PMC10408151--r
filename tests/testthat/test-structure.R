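test_that("distance-fallback contacts follow the cutoff rule", {
  # two single-atom sidechains 3.0 A apart: contact; 10 A apart: none
  near <- list(matrix(c(0, 0, 0), 1), matrix(c(3, 0, 0), 1))
  far <- list(matrix(c(0, 0, 0), 1), matrix(c(10, 0, 0), 1))
  expect_true(extractContacts(near)[1, 2])
  expect_false(extractContacts(far)[1, 2])
  # glycine: no sidechain heavy atoms, never a contact
  gly <- list(matrix(c(0, 0, 0), 1), matrix(numeric(0), 0, 3), NULL)
  expect_equal(sum(extractContacts(gly)), 0)
})

test_that("fallback contacts equal an all-pairs distance oracle", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- sample(5:15, 1)
      coords <- matrix(rnorm(n * 3, sd = 4), n)
      adj <- extractContacts(coords, contactSpec(cutoffA = 5))
      for (i in seq_len(n))
        for (j in seq_len(n))
          expect_equal(adj[i, j],
                       i != j && sqrt(sum((coords[i, ] - coords[j, ])^2)) <= 5)
    }
  })
})

test_that("precomputed contact lists pass through as their symmetrisation", {
  st <- StructureInfo("G1", plddt = rep(80, 6),
                      contacts = rbind(c(2, 5), c(5, 2), c(1, 6)))
  expect_true(st@contacts[2, 5] && st@contacts[5, 2])
  expect_true(st@contacts[1, 6] && st@contacts[6, 1])
  expect_equal(sum(st@contacts), 4)
})

test_that("fragment resolution maximises pLDDT with low-id tie-break", {
  f1 <- StructureInfo("G1", plddt = c(55, 60), contacts = matrix(FALSE, 2, 2),
                      fragmentId = 1L)
  f2 <- StructureInfo("G1", plddt = c(88, 60), contacts = matrix(FALSE, 2, 2),
                      fragmentId = 2L)
  expect_equal(resolveFragments(list(f1, f2), 1)@fragmentId, 2L)
  expect_equal(resolveFragments(list(f1), 1)@fragmentId, 1L)
  expect_equal(resolveFragments(list(f2, f1), 2)@fragmentId, 1L)  # tie
  f3 <- StructureInfo("G1", plddt = c(NA, 70, 30),
                      contacts = matrix(FALSE, 3, 3), fragmentId = 3L)
  expect_null(resolveFragments(list(f1, f2), 5))
  expect_equal(resolveFragments(list(f3), 3)@fragmentId, 3L)
})

test_that("conditioning residues are ranked by query-residue frequency", {
  # position 1 contacts 2, 3, 4 with pLDDT 80, 60, 90; the deep MSA
  # gives query-residue frequencies 0.5, 0.9, 0.7 at those positions
  adj <- matrix(FALSE, 4, 4)
  adj[1, 2:4] <- adj[2:4, 1] <- TRUE
  st <- StructureInfo("G1", plddt = c(85, 80, 60, 90), contacts = adj)
  q <- "AKLM"
  others <- c("AKLM", "AKLM", "AKLM", "AKLX", "AXLM",
              "AXLX", "AXLM", "AXLM", "AXXX")
  msa <- makeMsa(c(q, others), source = "deep")
  f2 <- sum(substr(c(q, others), 2, 2) == "K") / 10
  f3 <- sum(substr(c(q, others), 3, 3) == "L") / 10
  f4 <- sum(substr(c(q, others), 4, 4) == "M") / 10
  expect_equal(c(f2, f3, f4), c(0.5, 0.9, 0.7))
  picked <- pickConditioningResidues(1, st, msa)
  # position 3 (freq 0.9) fails the pLDDT>70 filter; 4 (0.7) then 2 (0.5)
  expect_equal(picked, c(4L, 2L))
})

test_that("conditioning respects the position's own confidence", {
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- TRUE
  stLow <- StructureInfo("G1", plddt = c(65, 90, 90), contacts = adj)
  msa <- makeMsa(c("AAA", "AAA"), source = "deep")
  expect_equal(pickConditioningResidues(1, stLow, msa), integer(0))
  stIso <- StructureInfo("G1", plddt = c(90, 90, 90),
                         contacts = matrix(FALSE, 3, 3))
  expect_equal(pickConditioningResidues(1, stIso, msa), integer(0))
  oneAdj <- matrix(FALSE, 3, 3)
  oneAdj[1, 3] <- oneAdj[3, 1] <- TRUE
  stOne <- StructureInfo("G1", plddt = c(90, 50, 90), contacts = oneAdj)
  expect_equal(pickConditioningResidues(1, stOne, msa), 3L)
})

test_that("empty conditioning equals the unconditioned frequencies", {
  withr::with_seed(32, {
    for (rep in 1:10) {
      msa <- randomMsa(L = 6, depth = 8)
      p <- sample(6, 1)
      wt <- substr(msa@query, p, p)
      mut <- sample(setdiff(AA_STANDARD, wt), 1)
      cs <- conditionedScores(msa, p, wt, mut, integer(0))
      fr <- columnFrequencies(msa, p, wt, mut)
      expect_identical(cs[["cond_wt_score"]], logOffset(fr[["wt_freq"]]))
      expect_identical(cs[["cond_mut_score"]], logOffset(fr[["mut_freq"]]))
    }
  })
})

test_that("conditioned scores match hand enumeration of retained rows", {
  # 5-row alignment; conditioning on position 1 keeps the 3 rows whose
  # first residue matches the query's A; the wild type at position 2 is
  # present in 2 of them
  msa <- makeMsa(c("AK", "AK", "A-", "CK", "CW"), source = "deep")
  cs <- conditionedScores(msa, 2, wt = "K", mut = "W", conditioning = 1L)
  expect_equal(cs[["cond_wt_score"]], logOffset(2 / 3))
  expect_equal(cs[["cond_mut_score"]], logOffset(0))

  # filter that retains no rows yields missingness
  msa2 <- makeMsa(c("AK", "CK", "CW"), source = "deep")
  cs2 <- conditionedScores(msa2, 2, "K", "W", conditioning = 1L,
                           spec = conditioningSpec(minFilteredRows = 2),
                           includeQuery = FALSE)
  expect_true(all(is.na(cs2)))
})

test_that("adding conditioning residues never grows the retained set", {
  withr::with_seed(33, {
    for (rep in 1:15) {
      msa <- randomMsa(L = 8, depth = 12)
      p <- sample(8, 1)
      wt <- substr(msa@query, p, p)
      mut <- sample(setdiff(AA_STANDARD, wt), 1)
      conds <- sample(setdiff(1:8, p), 3)
      retained <- function(cond) {
        keep <- rep(TRUE, msaDepth(msa))
        for (cp in cond)
          keep <- keep & (msaColumn(msa, cp) ==
                            substr(msa@query, cp, cp))
        sum(keep)
      }
      expect_true(retained(conds[1]) <= retained(integer(0)))
      expect_true(retained(conds[1:2]) <= retained(conds[1]))
      expect_true(retained(conds[1:3]) <= retained(conds[1:2]))
    }
  })
})

test_that("site features report degree and confidence", {
  adj <- matrix(FALSE, 4, 4)
  adj[1, 2:4] <- adj[2:4, 1] <- TRUE
  st <- StructureInfo("G1", plddt = c(91.5, 80, NA, 70), contacts = adj)
  expect_equal(siteFeatures(st, 1),
               c(contact_count = 3, plddt = 91.5))
  expect_equal(siteFeatures(st, 2),
               c(contact_count = 1, plddt = 80))
  expect_true(all(is.na(siteFeatures(st, 3))))  # uncovered residue
  iso <- StructureInfo("G1", plddt = 88, contacts = matrix(FALSE, 1, 1))
  expect_equal(siteFeatures(iso, 1)[["contact_count"]], 0)
})
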