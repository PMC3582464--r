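# a labelled clade tree built from explicit topology: root - A - leaves
starTree <- function(nLeaf, mutsPerLeaf = 1L) {
  pos <- seq(5000L, by = 7L, length.out = nLeaf * mutsPerLeaf)
  toks <- vapply(seq_len(nLeaf), function(i) {
    paste(pos[((i - 1L) * mutsPerLeaf + 1L):(i * mutsPerLeaf)], collapse = "; ")
  }, character(1))
  names(toks) <- paste0("s", seq_len(nLeaf))
  toks <- c(toks, root = "")
  hs <- hsFromTokens(toks)
  net <- buildMJNetwork(hs, ref = mtref, hypermutable = integer(0))
  rootAndLabel(net, emptyVariants(), cladeDefinitions = list(), ref = mtref)
}

test_that("rho of a star is the per-leaf mutation count", {
  tree <- starTree(8L, 1L)
  # label the root by hand so the whole star is one clade
  tree@nodes$clade[tree@nodes$id == tree@root] <- "ALL"
  expect_equal(rhoStatistic(tree, "ALL"), 8 / 9)  # root haplotype counts too
  # excluding the root sample: a pure 8-leaf star
  hs <- hsFromTokens(stats::setNames(
    paste0(seq(5000, by = 7, length.out = 8)), paste0("s", 1:8)))
  net <- buildMJNetwork(hs, ref = mtref, hypermutable = integer(0))
  tr <- rootAndLabel(net, emptyVariants(), ref = mtref)
  tr@nodes$clade[tr@nodes$id == tr@root] <- "ALL"
  expect_equal(rhoStatistic(tr, "ALL"), 1)
  expect_equal(sigmaSaillard(tr, "ALL"), 1 / sqrt(8))
})

test_that("rho averages unequal path lengths", {
  # two leaves at path lengths 1 and 3 below the common root
  gen <- ape::read.tree(text = "(t1:10,t2:10);")
  ev <- data.frame(edge = c(1L, 2L, 2L, 2L), class = "control",
    position = c(16126L, 16293L, 16311L, 16320L), alt = "C", age_gen = 1)
  tree <- cladeTreeFromGenealogy(gen, ev, mtref)
  expect_equal(rhoStatistic(tree, "ALL"), 2)
  expect_equal(sigmaSaillard(tree, "ALL"), sqrt(1 + 3) / 2)
})

test_that("a single lineage with four mutations has sigma 2", {
  hs <- hsFromTokens(c(a = "5000; 6000; 7000; 8000"))
  net <- buildMJNetwork(hs, ref = mtref, hypermutable = integer(0))
  tree <- rootAndLabel(net, emptyVariants(), ref = mtref)
  tree@nodes$clade[tree@nodes$id == tree@root] <- "ALL"
  expect_equal(sigmaSaillard(tree, "ALL"), 2)
})

test_that("rho and sigma match brute-force path and branch summation", {
  set.seed(31)
  for (rep in 1:5) {
    gen <- simulateGenealogy(50, demographicModel(ne = 600))
    sim <- dropMutations(gen, mutationModel(), mtref)
    tree <- cladeTreeFromGenealogy(sim$gen, sim$events, mtref)
    # oracle: per-sample path walk
    leafIds <- tree@nodes$id[tree@nodes$samples != ""]
    pathSum <- function(id, filter) {
      sum(vapply(mitophylo:::.pathEdges(tree, id), function(k)
        mitophylo:::.branchMutations(tree@edgeVariants[[k]], filter, mtref),
        numeric(1)))
    }
    for (filt in c("all_sites", "synonymous_only")) {
      oracleRho <- mean(vapply(leafIds, pathSum, numeric(1), filter = filt))
      expect_equal(rhoStatistic(tree, "ALL", filt, mtref), oracleRho)
      # oracle sigma: direct enumeration over branches
      ss <- 0
      for (k in seq_len(nrow(tree@edges))) {
        nb <- tree@nodes$n_sub[tree@nodes$id == tree@edges$child[k]]
        ss <- ss + nb^2 * mitophylo:::.branchMutations(tree@edgeVariants[[k]], filt, mtref)
      }
      expect_equal(sigmaSaillard(tree, "ALL", filt, mtref), sqrt(ss) / 50)
    }
  }
})

test_that("parent rho is the leaf-weighted mean of child contributions", {
  tree <- local({
    hs <- hsFromTokens(c(
      r = "1000",
      a1 = "1000; 2000", a2 = "1000; 2000; 3000",
      b1 = "1000; 4000", b2 = "1000; 4000; 5000"))
    net <- buildMJNetwork(hs, ref = mtref, hypermutable = integer(0))
    rootAndLabel(net, parseVariantString("1000", mtref),
      cladeDefinitions = list(P = "1000", CA = c("1000", "2000"), CB = c("1000", "4000")),
      ref = mtref)
  })
  rhoP <- rhoStatistic(tree, "P")
  rhoA <- rhoStatistic(tree, "CA")
  rhoB <- rhoStatistic(tree, "CB")
  nA <- length(cladeSamples(tree, "CA"))
  nB <- length(cladeSamples(tree, "CB"))
  nTot <- length(cladeSamples(tree, "P"))
  # each child clade's stem carries one mutation (2000 and 4000); the root's
  # own sample contributes a zero-length path
  expect_equal(rhoP, (nA * (rhoA + 1) + nB * (rhoB + 1)) / nTot)
  expect_equal(rhoP, 1.2)
})

test_that("the linear clock reproduces published synonymous-clock ages", {
  clk <- defaultSynonymousClock()
  expect_gt(clk@yearsPerSub, 7940)
  expect_lt(clk@yearsPerSub, 8040)
  expect_equal(ageLinear(0, clk), 0)
  expect_equal(ageLinear(3.74, clk), 29900)
  expect_equal(ageLinear(1.19, clk), 9500)
  expect_error(linearClock(-5), "positive")
})

test_that("the corrected clock maps whole-molecule rho to years", {
  plain <- correctedClock()  # correction disabled
  expect_equal(ageCorrected(0, plain), 0)
  expect_equal(ageCorrected(2.8085, plain), 10000)
  fitted <- defaultCorrectedClock()
  expect_equal(ageCorrected(0, fitted), 0)
  expect_lt(abs(ageCorrected(9.45, fitted, round100 = FALSE) - 26100) / 26100, 0.05)
  # extrapolation beyond the calibrated range warns
  expect_warning(ageCorrected(25, fitted), "extrapolat")
})

test_that("age is monotone in rho under both clocks", {
  rhoGrid <- seq(0, 13, by = 0.25)
  lin <- defaultSynonymousClock()
  cor <- defaultCorrectedClock()
  aLin <- vapply(rhoGrid, ageLinear, numeric(1), clock = lin, round100 = FALSE)
  aCor <- vapply(rhoGrid, function(r)
    suppressWarnings(ageCorrected(r, cor, round100 = FALSE)), numeric(1))
  expect_true(all(diff(aLin) > 0))
  expect_true(all(diff(aCor) >= 0))
})

test_that("the 95% CI brackets the age and collapses when sigma is 0", {
  clk <- defaultSynonymousClock()
  ci <- ci95Age(2.5, 0, clk)
  expect_equal(ci[1], ci[2])
  ci <- ci95Age(2.5, 0.6, clk, round100 = FALSE)
  age <- ageLinear(2.5, clk, round100 = FALSE)
  expect_lt(ci[1], age); expect_gt(ci[2], age)
  expect_equal(ci[2] - ci[1], 2 * 1.96 * 0.6 * clk@yearsPerSub)
  # corrected clock: endpoints monotone in the rho endpoints
  cc <- defaultCorrectedClock()
  ciA <- ci95Age(6, 0.5, cc, round100 = FALSE)
  ciB <- ci95Age(7, 0.5, cc, round100 = FALSE)
  expect_lt(ciA[1], ciB[1]); expect_lt(ciA[2], ciB[2])
  expect_error(ci95Age(2, -1, clk), "nonnegative")
})

test_that("calibration fitting recovers slopes and validates input", {
  clk <- fitCalibrationFromPairs(data.frame(rho = c(1, 2), age = c(8000, 16000)), "linear")
  expect_equal(clk@yearsPerSub, 8000)
  expect_error(fitCalibrationFromPairs(data.frame(rho = 1, age = 8000), "linear"),
    "at least two")
  expect_warning(fitCalibrationFromPairs(
    data.frame(rho = c(1, 2, 3), age = c(8000, 20000, 15000)), "corrected"),
    "monotone")
  # the packaged synonymous pairs give the published calibration
  tab <- cladeAgeCalibration()
  slope <- sum(tab$rho_syn * tab$age_syn) / sum(tab$rho_syn^2)
  fitted <- fitCalibrationFromPairs(data.frame(rho = tab$rho_syn, age = tab$age_syn), "linear")
  expect_equal(fitted@yearsPerSub, slope)
  expect_gt(slope, 7940); expect_lt(slope, 8040)
})

test_that("rho dating is unbiased on founder-effect clades", {
  set.seed(37)
  mut <- mutationModel()
  clk <- linearClock(25 / sum(mut@rates), classFilter = "all_sites")
  ages <- vapply(1:150, function(i) {
    sc <- scenario("founder_star", params = list(n = 15L, ageYears = 10000),
      seed = 37000 + i, ref = mtref)
    sim <- dropMutations(sc$genealogy, mut, mtref)
    tree <- cladeTreeFromGenealogy(sim$gen, sim$events, mtref)
    ageLinear(rhoStatistic(tree, "ALL"), clk, round100 = FALSE)
  }, numeric(1))
  expect_lt(abs(mean(ages) - 10000) / 10000, 0.1)
})

test_that("cladeAgeTable produces the published table shape", {
  tree <- local({
    hs <- hsFromTokens(c(a1 = "1000; 2000", a2 = "1000; 3000", b1 = "7000"))
    net <- buildMJNetwork(hs, ref = mtref, hypermutable = integer(0))
    rootAndLabel(net, emptyVariants(),
      cladeDefinitions = list(A = "1000", B = "7000"), ref = mtref)
  })
  clk <- linearClock(8000, classFilter = "all_sites")
  tab <- cladeAgeTable(tree, clk)
  expect_equal(tab$clade, c("A", "B"))
  expect_named(tab, c("clade", "n", "rho", "sigma", "age", "ci_low", "ci_high"))
  expect_equal(tab$age, roundAge100(tab$rho * 8000))
  expect_true(all(tab$ci_low <= tab$age & tab$age <= tab$ci_high))
})
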