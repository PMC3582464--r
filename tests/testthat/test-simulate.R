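test_that("identical seeds reproduce identical genealogies and mutations", {
  g1 <- simulateGenealogy(12, demographicModel(ne = 900), seed = 77)
  g2 <- simulateGenealogy(12, demographicModel(ne = 900), seed = 77)
  expect_equal(ape::write.tree(g1), ape::write.tree(g2))
  s1 <- dropMutations(g1, mutationModel(), mtref, seed = 78)
  s2 <- dropMutations(g2, mutationModel(), mtref, seed = 78)
  expect_equal(s1$events, s2$events)
  g3 <- simulateGenealogy(12, demographicModel(ne = 900), seed = 79)
  expect_false(identical(ape::write.tree(g1), ape::write.tree(g3)))
})

test_that("pairwise TMRCA matches the haploid coalescent expectation", {
  set.seed(51)
  tm <- vapply(1:4000, function(i)
    attr(simulateGenealogy(2, demographicModel(ne = 700)), "tmrca"), numeric(1))
  expect_lt(abs(mean(tm) - 700) / 700, 0.05)
})

test_that("TMRCA of ten lineages approaches 2Ne(1 - 1/n)", {
  set.seed(53)
  ne <- 500
  tm <- vapply(1:10000, function(i)
    attr(simulateGenealogy(10, demographicModel(ne = ne)), "tmrca"), numeric(1))
  expect_lt(abs(mean(tm) - 1.8 * ne) / (1.8 * ne), 0.03)
})

test_that("piecewise growth shortens ancient coalescent intervals", {
  set.seed(57)
  # strong recent expansion: most coalescences pushed beyond the epoch break
  dem <- demographicModel(start = c(0, 200), ne = c(50000, 200))
  tm <- vapply(1:300, function(i)
    attr(simulateGenealogy(10, dem), "tmrca"), numeric(1))
  expect_gt(mean(tm > 200), 0.9)
  expect_lt(mean(tm), 200 + 2 * 200 * 2)
})

test_that("invalid simulator inputs are rejected", {
  expect_error(simulateGenealogy(1), "at least two")
  expect_error(demographicModel(start = c(5, 10), ne = c(100, 100)), "start at time 0")
  expect_error(mutationModel(control = -1), "nonnegative")
})

test_that("zero mutation rates leave every haplotype at the root state", {
  gen <- simulateGenealogy(8, demographicModel(ne = 500), seed = 3)
  mm <- mutationModel(control = 0, rna_gene = 0, synonymous = 0, nonsynonymous = 0)
  sim <- dropMutations(gen, mm, mtref, seed = 4)
  expect_true(all(vapply(sampleIds(sim$haplotypes), function(id)
    nrow(variantsOf(sim$haplotypes, id)) == 0L, logical(1))))
})

test_that("mutation counts follow the Poisson mean over branch length", {
  gen <- simulateGenealogy(10, demographicModel(ne = 800), seed = 5)
  totalLen <- sum(gen$edge.length)
  mm <- mutationModel()
  rateTotal <- sum(mm@rates)
  set.seed(6)
  counts <- vapply(1:400, function(i)
    nrow(dropMutations(gen, mm, mtref)$events), numeric(1))
  expected <- rateTotal * totalLen
  # mean of 400 Poisson draws: allow 4 standard errors
  se <- sqrt(expected / 400)
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("emitted variant classes match the configured rate ratios", {
  gen <- simulateGenealogy(30, demographicModel(ne = 3000), seed = 7)
  mm <- mutationModel()
  set.seed(8)
  ev <- do.call(rbind, lapply(1:30, function(i) dropMutations(gen, mm, mtref)$events))
  obs <- table(factor(ev$class, levels = names(mm@rates)))
  expect_gt(sum(obs), 2000)
  chi <- stats::chisq.test(obs, p = mm@rates / sum(mm@rates))
  expect_gt(chi$p.value, 0.01)
  # and the emitted classes agree with the reference classifier
  idx <- sample(nrow(ev), 50)
  expect_equal(classifySites(mtref, ev$position[idx], ev$alt[idx]), ev$class[idx])
})

test_that("recurrent hits along one lineage revert rather than duplicate", {
  # a control-only rate high enough that the 1,122-position control pool is
  # hit repeatedly along each lineage
  gen <- ape::read.tree(text = "(t1:400,t2:400);")
  mm <- mutationModel(control = 0.5, rna_gene = 0, synonymous = 0,
    nonsynonymous = 0)
  sim <- dropMutations(gen, mm, mtref, seed = 13)
  for (id in c("t1", "t2")) {
    v <- variantsOf(sim$haplotypes, id)
    expect_false(anyDuplicated(v$position) > 0)
  }
  # with ~200 events per lineage, collisions are near-certain, so fewer
  # derived states survive than events occurred
  nEvents <- nrow(sim$events)
  nStates <- sum(vapply(c("t1", "t2"), function(id)
    nrow(variantsOf(sim$haplotypes, id)), integer(1)))
  expect_gt(nEvents, 300)
  expect_lt(nStates, nEvents)
})

test_that("the purifying knob depresses apparent rates in old clades only", {
  set.seed(61)
  mm <- mutationModel(selectionRemovalProb = 0.6, selectionThreshold = 400)
  classRate <- function(ageYears, cl, reps) {
    mean(vapply(1:reps, function(i) {
      gen <- mitophylo:::.starGenealogy(10L, ageYears / 25)
      ev <- dropMutations(gen, mm, mtref)$events
      sum(ev$class == cl) / (10 * ageYears)
    }, numeric(1)))
  }
  # young clade (200 generations): nothing is old enough to purge;
  # old clade (1000 generations): 60% of non-synonymous input predates the
  # threshold and is removed with probability 0.6 -> apparent rate ~0.64x
  youngNS <- classRate(5000, "nonsynonymous", 40)
  oldNS <- classRate(25000, "nonsynonymous", 40)
  expect_gt(youngNS, oldNS * 1.3)
  # synonymous rates are untouched by the knob
  youngS <- classRate(5000, "synonymous", 40)
  oldS <- classRate(25000, "synonymous", 40)
  expect_lt(abs(youngS - oldS) / youngS, 0.15)
})

test_that("scenario bundles carry coherent truth records", {
  sc <- scenario("founder_star", params = list(n = 6L), seed = 9, ref = mtref)
  expect_equal(sc$truth$tmrca_years, 10000)
  expect_equal(length(sc$haplotypes), 6L)
  expect_equal(attr(sc$genealogy, "tmrca"), 10000 / 25)

  sc2 <- scenario("two_pop_divergence", params = list(nPerPop = 5L), seed = 10,
    ref = mtref)
  expect_true(sc2$truth$expected_fst_zero)
  expect_equal(as.vector(table(populations(sc2$haplotypes))[c("popA", "popB")]),
    c(5L, 5L))

  sc3 <- scenario("null_language", params = list(nPops = 4L, nPerPop = 4L),
    seed = 11, ref = mtref)
  expect_length(sc3$familyMap, 4L)
  expect_equal(nrow(sc3$coordinates), 4L)
  expect_error(scenario("volcano", seed = 1), "unknown scenario")
})

test_that("scenario bundles write a complete file set", {
  sc <- scenario("founder_star", params = list(n = 4L), seed = 12, ref = mtref)
  dir <- tempfile()
  paths <- writeScenario(sc, dir, ref = mtref)
  expect_true(all(file.exists(paths)))
  back <- readSampleTable(paths["table"], ref = mtref)
  expect_equal(sampleIds(back), sampleIds(sc$haplotypes))
  tr <- ape::read.tree(paths["tree"])
  expect_equal(ape::Ntip(tr), 4L)
  truth <- yaml::read_yaml(paths["truth"])
  expect_equal(truth$scenario, "founder_star")
  expect_equal(truth$seed, 12L)
  fa <- Biostrings::readDNAStringSet(paths["fasta"])
  expect_equal(length(fa), 4L)
})
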