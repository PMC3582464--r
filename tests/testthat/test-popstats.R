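regionalLabels <- local({
  counts <- utils::read.delim(system.file("extdata", "m1_u6_regional_counts.tsv",
    package = "mitophylo"))
  expandRegionalCounts(counts)
})
HGS <- c("U6", "U6a", "U6b", "M1", "M1a", "M1b")

test_that("regional frequencies reproduce the published survey percentages", {
  ft <- frequencyTable(regionalLabels, HGS)
  row <- function(g) ft[ft$group == g, ]
  expect_equal(row("Morocco")$n, 530)
  expect_equal(row("Morocco")$U6, 40)
  expect_equal(row("Morocco")$U6_pct, 7.5)
  expect_equal(row("Ethiopia")$M1, 45)
  expect_equal(row("Ethiopia")$M1_pct, 16.7)
  expect_equal(row("Algeria")$U6_pct, 10.2)
})

test_that("region rows are the sums of their member populations", {
  ft <- frequencyTable(regionalLabels, HGS)
  nwa <- ft[ft$group == "NWA", ]
  expect_equal(nwa$U6,
    sum(ft$U6[ft$group %in% c("Morocco", "Algeria", "Tunisia")]))
  expect_equal(nwa$U6, 76)
  expect_equal(nwa$n, 1173)
  expect_equal(nwa$U6_pct, 6.5)
  # sub-haplogroup counts never exceed their parent
  expect_true(all(ft$U6a + ft$U6b <= ft$U6))
  expect_true(all(ft$M1a + ft$M1b <= ft$M1))
})

test_that("unlabelled samples and empty populations are handled", {
  bad <- regionalLabels
  bad$clade[1] <- NA
  expect_error(frequencyTable(bad, HGS), "unlabelled")
  one <- data.frame(sample_id = "x1", population = "Empty", region = "R",
    clade = "other")
  ft <- frequencyTable(one, HGS, populationSizes = c(Empty = 0L))
  expect_true(is.na(ft$U6_pct[ft$group == "Empty"]))
})

test_that("identical populations have zero linearised FST", {
  hsA <- hsFromTokens(c(a1 = "1000", a2 = "2000", a3 = ""), population = "A")
  hsB <- hsFromTokens(c(b1 = "1000", b2 = "2000", b3 = ""), population = "B")
  v <- linearizedFst(hsA, hsB)
  expect_equal(unname(v["fst"]), 0)
  expect_equal(unname(v["linearised"]), 0)
})

test_that("fixed populations one mutation apart have undefined linearisation", {
  hsA <- hsFromTokens(c(a1 = "1000", a2 = "1000"), population = "A")
  hsB <- hsFromTokens(c(b1 = "", b2 = ""), population = "B")
  expect_warning(v <- linearizedFst(hsA, hsB), "undefined")
  expect_equal(unname(v["fst"]), 1)
  expect_true(is.na(v["linearised"]))
})

test_that("FST matches a brute-force AMOVA variance decomposition", {
  hsA <- hsFromTokens(c(a1 = "1000; 2000", a2 = "1000", a3 = "", a4 = "1000; 3000"),
    population = "A")
  hsB <- hsFromTokens(c(b1 = "5000; 6000", b2 = "5000", b3 = "5000; 7000", b4 = "5000"),
    population = "B")
  got <- linearizedFst(hsA, hsB)
  # oracle: explicit double-loop AMOVA sums of squares on mismatch distances
  both <- c(lapply(c("a1", "a2", "a3", "a4"), function(i) variantsOf(hsA, i)),
    lapply(c("b1", "b2", "b3", "b4"), function(i) variantsOf(hsB, i)))
  keyOf <- function(v) if (!nrow(v)) character(0) else paste0(v$position, ":", v$derived)
  dd <- function(i, j) {
    ki <- keyOf(both[[i]]); kj <- keyOf(both[[j]])
    length(setdiff(ki, kj)) + length(setdiff(kj, ki))
  }
  n <- 8; nA <- 4
  ssT <- 0; for (i in 1:(n - 1)) for (j in (i + 1):n) ssT <- ssT + dd(i, j)
  ssT <- ssT / n
  ssA <- 0; for (i in 1:3) for (j in (i + 1):4) ssA <- ssA + dd(i, j)
  ssB <- 0; for (i in 5:7) for (j in (i + 1):8) ssB <- ssB + dd(i, j)
  ssW <- ssA / 4 + ssB / 4
  msW <- ssW / (n - 2)
  sigA <- ((ssT - ssW) / 1 - msW) / ((n - (nA^2 + (n - nA)^2) / n) / 1)
  fstOracle <- max(0, sigA / (sigA + msW))
  expect_equal(unname(got["fst"]), fstOracle)
  expect_equal(unname(got["linearised"]), fstOracle / (1 - fstOracle))
})

test_that("FST grows with divergence on simulated population pairs", {
  f <- vapply(c(0, 1500, 6000), function(tau) {
    sc <- scenario("two_pop_divergence",
      params = list(divergenceGen = tau, nPerPop = 12L), seed = 911, ref = mtref)
    hs <- buildAnalysisHaplotypes(sc$haplotypes, mtref)
    m <- fstMatrix(hs, applyGrouping(hs))
    m["popA", "popB"]
  }, numeric(1))
  expect_lt(f[1], 0.25)
  expect_true(all(diff(f) > 0))
})

test_that("language distance is binary on families and respects grouping", {
  fam <- c(Morocco = "AfroAsiatic", Egypt = "AfroAsiatic", Crete = "IndoEuropean",
    "Ethiopia+Somalia" = "AfroAsiatic")
  d <- languageDistance(names(fam), fam)
  expect_equal(d["Morocco", "Egypt"], 0)
  expect_equal(d["Morocco", "Crete"], 1)
  expect_equal(d["Ethiopia+Somalia", "Morocco"], 0)
  expect_true(all(diag(d) == 0))
  expect_error(languageDistance(c("Morocco", "Atlantis"), fam), "Atlantis")
})

test_that("great-circle distances behave like a metric", {
  co <- data.frame(population = c("x", "y", "anti"),
    lat = c(31.8, 31.8, -31.8), lon = c(-7.1, -7.1, 172.9))
  d <- geographicDistance(c("x", "y", "anti"), co)
  expect_equal(d["x", "y"], 0)
  expect_lt(abs(d["x", "anti"] - 20015), 10)  # half the mean circumference
  set.seed(19)
  for (rep in 1:20) {
    co3 <- data.frame(population = c("a", "b", "c"),
      lat = stats::runif(3, -80, 80), lon = stats::runif(3, -180, 180))
    d3 <- geographicDistance(c("a", "b", "c"), co3)
    expect_lte(d3["a", "c"], d3["a", "b"] + d3["b", "c"] + 1e-6)
  }
})

test_that("Mantel identity and reversal give r = +/-1", {
  set.seed(5)
  m <- matrix(stats::runif(49), 7); m <- m + t(m); diag(m) <- 0
  res <- mantelTest(m, m, nPermutations = 999, seed = 1)
  expect_equal(res$r, 1)
  expect_lte(res$p, 0.01)
  rev <- max(m) - m; diag(rev) <- 0
  res2 <- mantelTest(m, rev, nPermutations = 999, seed = 1)
  expect_equal(res2$r, -1)
})

test_that("Mantel r agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(13)
  a <- matrix(stats::runif(64), 8); a <- a + t(a); diag(a) <- 0
  b <- matrix(stats::runif(64), 8); b <- b + t(b); diag(b) <- 0
  ours <- mantelTest(a, b, nPermutations = 99, seed = 2)
  veg <- vegan::mantel(stats::as.dist(a), stats::as.dist(b), permutations = 99)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
})

test_that("Mantel r is invariant to joint relabelling of both matrices", {
  set.seed(23)
  a <- matrix(stats::runif(49), 7); a <- a + t(a); diag(a) <- 0
  b <- matrix(stats::runif(49), 7); b <- b + t(b); diag(b) <- 0
  r0 <- mantelTest(a, b, 9, seed = 1)$r
  p <- sample(7)
  r1 <- mantelTest(a[p, p], b[p, p], 9, seed = 1)$r
  expect_equal(r0, r1)
})

test_that("grouping pools members, drops exclusions, and flags conflicts", {
  hs <- hsFromTokens(c(e1 = "1000", e2 = "", s1 = "2000", i1 = "", m1 = "3000"),
    population = "x")
  hs@info$population <- c("Ethiopia", "Ethiopia", "Somalia", "Iran", "Morocco")
  g <- suppressMessages(applyGrouping(hs,
    groups = list("Ethiopia+Somalia" = c("Ethiopia", "Somalia")),
    exclude = "Iran"))
  expect_setequal(g[["Ethiopia+Somalia"]], c("e1", "e2", "s1"))
  expect_equal(g[["Morocco"]], "m1")
  expect_false("Iran" %in% names(g))
  expect_equal(attr(g, "excluded"), "Iran")
  expect_error(applyGrouping(hs, groups = list(G = "Iran"), exclude = "Iran"),
    "both")
  # empty spec: identity grouping
  g0 <- applyGrouping(hs)
  expect_setequal(names(g0), c("Ethiopia", "Somalia", "Iran", "Morocco"))
})
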