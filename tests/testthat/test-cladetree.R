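# small worked tree: reference root, clade A (10398), subclades
treeFixture <- function() {
  hs <- hsFromTokens(c(
    r1 = "",
    a1 = "10398",
    a2 = "10398; 12705",
    a3 = "10398; 12705; 16126",
    b1 = "8701"))
  net <- buildMJNetwork(hs, ref = mtref, hypermutable = integer(0))
  rootAndLabel(net, emptyVariants(),
    cladeDefinitions = list(
      A = "10398", A1 = c("10398", "12705"), A1a = c("10398", "12705", "16126"),
      B = "8701"),
    ref = mtref)
}

test_that("rooting a star gives three depth-1 children", {
  hs <- hsFromTokens(c(a = "1000", b = "2000", c = "3000", r = ""))
  net <- buildMJNetwork(hs, ref = mtref, hypermutable = integer(0))
  tree <- rootAndLabel(net, emptyVariants(), ref = mtref)
  rootId <- tree@root
  expect_equal(length(childNodes(tree, rootId)), 3L)
  expect_true(all(tree@edges$n_mut == 1L))
  expect_equal(tree@nodes$n_sub[tree@nodes$id == rootId], 4L)
})

test_that("nodes get the deepest clade whose defining variants lie on their path", {
  tree <- treeFixture()
  lab <- stats::setNames(tree@nodes$clade, tree@nodes$id)
  sampleNode <- function(s) tree@nodes$id[grepl(s, tree@nodes$samples)]
  expect_equal(unname(lab[sampleNode("a1")]), "A")
  expect_equal(unname(lab[sampleNode("a2")]), "A1")
  expect_equal(unname(lab[sampleNode("a3")]), "A1a")
  expect_equal(unname(lab[sampleNode("b1")]), "B")
  expect_true(is.na(lab[sampleNode("r1")]))
})

test_that("a haplotype missing one defining variant keeps the parent label", {
  hs <- hsFromTokens(c(r = "", x = "10398", y = "10398; 12705"))
  net <- buildMJNetwork(hs, ref = mtref, hypermutable = integer(0))
  tree <- rootAndLabel(net, emptyVariants(),
    cladeDefinitions = list(A = "10398", A1 = c("10398", "12705")), ref = mtref)
  nx <- tree@nodes$id[grepl("x", tree@nodes$samples)]
  expect_equal(tree@nodes$clade[tree@nodes$id == nx], "A")
})

test_that("a clade definition incompatible with the topology is reported", {
  hs <- hsFromTokens(c(r = "", x = "10398", y = "8701"))
  net <- buildMJNetwork(hs, ref = mtref, hypermutable = integer(0))
  expect_error(rootAndLabel(net, emptyVariants(),
    cladeDefinitions = list(BAD = c("10398", "8701")), ref = mtref), "BAD")
})

test_that("root-path concatenation reconstructs each leaf's variant state", {
  set.seed(29)
  sc <- scenario("founder_star", params = list(n = 12L), seed = 29, ref = mtref)
  net <- buildMJNetwork(sc$haplotypes, ref = mtref, hypermutable = integer(0))
  tree <- rootAndLabel(resolveReticulation(net), emptyVariants(), ref = mtref)
  for (id in sampleIds(sc$haplotypes)) {
    node <- tree@nodes$id[vapply(tree@nodes$samples, function(s)
      id %in% mitophylo:::.splitSamples(s), logical(1))]
    got <- rootPathState(tree, node)
    want <- sort(sub("\\.0:", ":", mitophylo:::.variantKeys(variantsOf(sc$haplotypes, id))))
    want <- sub("^(\\d+)\\.(\\d+):", "\\1+\\2:", want)
    expect_setequal(got, want)
  }
})

test_that("subtended sample counts are conserved down the tree", {
  tree <- treeFixture()
  for (p in unique(tree@edges$parent)) {
    kids <- childNodes(tree, p)
    own <- length(mitophylo:::.splitSamples(tree@nodes$samples[tree@nodes$id == p]))
    expect_equal(tree@nodes$n_sub[tree@nodes$id == p],
      own + sum(tree@nodes$n_sub[match(kids, tree@nodes$id)]))
  }
})

test_that("newick export encodes the mutation-count branch lengths", {
  tree <- treeFixture()
  nwk <- asNewick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(phy) + phy$Nnode, nrow(tree@nodes))
  expect_equal(sum(phy$edge.length), sum(tree@edges$n_mut))
})

test_that("marker typing places fully covered samples exactly", {
  tree <- treeFixture()
  full <- cbind(start = 1L, end = 16569L)
  hit <- assignCladeFromMarkers(tree,
    parseVariantString("10398; 12705; 16126", mtref), full, ref = mtref)
  expect_equal(hit$clade, "A1a")
  expect_length(hit$ambiguity, 0L)
})

test_that("panel-window typing yields the deepest supported clade plus ambiguity", {
  tree <- treeFixture()
  # typed only around 10398: derived there, everything deeper untyped
  windows <- cbind(start = c(10300L), end = c(10500L))
  hit <- assignCladeFromMarkers(tree, parseVariantString("10398", mtref),
    windows, ref = mtref)
  expect_equal(hit$clade, "A")
  expect_setequal(hit$ambiguity, c("A1", "A1a"))
})

test_that("conflicting branch markers make a sample unplaceable", {
  tree <- treeFixture()
  full <- cbind(start = 1L, end = 16569L)
  expect_error(assignCladeFromMarkers(tree,
    parseVariantString("10398; 8701", mtref), full, ref = mtref),
    "unplaceable")
})

test_that("typed-ancestral states exclude deeper clades", {
  tree <- treeFixture()
  # covered at 10398 (derived) and 12705 (ancestral): A but never A1
  windows <- cbind(start = c(10300L, 12600L), end = c(10500L, 12800L))
  hit <- assignCladeFromMarkers(tree, parseVariantString("10398", mtref),
    windows, ref = mtref)
  expect_equal(hit$clade, "A")
  expect_false("A1" %in% hit$ambiguity)
})

test_that("haplogroup nesting follows the letter/digit alternation", {
  expect_true(isSubclade("M1a", "M1"))
  expect_true(isSubclade("M1a1b2", "M1a"))
  expect_true(isSubclade("U6a7", "U6"))
  expect_false(isSubclade("M10", "M1"))
  expect_false(isSubclade("M1", "M1"))
  expect_false(isSubclade("U6", "M1"))
})
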