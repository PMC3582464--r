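# shared fixtures: the packaged reference is loaded once per test run
mtref <- loadMtReference()

# HaplotypeSet from a named character vector of variant strings
hsFromTokens <- function(tokens, population = "pop", region = "SIM", ref = mtref) {
  info <- data.frame(sample_id = names(tokens), population = population,
    region_code = region, stringsAsFactors = FALSE)
  vlist <- lapply(unname(tokens), parseVariantString, ref = ref)
  haplotypeSet(info, vlist)
}

emptyVariants <- function() mitophylo:::emptyVariantTable()

# random binary perfect-phylogeny haplotype set: a random rooted tree with
# one unique site per edge; leaf haplotypes = union of sites on the root path
randomPerfectPhylogeny <- function(nLeaf, positions) {
  stopifnot(length(positions) >= 2L * nLeaf)
  parent <- c(NA, vapply(2:(2L * nLeaf - 1L), function(i) sample.int(i - 1L, 1L), 1L))
  # nodes 1..(2n-1); assign a distinct position to every non-root node's stem
  sitePos <- c(NA, sample(positions, 2L * nLeaf - 2L))
  pathSites <- function(i) {
    out <- integer(0)
    while (!is.na(parent[i])) { out <- c(out, sitePos[i]); i <- parent[i] }
    sort(out)
  }
  isLeaf <- !(seq_len(2L * nLeaf - 1L) %in% parent)
  leaves <- which(isLeaf)[seq_len(min(nLeaf, sum(isLeaf)))]
  toks <- vapply(leaves, function(l) paste(pathSites(l), collapse = "; "), "")
  names(toks) <- paste0("L", seq_along(toks))
  # parsimony length counts sites segregating among the chosen leaves: a
  # site carried by every leaf needs no change on the network
  siteSets <- lapply(leaves, pathSites)
  allSites <- unique(unlist(siteSets))
  inAll <- vapply(allSites, function(s)
    all(vapply(siteSets, function(x) s %in% x, logical(1))), logical(1))
  list(tokens = toks, nSites = sum(!inAll))
}

# brute-force Steiner minimum over the binary site hypercube: minimum MST
# length over the observed vertices plus up to `maxExtra` Steiner vertices
steinerMinimum <- function(binMat, maxExtra = 2L) {
  nSites <- ncol(binMat)
  all <- as.matrix(expand.grid(rep(list(0:1), nSites)))
  obsKey <- apply(binMat, 1L, paste, collapse = "")
  allKey <- apply(all, 1L, paste, collapse = "")
  cand <- which(!(allKey %in% obsKey))
  mstLen <- function(m) {
    d <- as.matrix(stats::dist(m, method = "manhattan"))
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
    sum(igraph::E(igraph::mst(g))$weight)
  }
  best <- mstLen(binMat)
  if (maxExtra >= 1L) for (i in cand) {
    best <- min(best, mstLen(rbind(binMat, all[i, ])))
  }
  if (maxExtra >= 2L && length(cand) >= 2L) {
    combs <- utils::combn(cand, 2L)
    for (k in seq_len(ncol(combs)))
      best <- min(best, mstLen(rbind(binMat, all[combs[, k], ])))
  }
  best
}

# binary presence/absence matrix of a HaplotypeSet over its segregating sites
binaryMatrix <- function(hs) {
  st <- mitophylo:::.stateMatrix(hs)
  (st != ".") * 1L
}
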