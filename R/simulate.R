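#' Construct a piecewise demographic model
#'
#' @param start epoch start times in generations before present (first must
#'   be 0).
#' @param ne haploid effective size at each epoch's recent end.
#' @param growth forward-time exponential growth rate per generation in
#'   each epoch (0 = constant).
#' @return A [DemographicModel].
#' @export
demographicModel <- function(start = 0, ne = 1000, growth = 0) {
  methods::new("DemographicModel", epochs = data.frame(
    start = as.numeric(start), ne = as.numeric(ne),
    growth = rep_len(as.numeric(growth), length(start))))
}

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel with", nrow(object@epochs), "epoch(s):\n")
  print(object@epochs)
})

#' Construct a class-partitioned mutation model
#'
#' Default rates emulate the mutational input of the human mitochondrial
#' genome per 25-year generation: a synonymous coding-region rate matching
#' a synonymous clock of about 8,000 years per substitution, a
#' non-synonymous rate 0.63 times the synonymous one (the
#' non-synonymous-to-synonymous ratio observed in the M1/U6 data), an RNA
#' gene rate of similar order, and a faster control region dominated by the
#' hypervariable segments.
#'
#' @param control,rna_gene,synonymous,nonsynonymous genome-wide rates per
#'   lineage per generation.
#' @param selectionRemovalProb probability that a non-synonymous mutation
#'   older than `selectionThreshold` is purged (purifying-selection knob).
#' @param selectionThreshold age threshold in generations.
#' @return A [MutationModel].
#' @export
mutationModel <- function(control = 8e-3, rna_gene = 1.2e-3,
                          synonymous = 25 / 7995, nonsynonymous = 0.63 * 25 / 7995,
                          selectionRemovalProb = 0, selectionThreshold = 400) {
  methods::new("MutationModel",
    rates = c(control = control, rna_gene = rna_gene,
      synonymous = synonymous, nonsynonymous = nonsynonymous),
    selectionRemovalProb = selectionRemovalProb,
    selectionThreshold = selectionThreshold)
}

setMethod("show", "MutationModel", function(object) {
  cat("MutationModel rates/generation:",
    paste(names(object@rates), format(object@rates, digits = 3), sep = "=", collapse = ", "),
    "\n")
  if (object@selectionRemovalProb > 0)
    cat("  purifying knob: removal prob", object@selectionRemovalProb,
      "beyond", object@selectionThreshold, "generations\n")
})

# Ne at backward time t under the piecewise model
.neAt <- function(dem, t) {
  e <- dem@epochs
  i <- findInterval(t, e$start)
  e$ne[i] * exp(-e$growth[i] * (t - e$start[i]))
}

# waiting time from `t0` until cumulative coalescent intensity
# k(k-1)/(2*Ne(s)) reaches `target`, integrating across epochs
.coalWait <- function(dem, t0, kPairRate, target) {
  e <- dem@epochs
  bounds <- c(e$start, Inf)
  t <- t0
  remaining <- target
  repeat {
    i <- findInterval(t, e$start)
    hi <- bounds[i + 1L]
    ne0 <- e$ne[i]; g <- e$growth[i]; s0 <- e$start[i]
    if (g == 0) {
      rate <- kPairRate / ne0
      need <- remaining / rate
      if (t + need <= hi) return(t + need - t0)
      remaining <- remaining - rate * (hi - t)
      t <- hi
    } else {
      # Ne(s) = ne0*exp(-g*(s-s0)); intensity integral has closed form
      A <- kPairRate / (ne0 * g)
      intFull <- A * (exp(g * (hi - s0)) - exp(g * (t - s0)))
      if (is.finite(hi) && intFull < remaining) {
        remaining <- remaining - intFull
        t <- hi
      } else {
        dt <- log(exp(g * (t - s0)) + remaining / A) / g - (t - s0)
        return(t + dt - t0)
      }
    }
  }
}

#' Simulate a Kingman-coalescent genealogy
#'
#' Draws coalescent node times for `n` sampled lineages under a piecewise
#' demography (haploid Ne convention, appropriate for mtDNA) and returns
#' the genealogy as an `ape::phylo` tree with branch lengths in
#' generations.
#'
#' @param n number of tips (>= 2).
#' @param demography a [DemographicModel].
#' @param seed optional integer seed; identical seeds give identical trees.
#' @return An ultrametric `phylo` with tip labels `t1..tn` and an attribute
#'   `"tmrca"` (generations).
#' @export
simulateGenealogy <- function(n, demography = demographicModel(), seed = NULL) {
  if (n < 2L) stop("at least two lineages are required")
  if (!is.null(seed)) set.seed(seed)
  active <- seq_len(n)
  # provisional ids: tips 1..n, internals n+1 .. 2n-1 in coalescence order
  nodeHeight <- c(rep(0, n), rep(NA_real_, n - 1L))
  parentOf <- rep(NA_integer_, 2L * n - 1L)
  t <- 0
  nextInternal <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    w <- .coalWait(demography, t, k * (k - 1) / 2, stats::rexp(1))
    t <- t + w
    pick <- sample(seq_along(active), 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    nodeHeight[nextInternal] <- t
    parentOf[c(a, b)] <- nextInternal
    active <- c(active[-pick], nextInternal)
    nextInternal <- nextInternal + 1L
  }
  # assemble ape phylo: internal ids must be n+1 (root) .. 2n-1
  internals <- (n + 1L):(2L * n - 1L)
  # relabel so the root is n+1, others in decreasing height
  ord <- internals[order(nodeHeight[internals], decreasing = TRUE)]
  newId <- integer(2L * n - 1L)
  newId[seq_len(n)] <- seq_len(n)
  newId[ord] <- internals
  edges <- cbind(newId[parentOf[!is.na(parentOf)]], newId[which(!is.na(parentOf))])
  lens <- nodeHeight[parentOf[!is.na(parentOf)]] - nodeHeight[which(!is.na(parentOf))]
  phy <- structure(list(
    edge = edges, edge.length = lens, Nnode = n - 1L,
    tip.label = paste0("t", seq_len(n))), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "tmrca") <- t
  phy
}

#' Drop class-partitioned Poisson mutations onto a genealogy
#'
#' Each branch receives, per site class, a Poisson number of mutations with
#' mean `rate * branch length`; mutated positions (and derived alleles) are
#' drawn from the reference's per-class site pools, with recurrence
#' allowed. A site mutating again on a nested branch reverts, producing a
#' "!"-marked back mutation in the emitted haplotypes. When the purifying
#' knob is on, non-synonymous mutations older than the threshold are
#' removed with the configured probability.
#'
#' @param gen a `phylo` genealogy with branch lengths in generations.
#' @param model a [MutationModel].
#' @param ref an [MtReference].
#' @param seed optional integer seed.
#' @param population,region metadata stored on the emitted samples.
#' @return List with `haplotypes` (a [HaplotypeSet] over the tips),
#'   `events` (data.frame of all retained mutation events with their
#'   branch and class), and `gen`.
#' @export
dropMutations <- function(gen, model, ref, seed = NULL,
                          population = "sim", region = "SIM") {
  if (!is.null(seed)) set.seed(seed)
  gen <- ape::reorder.phylo(gen, "cladewise")  # parents before children
  pools <- sitePools(ref)
  for (cl in names(model@rates))
    if (model@rates[[cl]] > 0 && nrow(pools[[cl]]) == 0L)
      stop("positive mutation rate for class ", cl, " but its site pool is empty")
  nTip <- length(gen$tip.label)
  depth <- ape::node.depth.edgelength(gen)      # distance from root
  totalDepth <- max(depth)
  events <- list()
  for (e in seq_len(nrow(gen$edge))) {
    len <- gen$edge.length[e]
    for (cl in names(model@rates)) {
      lambda <- model@rates[[cl]] * len
      if (lambda <= 0) next
      m <- stats::rpois(1L, lambda)
      if (m == 0L) next
      pool <- pools[[cl]]
      draw <- pool[sample.int(nrow(pool), m, replace = TRUE), , drop = FALSE]
      # age of each event, in generations before present
      frac <- stats::runif(m)
      ageGen <- totalDepth - (depth[gen$edge[e, 1L]] + frac * len)
      keep <- rep(TRUE, m)
      if (cl == "nonsynonymous" && model@selectionRemovalProb > 0) {
        old <- ageGen > model@selectionThreshold
        keep[old] <- stats::runif(sum(old)) > model@selectionRemovalProb
      }
      if (any(keep))
        events[[length(events) + 1L]] <- data.frame(
          edge = e, class = cl, position = draw$position[keep],
          alt = draw$alt[keep], age_gen = ageGen[keep],
          stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(edge = integer(0), class = character(0), position = integer(0),
      alt = character(0), age_gen = numeric(0))
  # accumulate states tip-ward; a repeat hit at a mutated position reverts
  edgeEventsByChild <- split(seq_len(nrow(events)), gen$edge[events$edge, 2L])
  stateOf <- vector("list", nTip + gen$Nnode)
  backOf <- vector("list", nTip + gen$Nnode)
  root <- nTip + 1L
  stateOf[[root]] <- character(0)   # named character: position -> alt
  backOf[[root]] <- integer(0)
  ordEdges <- seq_len(nrow(gen$edge))
  for (e in ordEdges) {
    par <- gen$edge[e, 1L]; ch <- gen$edge[e, 2L]
    st <- stateOf[[par]]; bk <- backOf[[par]]
    evI <- edgeEventsByChild[[as.character(ch)]]
    if (!is.null(evI)) {
      evI <- evI[order(-events$age_gen[evI])]
      for (i in evI) {
        p <- as.character(events$position[i])
        if (!is.null(st[p]) && !is.na(st[p])) {
          # site already derived: revert to ancestral state
          st <- st[names(st) != p]
          bk[p] <- if (is.na(bk[p])) 1L else bk[p] + 1L
        } else {
          st[p] <- events$alt[i]
        }
      }
    }
    stateOf[[ch]] <- st
    backOf[[ch]] <- bk
  }
  vlist <- lapply(seq_len(nTip), function(tip) {
    st <- stateOf[[tip]]
    if (!length(st)) return(emptyVariantTable())
    pos <- as.integer(names(st))
    refB <- referenceBase(ref, pos)
    data.frame(position = pos, ins_index = NA_integer_, ref = refB,
      derived = unname(st),
      kind = vapply(seq_along(pos), function(i) .substitutionKind(refB[i], st[[i]]), character(1)),
      back = 0L, het = NA_character_, stringsAsFactors = FALSE)[order(pos), , drop = FALSE]
  })
  info <- data.frame(sample_id = gen$tip.label,
    population = population, region_code = region, source = "simulated",
    stringsAsFactors = FALSE)
  list(haplotypes = haplotypeSet(info, vlist), events = events, gen = gen)
}

# star genealogy: all n lineages coalesce at depth T (founder-effect shape)
.starGenealogy <- function(n, depthGen) {
  edge <- cbind(rep(n + 1L, n), seq_len(n))
  phy <- structure(list(edge = edge, edge.length = rep(depthGen, n),
    Nnode = 1L, tip.label = paste0("t", seq_len(n))), class = "phylo")
  attr(phy, "tmrca") <- depthGen
  phy
}

#' Named simulation scenarios
#'
#' Produces a complete input bundle (haplotypes, true genealogy and a
#' machine-readable truth record) for one of the study-shaped scenarios:
#'
#' * `founder_star`: a founder-effect clade, all lineages radiating from a
#'   single founder haplotype at a known age (default 20 tips, 10,000
#'   years) — the pattern a star-like sub-clade such as the Caucasian
#'   M1a1b2 cluster shows.
#' * `two_phase_expansion`: a single population whose haploid Ne steps up
#'   in two phases (defaults: Ne 500 beyond 880 generations (~22 KYA),
#'   5,000 until 400 generations (~10 KYA), 50,000 since), the shape that
#'   produces two visible expansion phases in a skyline.
#' * `two_pop_divergence`: two populations of constant size separated for
#'   `divergenceGen` generations (0 = panmixia), for FST calibration.
#' * `null_language`: several panmictic demes with language families
#'   assigned at random and random coordinates — no true gene-geography or
#'   gene-language association.
#'
#' @param name scenario name.
#' @param params named list overriding the scenario defaults.
#' @param seed integer seed governing all randomness in the bundle.
#' @param ref an [MtReference] (defaults to the packaged one).
#' @return List with elements `haplotypes`, `genealogy` (or a list of
#'   them), `truth` (named list), `params`.
#' @export
scenario <- function(name, params = list(), seed = 1L, ref = loadMtReference()) {
  set.seed(seed)
  defaults <- switch(name,
    founder_star = list(n = 20L, ageYears = 10000, generationTime = 25,
      mutation = mutationModel()),
    two_phase_expansion = list(n = 50L,
      demography = demographicModel(start = c(0, 400, 880),
        ne = c(50000, 5000, 500)),
      mutation = mutationModel()),
    two_pop_divergence = list(nPerPop = 15L, ne = 2000,
      divergenceGen = 0, mutation = mutationModel()),
    null_language = list(nPops = 8L, nPerPop = 10L, ne = 5000,
      families = c("AfroAsiatic", "IndoEuropean", "NigerCongo"),
      mutation = mutationModel()),
    stop("unknown scenario: ", name))
  p <- utils::modifyList(defaults, params)
  if (name == "founder_star") {
    depthGen <- p$ageYears / p$generationTime
    gen <- .starGenealogy(p$n, depthGen)
    sim <- dropMutations(gen, p$mutation, ref, population = "founder", region = "SIM")
    truth <- list(scenario = name, seed = seed, tmrca_years = p$ageYears,
      tmrca_generations = depthGen, n = p$n)
    return(list(haplotypes = sim$haplotypes, genealogy = gen, truth = truth, params = p))
  }
  if (name == "two_phase_expansion") {
    gen <- simulateGenealogy(p$n, p$demography)
    sim <- dropMutations(gen, p$mutation, ref, population = "expanding", region = "SIM")
    truth <- list(scenario = name, seed = seed,
      ne_epochs = p$demography@epochs, tmrca_generations = attr(gen, "tmrca"), n = p$n)
    return(list(haplotypes = sim$haplotypes, genealogy = gen, truth = truth, params = p))
  }
  if (name == "two_pop_divergence") {
    # two demes: independent coalescence until the split, then one pool
    gen <- .structuredPair(p$nPerPop, p$ne, p$divergenceGen)
    sim <- dropMutations(gen, p$mutation, ref)
    hs <- sim$haplotypes
    hs@info$population <- rep(c("popA", "popB"), each = p$nPerPop)
    truth <- list(scenario = name, seed = seed, divergence_generations = p$divergenceGen,
      ne = p$ne, expected_fst_zero = p$divergenceGen == 0)
    return(list(haplotypes = hs, genealogy = gen, truth = truth, params = p))
  }
  # null_language
  pops <- paste0("pop", seq_len(p$nPops))
  gen <- simulateGenealogy(p$nPops * p$nPerPop, demographicModel(ne = p$ne))
  sim <- dropMutations(gen, p$mutation, ref)
  hs <- sim$haplotypes
  hs@info$population <- rep(pops, each = p$nPerPop)
  fam <- stats::setNames(sample(p$families, p$nPops, replace = TRUE), pops)
  coords <- data.frame(population = pops,
    lat = stats::runif(p$nPops, -30, 45), lon = stats::runif(p$nPops, -15, 50))
  truth <- list(scenario = name, seed = seed, association = "none",
    families = as.list(fam))
  list(haplotypes = hs, genealogy = gen, truth = truth, params = p,
    familyMap = fam, coordinates = coords)
}

# two demes of nPer lineages each, constant haploid ne, merged at tau
.structuredPair <- function(nPer, ne, tau) {
  n <- 2L * nPer
  nodeHeight <- c(rep(0, n), rep(NA_real_, n - 1L))
  parentOf <- rep(NA_integer_, 2L * n - 1L)
  nextInternal <- n + 1L
  coalesce <- function(active, t0, tmax) {
    t <- t0
    while (length(active) > 1L) {
      k <- length(active)
      w <- stats::rexp(1) * 2 * ne / (k * (k - 1))
      if (t + w > tmax) return(list(active = active, t = tmax))
      t <- t + w
      id <- nextInternal
      nextInternal <<- id + 1L
      nodeHeight[id] <<- t
      pick <- sample(k, 2L)
      parentOf[active[pick]] <<- id
      active <- c(active[-pick], id)
    }
    list(active = active, t = t)
  }
  a <- coalesce(seq_len(nPer), 0, tau)
  b <- coalesce(nPer + seq_len(nPer), 0, tau)
  coalesce(c(a$active, b$active), tau, Inf)
  t <- max(nodeHeight, na.rm = TRUE)
  internals <- (n + 1L):(2L * n - 1L)
  ord <- internals[order(nodeHeight[internals], decreasing = TRUE)]
  newId <- integer(2L * n - 1L)
  newId[seq_len(n)] <- seq_len(n)
  newId[ord] <- internals
  edges <- cbind(newId[parentOf[!is.na(parentOf)]], newId[which(!is.na(parentOf))])
  lens <- nodeHeight[parentOf[!is.na(parentOf)]] - nodeHeight[which(!is.na(parentOf))]
  phy <- structure(list(edge = edges, edge.length = lens, Nnode = n - 1L,
    tip.label = paste0("t", seq_len(n))), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "tmrca") <- t
  phy
}

#' Write a scenario bundle to disk
#'
#' Emits the sample-table TSV, the haplotype FASTA, the true genealogy in
#' newick, and a YAML truth record (with the seed and parameters), so that
#' every downstream module can be run from files.
#'
#' @param bundle a list returned by [scenario()].
#' @param dir output directory (created if needed).
#' @param ref an [MtReference].
#' @param prefix file name prefix.
#' @return Invisibly, the paths written.
#' @export
writeScenario <- function(bundle, dir, ref = loadMtReference(), prefix = "scenario") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    table = file.path(dir, paste0(prefix, "_samples.tsv")),
    fasta = file.path(dir, paste0(prefix, ".fasta")),
    tree = file.path(dir, paste0(prefix, "_genealogy.nwk")),
    truth = file.path(dir, paste0(prefix, "_truth.yaml")))
  writeSampleTable(bundle$haplotypes, paths["table"])
  writeHaplotypeFasta(bundle$haplotypes, ref, paths["fasta"])
  ape::write.tree(bundle$genealogy, paths["tree"])
  yaml::write_yaml(bundle$truth, paths["truth"])
  invisible(paths)
}
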