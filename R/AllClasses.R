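#' @import methods
NULL

#' MtReference: packaged human mtDNA reference model
#'
#' Holds the 16,569-bp mitochondrial reference frame (rCRS coordinates), its
#' sequence, the control-region segments, the gene annotation (protein, tRNA,
#' rRNA records with strand), and the vertebrate mitochondrial codon table.
#' All coordinate-dependent operations in the package consult an object of
#' this class.
#'
#' @slot name reference identifier.
#' @slot sequence character vector of length 16569, one base per position.
#' @slot controlSegments integer matrix with columns `start`, `end` (1-based,
#'   closed) giving the control-region segments.
#' @slot genes data.frame with columns `name`, `start`, `end`, `type`
#'   (`protein`, `trna`, `rrna`, `control`), `strand` (`+`/`-`).
#' @slot codonTable named character vector mapping codons to amino acids
#'   under the vertebrate mitochondrial genetic code.
#'
#' @exportClass MtReference
setClass("MtReference",
  representation(
    name = "character",
    sequence = "character",
    controlSegments = "matrix",
    genes = "data.frame",
    codonTable = "character"
  )
)

setValidity("MtReference", function(object) {
  msg <- character()
  if (length(object@sequence) != 16569L)
    msg <- c(msg, "sequence must have exactly 16569 positions")
  if (!all(object@sequence %in% c("A", "C", "G", "T")))
    msg <- c(msg, "sequence must contain only A/C/G/T")
  g <- object@genes
  if (any(g$start < 1L) || any(g$end > 16569L) || any(g$start > g$end))
    msg <- c(msg, "gene records must lie within [1, 16569]")
  cs <- object@controlSegments
  hvs1 <- any(cs[, 1L] <= 16024L & cs[, 2L] >= 16400L)
  if (!hvs1)
    msg <- c(msg, "HVS-I window [16024, 16400] must lie inside a control segment")
  if (length(msg)) msg else TRUE
})

#' HaplotypeSet: a collection of mtDNA haplotypes
#'
#' Container for per-sample variant sets scored against an [MtReference].
#' Each sample carries metadata (population, broad region code, source tag),
#' a variant table (see [parseVariantToken()] for the columns), and a
#' coverage mask of typed position ranges.
#'
#' @slot info data.frame with columns `sample_id`, `population`,
#'   `region_code`, `source`.
#' @slot variants named list (by sample id) of variant data.frames.
#' @slot coverage named list (by sample id) of two-column integer matrices
#'   (`start`, `end`) of typed ranges; an entry spanning 1..16569 means
#'   fully typed.
#'
#' @exportClass HaplotypeSet
setClass("HaplotypeSet",
  representation(
    info = "data.frame",
    variants = "list",
    coverage = "list"
  )
)

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  ids <- object@info$sample_id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated sample ids")
  if (!identical(names(object@variants), ids))
    msg <- c(msg, "variants list names must match info$sample_id")
  if (!identical(names(object@coverage), ids))
    msg <- c(msg, "coverage list names must match info$sample_id")
  for (id in ids) {
    v <- object@variants[[id]]
    if (nrow(v)) {
      key <- paste(v$position, ifelse(is.na(v$ins_index), 0L, v$ins_index))
      if (anyDuplicated(key))
        msg <- c(msg, sprintf("sample %s: two variants share (position, insertion index)", id))
      cov <- object@coverage[[id]]
      inside <- vapply(v$position, function(p) any(p >= cov[, 1L] & p <= cov[, 2L]), logical(1))
      if (!all(inside))
        msg <- c(msg, sprintf("sample %s: variant outside coverage", id))
    }
  }
  if (length(msg)) msg else TRUE
})

#' HaploNetwork: a median-joining haplotype network
#'
#' Nodes are observed haplotypes plus synthesised median vectors; edges are
#' labelled with the variant sites separating their endpoints, and carry the
#' weighted mutation distance.
#'
#' @slot states character matrix; rows are network nodes, columns are
#'   variant sites (named by canonical token of the derived state), entries
#'   are the allelic state at that site.
#' @slot nodes data.frame with columns `id`, `type` (`observed`/`median`),
#'   `samples` (comma-separated sample ids carried by the node).
#' @slot edges data.frame with columns `from`, `to`, `weight`, `sites`
#'   (comma-separated site labels on which the endpoints differ).
#' @slot siteWeights named numeric vector of per-site weights.
#'
#' @exportClass HaploNetwork
setClass("HaploNetwork",
  representation(
    states = "matrix",
    nodes = "data.frame",
    edges = "data.frame",
    siteWeights = "numeric"
  )
)

setValidity("HaploNetwork", function(object) {
  msg <- character()
  if (nrow(object@states) != nrow(object@nodes))
    msg <- c(msg, "states and nodes disagree on node count")
  if (nrow(object@nodes) > 1L) {
    g <- igraph::graph_from_data_frame(object@edges[, c("from", "to")],
      directed = FALSE, vertices = object@nodes$id)
    if (!igraph::is_connected(g)) msg <- c(msg, "network must be connected")
  }
  if (length(msg)) msg else TRUE
})

#' CladeTree: rooted, mutation-labelled haplogroup tree
#'
#' A rooted tree whose branches carry defining-variant lists; nodes may be
#' labelled with haplogroup names (e.g. `M1a1b2`) and carry the sample ids
#' of haplotypes observed at that node.
#'
#' @slot nodes data.frame with columns `id`, `clade` (NA when unlabelled),
#'   `samples` (comma-separated sample ids observed at the node), `n_sub`
#'   (number of samples at or below the node).
#' @slot edges data.frame with columns `parent`, `child`, `n_mut`.
#' @slot edgeVariants list parallel to `edges` rows; each element a variant
#'   data.frame for the mutations on that branch.
#' @slot root id of the root node.
#'
#' @exportClass CladeTree
setClass("CladeTree",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    edgeVariants = "list",
    root = "character"
  )
)

setValidity("CladeTree", function(object) {
  msg <- character()
  if (!(object@root %in% object@nodes$id)) msg <- c(msg, "root must be a node")
  if (nrow(object@edges) != nrow(object@nodes) - 1L)
    msg <- c(msg, "a rooted tree needs exactly one edge per non-root node")
  if (nrow(object@edges) && anyDuplicated(object@edges$child))
    msg <- c(msg, "every node must have a single parent")
  # conservation of subtended sample counts
  if (nrow(object@edges)) {
    for (p in unique(object@edges$parent)) {
      kids <- object@edges$child[object@edges$parent == p]
      own <- object@nodes$samples[object@nodes$id == p]
      nOwn <- if (is.na(own) || own == "") 0L else length(strsplit(own, ",")[[1]])
      nSub <- object@nodes$n_sub[object@nodes$id == p]
      nKids <- sum(object@nodes$n_sub[match(kids, object@nodes$id)])
      if (nSub != nOwn + nKids)
        msg <- c(msg, sprintf("node %s: subtended counts do not add up", p))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ClockModel: a calibration converting rho to years
#'
#' Two modes are supported. `linear` multiplies rho by a constant number of
#' years per substitution (the synonymous coding-region clock). `corrected`
#' maps whole-molecule rho through a monotone calibration curve that absorbs
#' the time-dependent loss of mildly deleterious (mostly non-synonymous)
#' mutations under purifying selection; with the correction disabled it
#' reduces to `rho / (ratePerSiteYear * genomeSites)`.
#'
#' @slot id character identifier.
#' @slot classFilter `"synonymous_only"` or `"all_sites"`; which mutation
#'   classes feed the rho this clock expects.
#' @slot mode `"linear"` or `"corrected"`.
#' @slot yearsPerSub years per substitution (linear mode).
#' @slot ratePerSiteYear substitutions per site per year (corrected mode,
#'   correction disabled).
#' @slot genomeSites number of sites the rate applies to.
#' @slot curve numeric `c(a, b)`: corrected age in years = `a*rho + b*rho^2`
#'   (both nonnegative, so the curve is monotone and passes through the
#'   origin). Empty when the correction is disabled.
#' @slot calibRange numeric `c(min, max)` rho range covered by the
#'   calibration; outside it [ageCorrected()] warns about extrapolation.
#'
#' @exportClass ClockModel
setClass("ClockModel",
  representation(
    id = "character",
    classFilter = "character",
    mode = "character",
    yearsPerSub = "numeric",
    ratePerSiteYear = "numeric",
    genomeSites = "numeric",
    curve = "numeric",
    calibRange = "numeric"
  )
)

setValidity("ClockModel", function(object) {
  msg <- character()
  if (!object@mode %in% c("linear", "corrected"))
    msg <- c(msg, "mode must be 'linear' or 'corrected'")
  if (!object@classFilter %in% c("synonymous_only", "all_sites"))
    msg <- c(msg, "classFilter must be 'synonymous_only' or 'all_sites'")
  if (object@mode == "linear" && (length(object@yearsPerSub) != 1L || object@yearsPerSub <= 0))
    msg <- c(msg, "linear mode needs yearsPerSub > 0")
  if (object@mode == "corrected" && length(object@curve) == 2L && any(object@curve < 0))
    msg <- c(msg, "correction curve coefficients must be nonnegative (monotone through origin)")
  if (length(msg)) msg else TRUE
})

#' SkylineEstimate: stepwise Ne(t) reconstruction
#'
#' @slot intervals data.frame with columns `t_start`, `t_end`, `ne`
#'   (haploid effective size), ordered from the present backwards.
#' @slot units `"generations"` or `"years"` for the time axis.
#' @slot generationTimeYears generation time used for unit conversion.
#' @slot grouping number of consecutive coalescent intervals pooled per step.
#'
#' @exportClass SkylineEstimate
setClass("SkylineEstimate",
  representation(
    intervals = "data.frame",
    units = "character",
    generationTimeYears = "numeric",
    grouping = "numeric"
  )
)

setValidity("SkylineEstimate", function(object) {
  msg <- character()
  iv <- object@intervals
  if (any(iv$ne <= 0)) msg <- c(msg, "Ne must be positive")
  if (nrow(iv) > 1L && any(abs(iv$t_start[-1L] - iv$t_end[-nrow(iv)]) > 1e-8 * max(iv$t_end)))
    msg <- c(msg, "intervals must be contiguous")
  if (length(msg)) msg else TRUE
})

#' DemographicModel: piecewise Ne(t) in backward time
#'
#' Epochs are contiguous from time 0 (the present). Within an epoch starting
#' at `start` with size `ne` and forward growth rate `growth` (per
#' generation), the backward-time size is `ne * exp(-growth * (t - start))`.
#'
#' @slot epochs data.frame with columns `start` (generations before present),
#'   `ne` (haploid size at the epoch's recent end), `growth`.
#'
#' @exportClass DemographicModel
setClass("DemographicModel", representation(epochs = "data.frame"))

setValidity("DemographicModel", function(object) {
  e <- object@epochs
  msg <- character()
  if (nrow(e) == 0L) msg <- c(msg, "at least one epoch required")
  if (nrow(e) && e$start[1L] != 0) msg <- c(msg, "epochs must start at time 0")
  if (nrow(e) > 1L && any(diff(e$start) <= 0)) msg <- c(msg, "epoch starts must increase")
  if (any(e$ne <= 0)) msg <- c(msg, "Ne must be positive")
  if (length(msg)) msg else TRUE
})

#' MutationModel: class-partitioned Poisson mutation rates
#'
#' Genome-wide per-generation mutation rates for each site class, plus an
#' optional purifying-selection knob: a probability that a non-synonymous
#' mutation older than `selectionThreshold` generations is removed from the
#' observable record.
#'
#' @slot rates named numeric: `control`, `rna_gene`, `synonymous`,
#'   `nonsynonymous`, each the expected mutations per lineage per generation
#'   in that class over the whole molecule.
#' @slot selectionRemovalProb probability in \[0, 1\].
#' @slot selectionThreshold age threshold in generations.
#'
#' @exportClass MutationModel
setClass("MutationModel",
  representation(
    rates = "numeric",
    selectionRemovalProb = "numeric",
    selectionThreshold = "numeric"
  )
)

setValidity("MutationModel", function(object) {
  msg <- character()
  need <- c("control", "rna_gene", "synonymous", "nonsynonymous")
  if (!all(need %in% names(object@rates))) msg <- c(msg, "rates must name all four site classes")
  if (any(object@rates < 0)) msg <- c(msg, "rates must be nonnegative")
  if (object@selectionRemovalProb < 0 || object@selectionRemovalProb > 1)
    msg <- c(msg, "selectionRemovalProb must be in [0, 1]")
  if (length(msg)) msg else TRUE
})
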