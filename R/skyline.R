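#' Classical (and generalized) skyline plot
#'
#' Estimates haploid effective population size through time from the
#' coalescent intervals of a timed genealogy: an interval with `i` extant
#' lineages and duration `t` yields `Ne = i*(i-1)*t/2` in the units of the
#' branch lengths. With `grouping > 1`, consecutive intervals are pooled
#' (the generalized skyline): a composite of intervals `j` with `e`
#' coalescent events estimates `Ne = sum_j i_j*(i_j-1)*t_j / (2*e)`.
#'
#' @param gen a rooted, binary, ultrametric `ape::phylo` genealogy (tips at
#'   time 0).
#' @param grouping number of consecutive coalescent intervals pooled per
#'   skyline step.
#' @param units time units of the branch lengths (`"generations"` or
#'   `"years"`).
#' @param generationTimeYears generation time for unit conversion (default
#'   25 years).
#' @return A [SkylineEstimate]; intervals run from the present backwards
#'   and `ne` is in haploid individuals.
#' @export
classicalSkyline <- function(gen, grouping = 1L,
                             units = c("generations", "years"),
                             generationTimeYears = 25) {
  units <- match.arg(units)
  if (!inherits(gen, "phylo")) stop("gen must be an ape phylo object")
  nTip <- length(gen$tip.label)
  if (!ape::is.rooted(gen) || nrow(gen$edge) != 2L * nTip - 2L)
    stop("the genealogy must be rooted and strictly binary")
  # coalescent intervals from node times (tips at 0, increasing rootward)
  depth <- ape::node.depth.edgelength(gen)
  tt <- max(depth) - depth
  if (max(tt[seq_len(nTip)]) > 1e-6 * max(tt))
    stop("the genealogy must be ultrametric (all tips at time 0)")
  coalT <- sort(tt[(nTip + 1L):(nTip + gen$Nnode)])
  lineages <- nTip:2
  lengths <- diff(c(0, coalT))
  k <- length(lineages)
  groupId <- ceiling(seq_len(k) / grouping)
  tEnd <- cumsum(lengths)
  tStart <- c(0, tEnd[-k])
  rows <- lapply(unique(groupId), function(g) {
    j <- which(groupId == g)
    events <- length(j)  # one coalescence ends each classical interval
    ne <- sum(lineages[j] * (lineages[j] - 1) * lengths[j]) / (2 * events)
    data.frame(t_start = tStart[j[1L]], t_end = tEnd[j[length(j)]], ne = ne)
  })
  iv <- do.call(rbind, rows)
  iv <- iv[iv$ne > 0, , drop = FALSE]  # zero-length tie intervals carry no information
  # re-close gaps left by zero-information intervals
  if (nrow(iv) > 1L) iv$t_start[-1L] <- iv$t_end[-nrow(iv)]
  rownames(iv) <- NULL
  if (units == "years") iv$ne <- iv$ne / generationTimeYears
  methods::new("SkylineEstimate", intervals = iv, units = units,
    generationTimeYears = generationTimeYears, grouping = as.numeric(grouping))
}

setMethod("show", "SkylineEstimate", function(object) {
  iv <- object@intervals
  cat("SkylineEstimate:", nrow(iv), "steps over [0, ",
    format(max(iv$t_end), digits = 5), "] ", object@units,
    "; Ne range ", format(min(iv$ne), digits = 4), "-",
    format(max(iv$ne), digits = 4), "\n", sep = "")
})

#' Skyline intervals as a data.frame
#' @param est a [SkylineEstimate].
#' @export
skylineIntervals <- function(est) est@intervals

#' Write a skyline estimate as TSV
#' @param est a [SkylineEstimate].
#' @param path file path.
#' @export
writeSkyline <- function(est, path) {
  utils::write.table(est@intervals, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rescale a skyline's time axis through a corrected clock
#'
#' Published whole-molecule skylines are plotted on a time axis obtained by
#' converting the genealogy's mutational depth through the
#' purifying-selection-corrected clock: the root's rho maps to the
#' corrected age, and intermediate times are mapped through the same
#' monotone curve proportionally in rho. Ne values are converted to haploid
#' individuals using the generation time when the input axis is in
#' generations.
#'
#' @param est a [SkylineEstimate] whose time axis is proportional to
#'   mutational depth (e.g. a genealogy in generations under a constant
#'   mutation rate).
#' @param clock a corrected [ClockModel].
#' @param rho the observed whole-molecule rho at the root of the genealogy.
#' @return A [SkylineEstimate] in years; interval ordering is preserved
#'   because the clock map is monotone.
#' @export
rescaleTime <- function(est, clock, rho) {
  if (clock@mode != "corrected") stop("rescaleTime expects a corrected clock")
  iv <- est@intervals
  tRoot <- max(iv$t_end)
  if (tRoot <= 0) stop("degenerate skyline: zero total depth")
  mapT <- function(t) .clockAge(rho * t / tRoot, clock)
  out <- data.frame(t_start = mapT(iv$t_start), t_end = mapT(iv$t_end), ne = iv$ne)
  if (est@units == "generations") {
    # Ne stays in haploid individuals; only the axis changes units
    out$ne <- iv$ne
  }
  methods::new("SkylineEstimate", intervals = out, units = "years",
    generationTimeYears = est@generationTimeYears, grouping = est@grouping)
}
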