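#' Filtered mutation count of a branch
#'
#' @param ev branch variant data.frame.
#' @param classFilter `"all_sites"` or `"synonymous_only"`.
#' @param ref an [MtReference] (required for `synonymous_only`).
#' @return Integer count; reversals ("!"-marked changes) count as events.
#' @keywords internal
.branchMutations <- function(ev, classFilter, ref) {
  if (!nrow(ev)) return(0L)
  if (classFilter == "all_sites") return(nrow(ev))
  if (is.null(ref)) stop("a reference is required for class-filtered counting")
  keep <- vapply(seq_len(nrow(ev)), function(i) {
    der <- ev$derived[i]
    if (is.na(der)) der <- chartr("ACGT", "GTAC", referenceBase(ref, ev$position[i]))
    refA <- ev$ref[i]
    if (is.na(refA)) refA <- referenceBase(ref, ev$position[i])
    classifySite(ref, ev$position[i], refA, der) == "synonymous"
  }, logical(1))
  sum(keep)
}

#' The rho statistic of a clade
#'
#' Mean number of (class-filtered) mutations on the path from the clade's
#' root haplotype to each of its sampled haplotypes. Samples observed at
#' internal nodes contribute their (shorter) path; back mutations count as
#' mutation events.
#'
#' @param tree a labelled [CladeTree].
#' @param clade clade label.
#' @param classFilter `"all_sites"` (default) or `"synonymous_only"`.
#' @param ref an [MtReference], needed when filtering by class.
#' @return Nonnegative numeric.
#' @export
rhoStatistic <- function(tree, clade, classFilter = "all_sites", ref = NULL) {
  rootN <- cladeRootNode(tree, clade)
  ids <- .subtreeIds(tree, rootN)
  total <- 0
  nSamp <- 0L
  below <- stats::setNames(rep(0, length(ids)), ids)
  # path mutation counts relative to the clade root, BFS order
  queue <- rootN
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    nHere <- length(.splitSamples(tree@nodes$samples[tree@nodes$id == u]))
    total <- total + nHere * below[u]
    nSamp <- nSamp + nHere
    for (k in which(tree@edges$parent == u)) {
      ch <- tree@edges$child[k]
      below[ch] <- below[u] + .branchMutations(tree@edgeVariants[[k]], classFilter, ref)
      queue <- c(queue, ch)
    }
  }
  if (nSamp == 0L) stop("clade ", clade, " contains no samples")
  as.numeric(total / nSamp)
}

#' Saillard standard error of rho
#'
#' `sigma = sqrt( n^-2 * sum over clade branches of n_b^2 * m_b )`, where
#' `n_b` is the number of samples subtended by the branch and `m_b` its
#' (class-filtered) mutation count.
#'
#' @inheritParams rhoStatistic
#' @return Nonnegative numeric.
#' @export
sigmaSaillard <- function(tree, clade, classFilter = "all_sites", ref = NULL) {
  rootN <- cladeRootNode(tree, clade)
  ids <- .subtreeIds(tree, rootN)
  n <- sum(vapply(ids, function(id)
    length(.splitSamples(tree@nodes$samples[tree@nodes$id == id])), integer(1)))
  if (n == 0L) stop("clade ", clade, " contains no samples")
  ss <- 0
  for (k in which(tree@edges$child %in% setdiff(ids, rootN))) {
    m <- .branchMutations(tree@edgeVariants[[k]], classFilter, ref)
    nb <- tree@nodes$n_sub[tree@nodes$id == tree@edges$child[k]]
    ss <- ss + nb^2 * m
  }
  as.numeric(sqrt(ss) / n)
}

#' Construct a linear clock
#'
#' @param yearsPerSub years per (class-filtered) substitution.
#' @param classFilter mutation classes the clock expects (default
#'   synonymous-only, the coding-region synonymous clock).
#' @param id identifier.
#' @return A [ClockModel].
#' @export
linearClock <- function(yearsPerSub, classFilter = "synonymous_only",
                        id = "linear") {
  if (yearsPerSub <= 0) stop("yearsPerSub must be positive")
  methods::new("ClockModel", id = id, classFilter = classFilter,
    mode = "linear", yearsPerSub = yearsPerSub, ratePerSiteYear = numeric(0),
    genomeSites = numeric(0), curve = numeric(0), calibRange = numeric(0))
}

#' Construct a whole-molecule corrected clock
#'
#' With `curve` of length 2 the clock maps rho to
#' `curve[1]*rho + curve[2]*rho^2` years (a monotone
#' purifying-selection-corrected calibration). With `curve = numeric(0)`
#' the correction is disabled and the clock is the linear whole-molecule
#' rate `rho / (ratePerSiteYear * genomeSites)`.
#'
#' @param ratePerSiteYear long-term substitution rate per site per year
#'   (default 1.695e-8).
#' @param genomeSites sites the rate applies to (default 16569).
#' @param curve numeric `c(a, b)` or `numeric(0)`.
#' @param calibRange rho range covered by the calibration.
#' @param id identifier.
#' @return A [ClockModel].
#' @export
correctedClock <- function(ratePerSiteYear = 1.695e-8, genomeSites = 16569,
                           curve = numeric(0), calibRange = numeric(0),
                           id = "corrected") {
  methods::new("ClockModel", id = id, classFilter = "all_sites",
    mode = "corrected", yearsPerSub = numeric(0),
    ratePerSiteYear = ratePerSiteYear, genomeSites = genomeSites,
    curve = curve, calibRange = calibRange)
}

setMethod("show", "ClockModel", function(object) {
  if (object@mode == "linear")
    cat("ClockModel '", object@id, "': linear, ",
      format(object@yearsPerSub, digits = 6), " years/substitution (",
      object@classFilter, ")\n", sep = "")
  else if (length(object@curve))
    cat("ClockModel '", object@id, "': corrected, age = ",
      format(object@curve[1L], digits = 6), "*rho + ",
      format(object@curve[2L], digits = 6), "*rho^2 years\n", sep = "")
  else
    cat("ClockModel '", object@id, "': corrected (correction disabled), rate ",
      format(object@ratePerSiteYear, digits = 4), "/site/year over ",
      object@genomeSites, " sites\n", sep = "")
})

#' Round an age to the nearest 100 years
#' @param age years.
#' @export
roundAge100 <- function(age) round(age / 100) * 100

#' Age under a linear clock
#'
#' @param rho rho statistic.
#' @param clock a linear [ClockModel].
#' @param round100 report rounded to the nearest 100 years (the convention
#'   used for published clade ages)?
#' @return Age in years.
#' @export
ageLinear <- function(rho, clock, round100 = TRUE) {
  stopifnot(methods::is(clock, "ClockModel"))
  if (clock@mode != "linear") stop("ageLinear requires a linear clock")
  age <- rho * clock@yearsPerSub
  if (round100) roundAge100(age) else age
}

#' Age under the corrected whole-molecule clock
#'
#' @param rho whole-molecule rho.
#' @param clock a corrected [ClockModel].
#' @param round100 round to the nearest 100 years?
#' @return Age in years. Warns when `rho` falls outside the calibrated
#'   range (extrapolation).
#' @export
ageCorrected <- function(rho, clock, round100 = TRUE) {
  stopifnot(methods::is(clock, "ClockModel"))
  if (clock@mode != "corrected") stop("ageCorrected requires a corrected clock")
  if (length(clock@curve) == 2L) {
    if (length(clock@calibRange) == 2L && length(rho) == 1L && rho > 0 &&
        (rho < clock@calibRange[1L] || rho > clock@calibRange[2L]))
      warning("rho ", format(rho), " outside the calibrated range [",
        clock@calibRange[1L], ", ", clock@calibRange[2L], "]; extrapolating")
    age <- clock@curve[1L] * rho + clock@curve[2L] * rho^2
  } else {
    age <- rho / (clock@ratePerSiteYear * clock@genomeSites)
  }
  if (round100) roundAge100(age) else age
}

.clockAge <- function(rho, clock, round100 = FALSE) {
  if (clock@mode == "linear") ageLinear(rho, clock, round100)
  else suppressWarnings(ageCorrected(rho, clock, round100))
}

#' 95% confidence interval of a clade age
#'
#' Applies the clock to `rho +/- 1.96*sigma`, flooring the lower rho bound
#' at zero. Because both clock modes are monotone nondecreasing in rho, the
#' interval brackets the point age.
#'
#' @param rho rho statistic.
#' @param sigma Saillard standard error.
#' @param clock a [ClockModel].
#' @param round100 round endpoints to the nearest 100 years?
#' @return Numeric `c(low, high)` in years.
#' @export
ci95Age <- function(rho, sigma, clock, round100 = TRUE) {
  if (sigma < 0) stop("sigma must be nonnegative")
  lo <- .clockAge(max(0, rho - 1.96 * sigma), clock)
  hi <- .clockAge(rho + 1.96 * sigma, clock)
  if (round100) c(roundAge100(lo), roundAge100(hi)) else c(lo, hi)
}

#' Fit a clock calibration from (rho, age) pairs
#'
#' Linear mode fits a least-squares slope through the origin (years per
#' substitution). Corrected mode fits the monotone curve
#' `age = a*rho + b*rho^2` through the origin by least squares with
#' nonnegativity of the coefficients enforced (falling back to the pure
#' linear term when the quadratic coefficient would be negative), and warns
#' when the pairs are not monotone.
#'
#' @param pairs data.frame or matrix with columns `rho`, `age` (>= 2 rows).
#' @param mode `"linear"` or `"corrected"`.
#' @param classFilter stored on the resulting clock.
#' @return A [ClockModel].
#' @export
fitCalibrationFromPairs <- function(pairs, mode = c("linear", "corrected"),
                                    classFilter = NULL) {
  mode <- match.arg(mode)
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 2L) stop("at least two (rho, age) pairs are required")
  o <- order(pairs$rho)
  x <- pairs$rho[o]; y <- pairs$age[o]
  if (anyDuplicated(x)) {
    y <- tapply(y, x, mean)
    x <- sort(unique(x))
  }
  if (mode == "linear") {
    slope <- sum(x * y) / sum(x^2)
    return(linearClock(slope,
      classFilter = if (is.null(classFilter)) "synonymous_only" else classFilter,
      id = "fitted-linear"))
  }
  if (any(diff(y) < 0))
    warning("(rho, age) pairs are not monotone; the fitted curve smooths over them")
  X <- cbind(x, x^2)
  cf <- as.numeric(solve(crossprod(X), crossprod(X, y)))
  if (cf[2L] < 0 || cf[1L] < 0) {
    cf <- c(sum(x * y) / sum(x^2), 0)
  }
  correctedClock(curve = cf, calibRange = range(x), id = "fitted-corrected")
}

.loadCladeAges <- function() {
  path <- system.file("extdata", "m1_u6_clade_ages.tsv", package = "mitophylo")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published clade-age calibration table for M1 and U6
#'
#' The packaged compilation of published coalescent-age estimates for M1,
#' U6 and their major sub-clades: sample size, synonymous rho with its age
#' under the synonymous coding-region clock, and whole-molecule rho with
#' its purifying-selection-corrected age and 95% CI.
#'
#' @return data.frame with columns `clade`, `n`, `rho_syn`, `age_syn`,
#'   `age_syn_pm`, `rho_full`, `age_full`, `ci_low`, `ci_high`.
#' @export
cladeAgeCalibration <- function() .loadCladeAges()

#' Packaged default clocks
#'
#' `defaultSynonymousClock()` returns the synonymous coding-region clock
#' recovered by a least-squares fit through the origin of the packaged
#' (rho, age) calibration pairs (about 7,995 years per synonymous
#' substitution). `defaultCorrectedClock()` returns the monotone
#' whole-molecule calibration fitted to the corrected-age pairs; pass
#' `correction = FALSE` for the plain long-term rate.
#'
#' @param exclude optional clade labels to leave out of the fit (used for
#'   leave-one-out validation).
#' @return A [ClockModel].
#' @export
defaultSynonymousClock <- function(exclude = character(0)) {
  tab <- .loadCladeAges()
  tab <- tab[!tab$clade %in% exclude, ]
  fitCalibrationFromPairs(data.frame(rho = tab$rho_syn, age = tab$age_syn), "linear")
}

#' @rdname defaultSynonymousClock
#' @param correction fit the monotone correction curve (`TRUE`) or use the
#'   uncorrected long-term rate (`FALSE`)?
#' @export
defaultCorrectedClock <- function(correction = TRUE, exclude = character(0)) {
  if (!correction) return(correctedClock())
  tab <- .loadCladeAges()
  tab <- tab[!tab$clade %in% exclude, ]
  fitCalibrationFromPairs(data.frame(rho = tab$rho_full, age = tab$age_full), "corrected")
}

#' Date every labelled clade of a tree
#'
#' Computes n, rho, sigma, age and 95% CI for each labelled clade under a
#' clock, in the shape of a published coalescent-age table.
#'
#' @param tree a labelled [CladeTree].
#' @param clock a [ClockModel].
#' @param ref an [MtReference] (used for class filtering).
#' @param clades clade labels to date; defaults to all labels on the tree.
#' @return data.frame with columns `clade`, `n`, `rho`, `sigma`, `age`,
#'   `ci_low`, `ci_high`.
#' @export
cladeAgeTable <- function(tree, clock, ref = NULL, clades = NULL) {
  if (is.null(clades)) clades <- sort(unique(stats::na.omit(tree@nodes$clade)))
  filt <- clock@classFilter
  rows <- lapply(clades, function(cl) {
    r <- rhoStatistic(tree, cl, filt, ref)
    s <- sigmaSaillard(tree, cl, filt, ref)
    ci <- ci95Age(r, s, clock)
    data.frame(clade = cl, n = length(cladeSamples(tree, cl)),
      rho = r, sigma = s, age = .clockAge(r, clock, round100 = TRUE),
      ci_low = ci[1L], ci_high = ci[2L], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
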