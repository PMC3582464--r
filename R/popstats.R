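#' Nested haplogroup frequency table
#'
#' Counts clade-labelled samples per population (or broad region) for a set
#' of haplogroup column labels, nesting counts by the haplogroup hierarchy:
#' a sample labelled `M1a1` counts towards `M1a1`, `M1a` and `M1`.
#' Region rows are the sums of their member populations.
#'
#' @param labels data.frame with columns `sample_id`, `population`,
#'   `region`, `clade`.
#' @param haplogroups column labels to tabulate (e.g.
#'   `c("U6", "U6a", "U6b", "M1", "M1a", "M1b")`).
#' @param grouping `"population"` (default; with region subtotal rows) or
#'   `"region"`.
#' @param populationSizes named integer vector giving each population's
#'   total sample size `n`. When omitted, `n` is the number of rows per
#'   population in `labels` (i.e. `labels` must then contain every surveyed
#'   sample, not just the haplogroup members).
#' @return data.frame with one row per group: `group`, `n`, then a count
#'   column and a percentage column (1 decimal, of row n) per haplogroup.
#' @export
frequencyTable <- function(labels, haplogroups, grouping = c("population", "region"),
                           populationSizes = NULL) {
  grouping <- match.arg(grouping)
  if (any(is.na(labels$clade) | labels$clade == ""))
    stop("unlabelled samples: ",
      paste(utils::head(labels$sample_id[is.na(labels$clade) | labels$clade == ""], 5L),
        collapse = ", "))
  inClade <- function(clades, hg) clades == hg | vapply(clades, isSubclade, logical(1), parent = hg)
  countFor <- function(sub) vapply(haplogroups, function(hg) sum(inClade(sub$clade, hg)), integer(1))
  pops <- unique(labels$population)
  regionOfPop <- vapply(pops, function(p) labels$region[labels$population == p][1L], character(1))
  if (is.null(populationSizes)) {
    populationSizes <- vapply(pops, function(p) sum(labels$population == p), integer(1))
  } else {
    missing <- setdiff(pops, names(populationSizes))
    if (length(missing)) stop("populationSizes missing for: ", paste(missing, collapse = ", "))
    populationSizes <- populationSizes[pops]
  }
  popCounts <- t(vapply(pops, function(p) countFor(labels[labels$population == p, , drop = FALSE]),
    integer(length(haplogroups))))
  rownames(popCounts) <- pops
  mkRows <- function(groupNames, nVec, cnt) {
    out <- data.frame(group = groupNames, n = as.integer(nVec), stringsAsFactors = FALSE)
    for (j in seq_along(haplogroups)) {
      out[[haplogroups[j]]] <- cnt[, j]
      pct <- ifelse(nVec > 0, round(100 * cnt[, j] / nVec, 1), NA_real_)
      out[[paste0(haplogroups[j], "_pct")]] <- pct
    }
    out
  }
  regions <- unique(regionOfPop)
  regN <- vapply(regions, function(r) sum(populationSizes[regionOfPop == r]), numeric(1))
  regCnt <- t(vapply(regions, function(r)
    colSums(popCounts[regionOfPop == r, , drop = FALSE]), numeric(length(haplogroups))))
  if (grouping == "region") return(mkRows(regions, regN, regCnt))
  rows <- list()
  for (r in regions) {
    rows[[length(rows) + 1L]] <- mkRows(r, regN[r], regCnt[r, , drop = FALSE])
    members <- pops[regionOfPop == r]
    rows[[length(rows) + 1L]] <- mkRows(members, populationSizes[members],
      popCounts[members, , drop = FALSE])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expand a regional count table into per-sample clade labels
#'
#' Inverse of tabulation: given per-population counts of nested haplogroups
#' (plus the population total `n`), emits one row per surveyed sample with
#' the deepest label its counts support; samples outside the listed
#' haplogroups get the label `"other"`.
#'
#' @param counts data.frame with columns `population`, `region`, `n`, and
#'   one count column per haplogroup label (nested labels such as `U6`,
#'   `U6a` with `U6a` a subset of `U6`).
#' @return data.frame with columns `sample_id`, `population`, `region`,
#'   `clade`.
#' @export
expandRegionalCounts <- function(counts) {
  hgCols <- setdiff(names(counts), c("population", "region", "n"))
  ord <- hgCols[order(nchar(hgCols), decreasing = TRUE)]  # deepest first
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    remaining <- stats::setNames(as.integer(counts[i, hgCols]), hgCols)
    lab <- character(0)
    for (hg in ord) {
      k <- remaining[hg]
      if (k > 0L) {
        lab <- c(lab, rep(hg, k))
        # subtract from every ancestor label
        for (anc in hgCols[vapply(hgCols, function(a) isSubclade(hg, a), logical(1))])
          remaining[anc] <- remaining[anc] - k
        remaining[hg] <- 0L
      }
    }
    nOther <- counts$n[i] - length(lab)
    if (nOther < 0L) stop("counts exceed population n for ", counts$population[i])
    lab <- c(lab, rep("other", nOther))
    rows[[i]] <- data.frame(
      sample_id = sprintf("%s_%04d", gsub("[^A-Za-z]", "", counts$population[i]), seq_along(lab)),
      population = counts$population[i], region = counts$region[i],
      clade = lab, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Slatkin-linearised pairwise FST between two populations
#'
#' Distance-based FST (a Phi-statistic) from the AMOVA variance
#' decomposition of haplotype mismatch distances: the among-population
#' variance component over the total, linearised as `FST / (1 - FST)`.
#' Negative FST estimates are truncated to zero before linearisation;
#' `FST = 1` has no finite linearisation and yields `NA` with a warning.
#'
#' @param distA within-A mismatch matrix, or a [HaplotypeSet] for
#'   population A (with `distB`/`distAB` then computed internally when
#'   `hsB` is given).
#' @param hsB optional [HaplotypeSet] for population B when `distA` is a
#'   [HaplotypeSet].
#' @param dAB optional full mismatch matrix over both populations with the
#'   first `nA` rows from A (used with matrix input).
#' @param nA number of A samples when `distA` is a matrix.
#' @return Named numeric `c(fst = ..., linearised = ...)`.
#' @export
linearizedFst <- function(distA = NULL, hsB = NULL, dAB = NULL, nA = NULL) {
  if (methods::is(distA, "HaplotypeSet")) {
    if (is.null(hsB)) stop("two populations are required")
    both <- haplotypeSet(rbind(distA@info, hsB@info),
      c(distA@variants, hsB@variants), c(distA@coverage, hsB@coverage))
    dAB <- mismatchMatrix(both)
    nA <- length(distA)
  } else {
    if (is.null(dAB) || is.null(nA)) stop("matrix input needs dAB and nA")
  }
  n <- nrow(dAB)
  nB <- n - nA
  if (nA < 2L || nB < 2L) stop("at least two samples per population are required")
  idxA <- seq_len(nA); idxB <- (nA + 1L):n
  # AMOVA sums of squares from (squared) mismatch distances
  ssTotal <- sum(dAB[upper.tri(dAB)]) / n
  ssWithin <- sum(dAB[idxA, idxA][upper.tri(dAB[idxA, idxA])]) / nA +
    sum(dAB[idxB, idxB][upper.tri(dAB[idxB, idxB])]) / nB
  ssAmong <- ssTotal - ssWithin
  dfAmong <- 1L
  dfWithin <- n - 2L
  msWithin <- ssWithin / dfWithin
  nPrime <- (n - (nA^2 + nB^2) / n) / dfAmong
  sigmaAmong <- (ssAmong / dfAmong - msWithin) / nPrime
  sigmaTotal <- sigmaAmong + msWithin
  fst <- if (sigmaTotal <= 0) 0 else sigmaAmong / sigmaTotal
  fst <- max(0, fst)
  if (fst >= 1 - 1e-12) {
    warning("FST = 1: linearisation FST/(1-FST) is undefined")
    return(c(fst = 1, linearised = NA_real_))
  }
  c(fst = fst, linearised = fst / (1 - fst))
}

#' Pairwise linearised-FST matrix over grouped populations
#'
#' @param hs a [HaplotypeSet] (typically after [buildAnalysisHaplotypes()]).
#' @param groups named list: group label -> sample ids (see
#'   [applyGrouping()]).
#' @return Symmetric matrix with `metric` attribute `"linearized_fst"`;
#'   undefined cells (FST = 1) are `NA` and flagged with a warning.
#' @export
fstMatrix <- function(hs, groups) {
  labs <- names(groups)
  k <- length(labs)
  d <- mismatchMatrix(hs)
  out <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ids <- c(groups[[i]], groups[[j]])
    sub <- d[ids, ids, drop = FALSE]
    v <- suppressWarnings(linearizedFst(dAB = sub, nA = length(groups[[i]])))
    if (is.na(v["linearised"]))
      warning("FST = 1 between ", labs[i], " and ", labs[j], "; cell flagged NA")
    out[i, j] <- out[j, i] <- v[["linearised"]]
  }
  attr(out, "metric") <- "linearized_fst"
  out
}

#' Binary language-family distance matrix
#'
#' Distance 0 between (grouped) populations speaking languages of the same
#' family, 1 otherwise.
#'
#' @param pops population (or group) labels.
#' @param familyMap named character vector: population -> language family.
#' @return Symmetric 0/1 matrix with `metric` attribute `"language_binary"`.
#' @export
languageDistance <- function(pops, familyMap) {
  missing <- setdiff(pops, names(familyMap))
  if (length(missing)) stop("no language family mapped for: ", paste(missing, collapse = ", "))
  fam <- familyMap[pops]
  out <- outer(fam, fam, FUN = function(a, b) as.numeric(a != b))
  dimnames(out) <- list(pops, pops)
  attr(out, "metric") <- "language_binary"
  out
}

#' Great-circle geographic distance matrix
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param pops population (or group) labels.
#' @param coordinates data.frame with columns `population`, `lat`, `lon`
#'   (decimal degrees), or a named list of `c(lat, lon)`.
#' @return Symmetric matrix in km with `metric` attribute
#'   `"great_circle_km"`.
#' @export
geographicDistance <- function(pops, coordinates) {
  if (is.data.frame(coordinates)) {
    idx <- match(pops, coordinates$population)
    if (any(is.na(idx))) stop("missing coordinates for: ",
      paste(pops[is.na(idx)], collapse = ", "))
    ll <- cbind(coordinates$lon[idx], coordinates$lat[idx])
  } else {
    missing <- setdiff(pops, names(coordinates))
    if (length(missing)) stop("missing coordinates for: ", paste(missing, collapse = ", "))
    ll <- t(vapply(coordinates[pops], function(x) c(x[2L], x[1L]), numeric(2)))
  }
  k <- length(pops)
  out <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) out[i, j] <- out[j, i] <-
      geosphere::distHaversine(ll[i, ], ll[j, ], r = 6371000) / 1000
  }
  attr(out, "metric") <- "great_circle_km"
  out
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the upper off-diagonal entries, with a one-sided
#' permutation p-value under simultaneous row/column permutation of the
#' second matrix, using the customary +1 correction. The default
#' alternative `"greater"` counts permutations with `r >= r_obs` — the
#' convention of the standard population-genetics software, under which a
#' negative observed correlation yields a large p-value and null p-values
#' are uniform.
#'
#' @param matA,matB symmetric distance matrices with identical labels and
#'   ordering.
#' @param nPermutations number of permutations (>= 1).
#' @param seed optional integer seed for the permutation stream.
#' @param alternative `"greater"` (default) or `"less"`.
#' @return List with elements `r`, `p`, `n_permutations`.
#' @export
mantelTest <- function(matA, matB, nPermutations = 100000L, seed = NULL,
                       alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!all(dim(matA) == dim(matB)))
    stop("distance matrices must have identical dimensions")
  if (!is.null(dimnames(matA)[[1L]]) && !is.null(dimnames(matB)[[1L]]) &&
      !identical(dimnames(matA)[[1L]], dimnames(matB)[[1L]]))
    stop("distance matrices must share label ordering")
  if (nPermutations < 1L) stop("nPermutations must be >= 1")
  n <- nrow(matA)
  ut <- which(upper.tri(matA), arr.ind = TRUE)
  a <- matA[ut]
  b <- matB[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("a distance matrix with constant off-diagonal entries has no Mantel correlation")
  rObs <- stats::cor(a, b)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  perms <- replicate(nPermutations, sample.int(n))
  ii <- matrix(perms[ut[, 1L], ], nrow = nrow(ut))
  jj <- matrix(perms[ut[, 2L], ], nrow = nrow(ut))
  bp <- matrix(matB[cbind(as.vector(ii), as.vector(jj))], nrow = nrow(ut))
  aC <- a - mean(a)
  bpC <- sweep(bp, 2L, colMeans(bp))
  rPerm <- as.vector(crossprod(aC, bpC)) /
    (sqrt(sum(aC^2)) * sqrt(colSums(bpC^2)))
  p <- if (alternative == "greater")
    (1 + sum(rPerm >= rObs - 1e-12)) / (1 + nPermutations)
  else (1 + sum(rPerm <= rObs + 1e-12)) / (1 + nPermutations)
  list(r = rObs, p = p, n_permutations = as.integer(nPermutations))
}

#' Pool populations into analysis groups
#'
#' Small populations are pooled with a close neighbour of the same language
#' family; populations that cannot be pooled are excluded. The spec lists
#' group members and exclusions; unlisted populations form singleton
#' groups.
#'
#' @param hs a [HaplotypeSet].
#' @param groups named list: group label -> population names to pool.
#' @param exclude population names dropped from the analysis (recorded in
#'   the returned attribute `"excluded"`).
#' @return Named list: group label -> sample ids; with attribute
#'   `"excluded"`.
#' @export
applyGrouping <- function(hs, groups = list(), exclude = character(0)) {
  inGroups <- unlist(groups, use.names = FALSE)
  clash <- intersect(inGroups, exclude)
  if (length(clash))
    stop("populations listed both in a group and in the exclusions: ",
      paste(clash, collapse = ", "))
  pop <- populations(hs)
  out <- list()
  for (g in names(groups)) {
    ids <- names(pop)[pop %in% groups[[g]]]
    if (length(ids)) out[[g]] <- ids
  }
  rest <- setdiff(unique(pop), c(inGroups, exclude))
  for (p in rest) out[[p]] <- names(pop)[pop == p]
  dropped <- intersect(unique(pop), exclude)
  if (length(dropped))
    message("excluded populations: ", paste(dropped, collapse = ", "))
  attr(out, "excluded") <- dropped
  out
}
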