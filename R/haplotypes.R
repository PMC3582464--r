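.FULL_COVERAGE <- cbind(start = 1L, end = 16569L)

#' Construct a HaplotypeSet
#'
#' @param info data.frame with columns `sample_id`, `population`,
#'   `region_code`, and optionally `source`.
#' @param variants list of variant data.frames, one per sample, in `info`
#'   row order.
#' @param coverage optional list of two-column matrices of typed ranges;
#'   defaults to fully typed samples.
#' @return A [HaplotypeSet].
#' @export
haplotypeSet <- function(info, variants, coverage = NULL) {
  if (is.null(info$source)) info$source <- rep("unspecified", nrow(info))
  info <- info[, c("sample_id", "population", "region_code", "source")]
  info$sample_id <- as.character(info$sample_id)
  names(variants) <- info$sample_id
  if (is.null(coverage)) coverage <- rep(list(.FULL_COVERAGE), nrow(info))
  names(coverage) <- info$sample_id
  methods::new("HaplotypeSet", info = info, variants = variants, coverage = coverage)
}

#' @describeIn haplotypeSet number of samples
#' @param x,object a [HaplotypeSet].
#' @export
setMethod("length", "HaplotypeSet", function(x) nrow(x@info))

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet with", nrow(object@info), "samples from",
    length(unique(object@info$population)), "populations\n")
  nv <- vapply(object@variants, nrow, integer(1))
  if (length(nv)) cat("  variants per sample:", min(nv), "-", max(nv), "\n")
})

#' Sample ids of a HaplotypeSet
#' @param hs a [HaplotypeSet].
#' @export
sampleIds <- function(hs) hs@info$sample_id

#' Population labels of a HaplotypeSet
#' @param hs a [HaplotypeSet].
#' @export
populations <- function(hs) stats::setNames(hs@info$population, hs@info$sample_id)

#' Variant table of one sample
#' @param hs a [HaplotypeSet].
#' @param id sample id.
#' @export
variantsOf <- function(hs, id) {
  v <- hs@variants[[id]]
  if (is.null(v)) stop("unknown sample id: ", id)
  v
}

#' Subset a HaplotypeSet by sample id
#' @param x a [HaplotypeSet]; `i` sample ids or indices.
#' @param i,j,...,drop standard subset arguments (only `i` is used).
#' @export
setMethod("[", "HaplotypeSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@info$sample_id)
  methods::new("HaplotypeSet", info = x@info[i, , drop = FALSE],
    variants = x@variants[i], coverage = x@coverage[i])
})

#' Read a sample table
#'
#' Reads a TSV with columns `sample_id`, `population`, `region_code`, and
#' `variants` (semicolon-separated nomenclature tokens; optionally a
#' `source` column). Rows with malformed tokens are reported with their row
#' numbers.
#'
#' @param path file path.
#' @param ref optional [MtReference] used to fill in alleles while parsing.
#' @return A [HaplotypeSet].
#' @export
readSampleTable <- function(path, ref = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "population", "region_code", "variants")
  if (!all(need %in% names(tab)))
    stop("sample table is missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  vlist <- vector("list", nrow(tab))
  bad <- character(0)
  for (i in seq_len(nrow(tab))) {
    vlist[[i]] <- tryCatch(parseVariantString(tab$variants[i], ref = ref),
      error = function(e) { bad <<- c(bad, sprintf("row %d: %s", i, conditionMessage(e))); NULL })
  }
  if (length(bad)) stop("parse errors in sample table:\n", paste(bad, collapse = "\n"))
  haplotypeSet(tab, vlist)
}

#' Write a sample table
#'
#' @param hs a [HaplotypeSet].
#' @param path file path.
#' @export
writeSampleTable <- function(hs, path) {
  tab <- hs@info
  tab$variants <- vapply(hs@variants, function(v) {
    if (nrow(v) == 0L) "" else paste(formatVariantToken(v), collapse = "; ")
  }, character(1))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write haplotype sequences as FASTA
#'
#' Reconstructs each sample's full sequence by applying its variants to the
#' reference and writes a FASTA file.
#'
#' @param hs a [HaplotypeSet].
#' @param ref an [MtReference].
#' @param path file path.
#' @export
writeHaplotypeFasta <- function(hs, ref, path) {
  seqs <- vapply(sampleIds(hs), function(id) applyVariants(ref, variantsOf(hs, id)), character(1))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- sampleIds(hs)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Reduce haplotypes to the form used for population comparisons
#'
#' Keeps coding-region variants plus control-region variants inside the
#' HVS-I window (16024-16400); drops HVS-II (positions it was not possible
#' to assume typed across studies), variants in the homopolymeric-tract
#' mask, and heteroplasmic calls. Coverage is set to the full molecule
#' afterwards: positions that were not typed are treated as
#' reference-identical for distance computation.
#'
#' @param hs a [HaplotypeSet].
#' @param ref an [MtReference] (defines the control/coding partition).
#' @param hvs1 integer `c(start, end)` of the retained control window.
#' @param hvs2 integer `c(start, end)` of the excluded HVS-II window.
#' @param mask homopolymeric-tract mask matrix; `NULL` disables.
#' @return A filtered [HaplotypeSet] with full coverage.
#' @export
buildAnalysisHaplotypes <- function(hs, ref, hvs1 = c(16024L, 16400L),
                                    hvs2 = c(57L, 372L),
                                    mask = defaultCtractMask()) {
  vlist <- lapply(sampleIds(hs), function(id) {
    v <- variantsOf(hs, id)
    if (!nrow(v)) return(v)
    keep <- rep(TRUE, nrow(v))
    region <- regionOf(ref, v$position)
    inHvs1 <- v$position >= hvs1[1L] & v$position <= hvs1[2L]
    keep <- keep & (region == "coding" | inHvs1)
    keep <- keep & !(v$position >= hvs2[1L] & v$position <= hvs2[2L])
    if (!is.null(mask)) keep <- keep & !.maskedOut(v, mask)
    keep <- keep & is.na(v$het)
    out <- v[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  haplotypeSet(hs@info, vlist, coverage = NULL)
}

# site key used to compare variant sets: position / insertion index / state
.variantKeys <- function(v) {
  if (!nrow(v)) return(character(0))
  v <- v[v$back %% 2L == 0L & is.na(v$het), , drop = FALSE]
  if (!nrow(v)) return(character(0))
  paste0(v$position, ".", ifelse(is.na(v$ins_index), 0L, v$ins_index), ":",
    ifelse(is.na(v$derived), "t", v$derived))
}

#' Pairwise mutation mismatch distance between samples
#'
#' Number of variant states (position, insertion index, derived allele) by
#' which two haplotypes differ; variants with an odd back-mutation count or
#' a heteroplasmic call do not contribute.
#'
#' @param hs a [HaplotypeSet] (typically after [buildAnalysisHaplotypes()]).
#' @return Symmetric integer matrix with sample ids as dimnames.
#' @export
mismatchMatrix <- function(hs) {
  ids <- sampleIds(hs)
  keys <- lapply(ids, function(id) .variantKeys(variantsOf(hs, id)))
  n <- length(ids)
  d <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- length(setdiff(keys[[i]], keys[[j]])) +
        length(setdiff(keys[[j]], keys[[i]]))
    }
  }
  d
}
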