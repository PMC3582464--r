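#' Load the packaged mtDNA reference model
#'
#' Builds an [MtReference] from the annotation and reference sequence
#' shipped with the package, or from user-supplied files with the same
#' layout. The packaged gene annotation uses the standard rCRS coordinate
#' frame (16,569 bp, 1-based): 13 protein-coding genes, 22 tRNAs, 2 rRNAs,
#' and the control region split across the origin (16024-16569 and 1-576).
#' The packaged sequence is a synthetic stand-in on the same coordinate
#' frame (see the package vignette); all coordinate arithmetic, codon frames
#' and site classes are computed from it deterministically.
#'
#' @param annotation path to a gene-annotation TSV with columns
#'   `name`, `start`, `end`, `type` (`protein`/`trna`/`rrna`/`control`),
#'   `strand`. Defaults to the packaged table.
#' @param fasta path to a single-record FASTA with the 16,569-bp reference
#'   sequence. Defaults to the packaged synthetic sequence.
#' @param name identifier stored in the object.
#' @return An [MtReference].
#' @examples
#' ref <- loadMtReference()
#' regionOf(ref, 16126)
#' @export
loadMtReference <- function(annotation = NULL, fasta = NULL, name = "mtref") {
  if (is.null(annotation))
    annotation <- system.file("extdata", "mtdna_annotation.tsv", package = "mitophylo")
  if (is.null(fasta))
    fasta <- system.file("extdata", "mtdna_reference_synthetic.fasta", package = "mitophylo")
  genes <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  dna <- Biostrings::readDNAStringSet(fasta)
  seqChars <- strsplit(as.character(dna[[1L]]), "")[[1L]]
  ctrl <- genes[genes$type == "control", , drop = FALSE]
  cs <- cbind(start = as.integer(ctrl$start), end = as.integer(ctrl$end))
  methods::new("MtReference",
    name = name,
    sequence = seqChars,
    controlSegments = cs,
    genes = genes[genes$type != "control", , drop = FALSE],
    codonTable = Biostrings::getGeneticCode("2")
  )
}

setMethod("show", "MtReference", function(object) {
  cat("MtReference '", object@name, "': ", length(object@sequence), " bp, ",
    nrow(object@genes), " gene records, ",
    nrow(object@controlSegments), " control segments\n", sep = "")
})

#' Reference base at a position
#'
#' @param ref an [MtReference].
#' @param position 1-based position(s).
#' @return Character vector of bases.
#' @export
referenceBase <- function(ref, position) {
  .checkPositions(position)
  ref@sequence[position]
}

.checkPositions <- function(position) {
  if (any(is.na(position)) || any(position < 1L) || any(position > 16569L))
    stop("position out of reference bounds [1, 16569]")
  invisible(position)
}

#' Control vs coding partition of the molecule
#'
#' @param ref an [MtReference].
#' @param position 1-based position(s).
#' @return `"control"` or `"coding"` per position.
#' @examples
#' ref <- loadMtReference()
#' regionOf(ref, c(16024, 16200, 10000))
#' @export
regionOf <- function(ref, position) {
  .checkPositions(position)
  cs <- ref@controlSegments
  inCtrl <- vapply(position, function(p) any(p >= cs[, 1L] & p <= cs[, 2L]), logical(1))
  ifelse(inCtrl, "control", "coding")
}

# first gene record (annotation order) containing a position; NA row index if none
.geneAt <- function(ref, position) {
  g <- ref@genes
  hit <- which(g$start <= position & g$end >= position)
  if (length(hit)) hit[1L] else NA_integer_
}

# translate the codon containing `position` in protein gene row `gi`,
# with the base at `position` set to `base`; returns NA for positions in an
# incomplete terminal codon
.aminoAt <- function(ref, gi, position, base) {
  g <- ref@genes[gi, ]
  if (g$strand == "+") {
    offset <- position - g$start
    cstart <- g$start + (offset %/% 3L) * 3L
    cpos <- cstart + 0:2
    if (cpos[3L] > g$end) return(NA_character_)
    codon <- ref@sequence[cpos]
    codon[position - cstart + 1L] <- base
  } else {
    offset <- g$end - position
    cstart <- g$end - (offset %/% 3L) * 3L
    cpos <- cstart - (0:2)
    if (cpos[3L] < g$start) return(NA_character_)
    codon <- ref@sequence[cpos]
    codon[cstart - position + 1L] <- base
    codon <- chartr("ACGT", "TGCA", codon)
  }
  unname(ref@codonTable[paste(codon, collapse = "")])
}

#' Classify a site change into the four mutation classes
#'
#' Every (position, ref, derived) change maps to exactly one of `control`,
#' `rna_gene`, `synonymous`, `nonsynonymous`. Control-region changes are
#' `control`; changes in tRNA/rRNA genes (and the few intergenic spacers)
#' are `rna_gene`; substitutions inside protein genes are classified by
#' translating the affected codon under the vertebrate mitochondrial code
#' over the annotated frame (light-strand genes are translated from the
#' complementary strand). Indels in protein genes are `nonsynonymous`, as
#' are substitutions in the one or two incomplete terminal codon positions
#' of genes whose stop codon is completed by polyadenylation. For display,
#' `{control, rna_gene}` jointly correspond to the conventional "non-coding"
#' colouring of haplogroup trees; they are kept distinct here because the
#' synonymous clock must count strictly coding synonymous changes.
#'
#' @param ref an [MtReference].
#' @param position 1-based position.
#' @param refAllele reference base (defaults to the packaged base at
#'   `position`).
#' @param altAllele derived base, or `"-"` for a deletion, or a multi-base
#'   string for an insertion.
#' @return One of `"control"`, `"rna_gene"`, `"synonymous"`,
#'   `"nonsynonymous"`.
#' @examples
#' ref <- loadMtReference()
#' classifySite(ref, 16126, "T", "C")  # control region
#' classifySite(ref, 750, "A", "G")    # 12S rRNA
#' @export
classifySite <- function(ref, position, refAllele = NULL, altAllele = NULL) {
  .checkPositions(position)
  if (is.null(refAllele)) refAllele <- ref@sequence[position]
  if (is.null(altAllele)) stop("altAllele is required")
  if (regionOf(ref, position) == "control") return("control")
  gi <- .geneAt(ref, position)
  if (is.na(gi) || ref@genes$type[gi] != "protein") return("rna_gene")
  isIndel <- altAllele == "-" || nchar(altAllele) > 1L || refAllele == "-"
  if (isIndel) return("nonsynonymous")
  if (!altAllele %in% c("A", "C", "G", "T")) return("nonsynonymous")
  aaRef <- .aminoAt(ref, gi, position, refAllele)
  aaAlt <- .aminoAt(ref, gi, position, altAllele)
  if (is.na(aaRef) || is.na(aaAlt)) return("nonsynonymous")
  if (identical(aaRef, aaAlt)) "synonymous" else "nonsynonymous"
}

#' Classify many substitutions at once
#'
#' Vectorised version of [classifySite()] restricted to single-base
#' substitutions, used when building per-class site pools.
#'
#' @param ref an [MtReference].
#' @param positions integer vector.
#' @param altAlleles character vector of derived bases, recycled.
#' @return Character vector of site classes.
#' @export
classifySites <- function(ref, positions, altAlleles) {
  altAlleles <- rep_len(altAlleles, length(positions))
  vapply(seq_along(positions), function(i) {
    classifySite(ref, positions[i], NULL, altAlleles[i])
  }, character(1))
}

# package-local cache of per-class site pools, keyed by reference name
.poolCache <- new.env(parent = emptyenv())

#' Per-class site pools
#'
#' Enumerates, for each site class, the (position, derived allele) pairs on
#' the reference that would produce a change of that class. Used by the
#' simulator to draw mutation targets; cached per reference name.
#'
#' @param ref an [MtReference].
#' @return Named list with elements `control`, `rna_gene`, `synonymous`,
#'   `nonsynonymous`, each a data.frame with columns `position`, `alt`.
#' @export
sitePools <- function(ref) {
  key <- ref@name
  if (!is.null(.poolCache[[key]])) return(.poolCache[[key]])
  bases <- c("A", "C", "G", "T")
  cs <- ref@controlSegments
  ctrlPos <- unlist(lapply(seq_len(nrow(cs)), function(i) cs[i, 1L]:cs[i, 2L]))
  allPos <- 1:16569
  codingPos <- setdiff(allPos, ctrlPos)
  g <- ref@genes
  protPos <- sort(unique(unlist(lapply(which(g$type == "protein"), function(i) g$start[i]:g$end[i]))))
  protPos <- setdiff(protPos, ctrlPos)
  # positions assigned to a non-protein record first keep that assignment
  firstGene <- vapply(protPos, function(p) .geneAt(ref, p), integer(1))
  protPos <- protPos[g$type[firstGene] == "protein"]
  rnaPos <- setdiff(codingPos, protPos)
  mkPool <- function(pos) {
    refB <- ref@sequence[pos]
    data.frame(
      position = rep(pos, each = 3L),
      alt = unlist(lapply(refB, function(b) setdiff(bases, b))),
      stringsAsFactors = FALSE
    )
  }
  prot <- mkPool(protPos)
  cls <- .classifyProteinBulk(ref, prot$position, prot$alt,
    firstGene[match(prot$position, protPos)])
  pools <- list(
    control = mkPool(ctrlPos),
    rna_gene = mkPool(rnaPos),
    synonymous = prot[cls == "synonymous", , drop = FALSE],
    nonsynonymous = prot[cls == "nonsynonymous", , drop = FALSE]
  )
  .poolCache[[key]] <- pools
  pools
}

# vectorised synonymous/nonsynonymous classification for substitutions in
# protein genes; `gi` is the annotation row of each position's gene
.classifyProteinBulk <- function(ref, positions, alts, gi) {
  g <- ref@genes
  out <- rep("nonsynonymous", length(positions))
  plus <- g$strand[gi] == "+"
  sq <- ref@sequence
  ct <- ref@codonTable
  for (strandPlus in c(TRUE, FALSE)) {
    sel <- which(plus == strandPlus)
    if (!length(sel)) next
    pos <- positions[sel]
    start <- g$start[gi[sel]]; end <- g$end[gi[sel]]
    if (strandPlus) {
      off <- pos - start
      cstart <- start + (off %/% 3L) * 3L
      complete <- cstart + 2L <= end
      within <- pos - cstart + 1L
      c1 <- sq[cstart]; c2 <- sq[cstart + 1L]; c3 <- sq[cstart + 2L]
      refB <- sq[pos]; altB <- alts[sel]
    } else {
      off <- end - pos
      cstart <- end - (off %/% 3L) * 3L
      complete <- cstart - 2L >= start
      within <- cstart - pos + 1L
      comp <- function(x) chartr("ACGT", "TGCA", x)
      c1 <- comp(sq[cstart]); c2 <- comp(sq[cstart - 1L]); c3 <- comp(sq[cstart - 2L])
      refB <- comp(sq[pos]); altB <- comp(alts[sel])
    }
    m1 <- c1; m2 <- c2; m3 <- c3
    m1[within == 1L] <- altB[within == 1L]
    m2[within == 2L] <- altB[within == 2L]
    m3[within == 3L] <- altB[within == 3L]
    aaRef <- ct[paste0(c1, c2, c3)]
    aaAlt <- ct[paste0(m1, m2, m3)]
    syn <- complete & !is.na(aaRef) & !is.na(aaAlt) & aaRef == aaAlt
    out[sel[syn]] <- "synonymous"
  }
  out
}
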