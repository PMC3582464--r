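#' @importFrom stats setNames
NULL

.IUB_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
.PURINES <- c("A", "G")

# column layout shared by every variant table in the package
emptyVariantTable <- function() {
  data.frame(
    position = integer(0), ins_index = integer(0), ref = character(0),
    derived = character(0), kind = character(0), back = integer(0),
    het = character(0), stringsAsFactors = FALSE
  )
}

.substitutionKind <- function(ref, derived) {
  if (is.na(ref) || is.na(derived)) return(NA_character_)
  if ((ref %in% .PURINES) == (derived %in% .PURINES)) "transition" else "transversion"
}

#' Parse one variant token of the haplogroup-tree nomenclature
#'
#' Tokens follow the convention of published mtDNA haplogroup trees scored
#' against a reference sequence: a bare position (`"16126"`) is a
#' transition; a trailing capital base marks the resulting transversion
#' (`"16182C"`); an explicit leading reference base is accepted
#' (`"C14110T"`); insertions anchor at a position plus index
#' (`"309+2C"`, or `"573iC"` as shorthand for index 1); deletions end in
#' `d` (`"15944d"`); one or two trailing exclamation marks record a
#' reversal to the ancestral state or a double back mutation; an IUB
#' ambiguity letter records a heteroplasmic call and is kept but excluded
#' from all downstream counting.
#'
#' @param token character scalar.
#' @param ref optional [MtReference]; when supplied, missing alleles are
#'   filled in from the reference sequence (a bare transition token gets
#'   its reference base and its transition partner as derived base).
#' @return A one-row variant data.frame with columns `position`,
#'   `ins_index`, `ref`, `derived`, `kind`, `back`, `het`.
#' @examples
#' parseVariantToken("309+2C")
#' parseVariantToken("16189!")
#' @export
parseVariantToken <- function(token, ref = NULL) {
  tok <- trimws(token)
  m <- regmatches(tok, regexec(
    "^([ACGT])?([0-9]+)(?:\\+([0-9]+)([ACGT]+)|i([ACGT]+)|(d)|([A-Z]))?(!{0,2})$", tok))[[1L]]
  if (length(m) == 0L || m[1L] != tok)
    stop("malformed variant token: '", token, "'")
  pos <- as.integer(m[3L])
  if (is.na(pos) || pos < 1L || pos > 16569L)
    stop("malformed variant token: '", token, "' (position out of range)")
  lead <- if (nzchar(m[2L])) m[2L] else NA_character_
  insIdx <- if (nzchar(m[4L])) as.integer(m[4L]) else NA_integer_
  insBases <- if (nzchar(m[5L])) m[5L] else if (nzchar(m[6L])) m[6L] else NA_character_
  isDel <- nzchar(m[7L])
  suffix <- if (nzchar(m[8L])) m[8L] else NA_character_
  back <- nchar(m[9L])
  refBase <- lead
  derived <- NA_character_
  het <- NA_character_
  if (!is.na(insBases)) {
    kind <- "insertion"
    if (is.na(insIdx)) insIdx <- 1L
    derived <- insBases
    refBase <- NA_character_
  } else if (isDel) {
    kind <- "deletion"
    derived <- "-"
    if (is.na(refBase) && !is.null(ref)) refBase <- referenceBase(ref, pos)
  } else if (!is.na(suffix) && suffix %in% .IUB_AMBIG) {
    kind <- "transition"  # placeholder; heteroplasmic calls are never counted
    het <- suffix
    derived <- suffix
    if (is.na(refBase) && !is.null(ref)) refBase <- referenceBase(ref, pos)
  } else if (!is.na(suffix)) {
    if (!suffix %in% c("A", "C", "G", "T"))
      stop("malformed variant token: '", token, "' (unknown suffix)")
    derived <- suffix
    if (is.na(refBase) && !is.null(ref)) refBase <- referenceBase(ref, pos)
    kind <- if (!is.na(refBase)) .substitutionKind(refBase, derived) else "transversion"
    if (!is.na(refBase) && refBase == derived)
      stop("malformed variant token: '", token, "' (derived equals reference)")
  } else {
    # bare position: transition relative to the reference base
    kind <- "transition"
    if (is.na(refBase) && !is.null(ref)) refBase <- referenceBase(ref, pos)
    if (!is.na(refBase)) derived <- chartr("ACGT", "GTAC", refBase)  # transition partner
  }
  data.frame(
    position = pos, ins_index = insIdx, ref = refBase, derived = derived,
    kind = kind, back = as.integer(back), het = het, stringsAsFactors = FALSE
  )
}

#' Format a variant row back to its canonical token
#'
#' Canonical forms: transitions print as the bare position, transversions
#' append the derived base, heteroplasmies append the IUB letter,
#' insertions print `position+indexBASES`, deletions `positiond`; back
#' mutations append `!` or `!!`.
#'
#' @param v a one-row variant data.frame (or a multi-row table, formatted
#'   row-wise).
#' @return Character vector of canonical tokens.
#' @export
formatVariantToken <- function(v) {
  vapply(seq_len(nrow(v)), function(i) {
    r <- v[i, ]
    core <- switch(r$kind,
      insertion = paste0(r$position, "+", r$ins_index, r$derived),
      deletion = paste0(r$position, "d"),
      {
        if (!is.na(r$het)) paste0(r$position, r$het)
        else if (identical(r$kind, "transition")) as.character(r$position)
        else paste0(r$position, r$derived)
      })
    paste0(core, strrep("!", r$back))
  }, character(1))
}

#' Parse a semicolon-separated variant string
#'
#' @param x character scalar like `"16126; 16189!; 309+2C"` (separators
#'   `;` or whitespace).
#' @param ref optional [MtReference] passed to [parseVariantToken()].
#' @return A variant data.frame (zero rows for an empty string).
#' @export
parseVariantString <- function(x, ref = NULL) {
  toks <- unlist(strsplit(x, "[;[:space:]]+"))
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(emptyVariantTable())
  out <- do.call(rbind, lapply(toks, parseVariantToken, ref = ref))
  key <- paste(out$position, ifelse(is.na(out$ins_index), 0L, out$ins_index))
  if (anyDuplicated(key))
    stop("duplicate variant at position ", out$position[duplicated(key)][1L])
  out[order(out$position, out$ins_index, na.last = FALSE), , drop = FALSE]
}

#' Apply a variant set to the reference sequence
#'
#' Reconstructs the haplotype's sequence by substituting, deleting and
#' inserting relative to the reference. Variants with an odd back-mutation
#' count revert to the ancestral state and leave the sequence unchanged;
#' heteroplasmic calls are skipped.
#'
#' @param ref an [MtReference].
#' @param variants a variant data.frame.
#' @return Character scalar, the haplotype sequence.
#' @export
applyVariants <- function(ref, variants) {
  seqChars <- as.list(ref@sequence)
  if (nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (!is.na(v$het)) next
      if (v$back %% 2L == 1L) next  # reverted to ancestral state
      if (v$kind == "insertion") {
        seqChars[[v$position]] <- c(seqChars[[v$position]], strsplit(v$derived, "")[[1L]])
      } else if (v$kind == "deletion") {
        seqChars[[v$position]] <- character(0)
      } else {
        der <- if (!is.na(v$derived)) v$derived else chartr("ACGT", "GTAC", ref@sequence[v$position])
        seqChars[[v$position]] <- c(der, seqChars[[v$position]][-1L])
      }
    }
  }
  paste(unlist(seqChars), collapse = "")
}

#' Default homopolymeric-tract mask
#'
#' Length variation in the control-region C tracts (around 303-315 and
#' 16180-16195) and the 514-524 AC repeat is conventionally ignored when
#' scoring haplotypes; this returns those ranges as a two-column matrix.
#'
#' @return Integer matrix with columns `start`, `end`.
#' @export
defaultCtractMask <- function() {
  cbind(start = c(303L, 514L, 16180L), end = c(315L, 524L, 16195L))
}

.inMask <- function(position, mask) {
  vapply(position, function(p) any(p >= mask[, 1L] & p <= mask[, 2L]), logical(1))
}

# the homopolymer convention ignores tract-length artifacts (indels) and
# the run-extending transversions (e.g. 16182C), but keeps ordinary
# transitions such as 16189 that merely sit inside the window
.maskedOut <- function(v, mask) {
  if (is.null(mask) || !nrow(v)) return(rep(FALSE, nrow(v)))
  .inMask(v$position, mask) & v$kind != "transition"
}

#' Diff a sequence against the reference
#'
#' Aligns a full mtDNA sequence to the reference (positionally when the
#' lengths match, otherwise through a global pairwise alignment to place
#' indels) and returns the variant set that reconstructs it. Positions
#' inside the homopolymeric-tract mask are excluded.
#'
#' @param ref an [MtReference].
#' @param sequence character scalar (or a `Biostrings::DNAString`).
#' @param mask two-column matrix of masked ranges; `NULL` disables masking.
#' @return A variant data.frame.
#' @export
diffToReference <- function(ref, sequence, mask = defaultCtractMask()) {
  seqStr <- toupper(as.character(sequence))
  if (grepl("[^ACGTN-]", seqStr))
    stop("sequence contains non-nucleotide symbols")
  if (abs(nchar(seqStr) - 16569L) > 600L)
    stop("sequence length is wildly off the 16,569-bp reference")
  refStr <- paste(ref@sequence, collapse = "")
  if (nchar(seqStr) == 16569L && !grepl("-", seqStr)) {
    alnRef <- refStr
    alnSeq <- seqStr
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(gsub("-", "", seqStr)), Biostrings::DNAString(refStr),
      type = "global", gapOpening = 10, gapExtension = 4)
    alnSeq <- as.character(Biostrings::alignedPattern(pa))
    alnRef <- as.character(Biostrings::alignedSubject(pa))
  }
  rc <- strsplit(alnRef, "")[[1L]]
  sc <- strsplit(alnSeq, "")[[1L]]
  out <- emptyVariantTable()
  pos <- 0L
  i <- 1L
  n <- length(rc)
  while (i <= n) {
    if (rc[i] != "-") {
      pos <- pos + 1L
      if (sc[i] == "-") {
        out <- rbind(out, data.frame(position = pos, ins_index = NA_integer_,
          ref = rc[i], derived = "-", kind = "deletion", back = 0L,
          het = NA_character_, stringsAsFactors = FALSE))
      } else if (sc[i] != rc[i] && sc[i] != "N") {
        out <- rbind(out, data.frame(position = pos, ins_index = NA_integer_,
          ref = rc[i], derived = sc[i],
          kind = .substitutionKind(rc[i], sc[i]), back = 0L,
          het = NA_character_, stringsAsFactors = FALSE))
      }
      i <- i + 1L
    } else {
      # run of inserted bases anchored at the previous reference position
      j <- i
      while (j <= n && rc[j] == "-") j <- j + 1L
      ins <- paste(sc[i:(j - 1L)], collapse = "")
      out <- rbind(out, data.frame(position = max(pos, 1L), ins_index = 1L,
        ref = NA_character_, derived = ins, kind = "insertion", back = 0L,
        het = NA_character_, stringsAsFactors = FALSE))
      i <- j
    }
  }
  if (!is.null(mask) && nrow(out))
    out <- out[!.maskedOut(out, mask), , drop = FALSE]
  rownames(out) <- NULL
  out
}
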