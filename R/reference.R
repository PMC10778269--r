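#' Generate a random toy reference locus
#'
#' Creates a synthetic target region standing in for a ~2 kb amplicon panel
#' locus (e.g. the exon cluster of an oncogene targeted by a single-primer-
#' extension capture). All downstream coordinates are 0-based half-open
#' offsets into this sequence.
#'
#' @param seed Integer seed; the sequence is deterministic given the seed.
#' @param length Locus length in bp. Must be at least 1000 so a default-sized
#'   deletion plus full-length read flanks fit inside.
#' @param name Sequence name used in SAM/VCF headers.
#' @return An object of class `reference_locus` with fields `name`,
#'   `sequence` (uppercase ACGT string) and `length`.
#' @examples
#' loc <- make_reference(seed = 1, length = 2000)
#' loc$length
#' @export
make_reference <- function(seed, length = 2000L, name = "locus") {
  if (!is.numeric(length) || length < 1000)
    stop("locus length must be at least 1000 bp", call. = FALSE)
  length <- as.integer(length)
  set.seed(as.integer(seed))
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  reference_locus(name, seq)
}

#' Construct a reference locus from an explicit sequence
#'
#' @param name Sequence name.
#' @param sequence Uppercase DNA string (A/C/G/T only).
#' @return A `reference_locus` object.
#' @export
reference_locus <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("locus sequence must contain only A, C, G, T", call. = FALSE)
  structure(
    list(name = as.character(name), sequence = sequence,
         length = nchar(sequence)),
    class = "reference_locus"
  )
}

#' @export
print.reference_locus <- function(x, ...) {
  cat(sprintf("<reference_locus> %s: %d bp\n", x$name, x$length))
  invisible(x)
}

#' Describe a deletion allele on the reference locus
#'
#' @param start 0-based offset of the first deleted base.
#' @param end 0-based exclusive offset (one past the last deleted base).
#' @param microhomology_len Number of bases immediately left of `start` that
#'   are (to be made) identical to the bases immediately left of `end`,
#'   rendering the junction placement ambiguous. See
#'   [install_microhomology()].
#' @return A `deletion_spec` object with fields `start`, `end`, `length`,
#'   `microhomology_len`.
#' @export
deletion_spec <- function(start, end, microhomology_len = 0L) {
  start <- as.integer(start); end <- as.integer(end)
  microhomology_len <- as.integer(microhomology_len)
  if (is.na(start) || is.na(end) || start <= 0L || end <= start)
    stop("require 0 < start < end", call. = FALSE)
  if (end - start < 10L)
    stop("deletions shorter than 10 bp are not modelled", call. = FALSE)
  if (microhomology_len < 0L)
    stop("microhomology_len must be non-negative", call. = FALSE)
  structure(
    list(start = start, end = end, length = end - start,
         microhomology_len = microhomology_len),
    class = "deletion_spec"
  )
}

#' @export
print.deletion_spec <- function(x, ...) {
  cat(sprintf("<deletion_spec> [%d,%d) %d bp, microhomology %d bp\n",
              x$start, x$end, x$length, x$microhomology_len))
  invisible(x)
}

validate_deletion_spec <- function(spec, locus) {
  stopifnot(inherits(spec, "deletion_spec"), inherits(locus, "reference_locus"))
  if (spec$end >= locus$length)
    stop("deletion spec exceeds locus bounds", call. = FALSE)
  if (spec$microhomology_len >= min(spec$start, locus$length - spec$end))
    stop("microhomology_len too large for locus flanks", call. = FALSE)
  invisible(TRUE)
}

# substring in 0-based half-open coordinates
subseq0 <- function(seq, start0, end0) substr(seq, start0 + 1L, end0)

base_at0 <- function(seq, pos0) substr(seq, pos0 + 1L, pos0 + 1L)

`base_at0<-` <- function(seq, pos0, value) {
  substr(seq, pos0 + 1L, pos0 + 1L) <- value
  seq
}

#' Delete a region from the locus sequence
#'
#' Returns the mutant haplotype obtained by removing the half-open interval
#' `[start, end)` of the deletion spec from the locus sequence.
#'
#' @param locus A [reference_locus()].
#' @param spec A [deletion_spec()].
#' @return Character string of length `locus$length - spec$length`.
#' @examples
#' loc <- make_reference(1, 2000)
#' nchar(apply_deletion(loc, deletion_spec(500, 1048)))  # 1452
#' @export
apply_deletion <- function(locus, spec) {
  validate_deletion_spec(spec, locus)
  paste0(subseq0(locus$sequence, 0L, spec$start),
         subseq0(locus$sequence, spec$end, locus$length))
}

#' Install an exact-length microhomology at a deletion junction
#'
#' Edits the locus so that the `microhomology_len` bases immediately left of
#' `spec$start` equal those immediately left of `spec$end`, and so that the
#' homology does not extend further in either direction. Deleting
#' `[start, end)` then admits exactly `microhomology_len + 1` equivalent
#' placements, which is what makes junction canonicalization non-trivial.
#'
#' @inheritParams apply_deletion
#' @return A modified `reference_locus`.
#' @export
install_microhomology <- function(locus, spec) {
  validate_deletion_spec(spec, locus)
  s <- locus$sequence
  mh <- spec$microhomology_len
  if (mh > 0L) {
    block <- subseq0(s, spec$start - mh, spec$start)
    substr(s, spec$end - mh + 1L, spec$end) <- block
  }
  other <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  # break right extension: first deleted base must differ from first kept base
  if (base_at0(s, spec$start) == base_at0(s, spec$end))
    base_at0(s, spec$start) <- other(base_at0(s, spec$start))
  # break left extension beyond mh (edited base lies inside the deleted region)
  if (base_at0(s, spec$start - mh - 1L) == base_at0(s, spec$end - mh - 1L))
    base_at0(s, spec$end - mh - 1L) <- other(base_at0(s, spec$end - mh - 1L))
  reference_locus(locus$name, s)
}

#' Microhomology extent of a candidate junction
#'
#' For a deletion of `[b1, b2)`, computes how far the junction can slide left
#' and right while producing the same mutant sequence: the deletion is
#' equivalent to `[b1 + k, b2 + k)` for every `k` in `[-left, right]`.
#'
#' @param locus A [reference_locus()].
#' @param b1,b2 0-based half-open breakpoints of the deleted region.
#' @return List with integer fields `left` and `right`.
#' @export
junction_shift_range <- function(locus, b1, b2) {
  s <- locus$sequence
  if (b1 < 0L || b2 > locus$length || b1 >= b2)
    stop("candidate breakpoints outside locus bounds", call. = FALSE)
  right <- 0L
  while (b2 + right < locus$length &&
         base_at0(s, b1 + right) == base_at0(s, b2 + right))
    right <- right + 1L
  left <- 0L
  while (b1 - left > 0L &&
         base_at0(s, b1 - left - 1L) == base_at0(s, b2 - left - 1L))
    left <- left + 1L
  list(left = left, right = right)
}
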