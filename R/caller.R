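#' Enumerate candidate deletions from split-read segments
#'
#' Every reference gap between consecutive aligned segments of one read
#' (including gaps represented as in-read deletions) of an unflagged pair
#' becomes one candidate deletion; support is tallied per unique molecule,
#' so a pair whose read 1 and read 2 both span the same junction counts
#' once.
#'
#' @param rps A `read_pair_set` with duplicates marked.
#' @param min_del_len Candidates shorter than this are discarded (alignment
#'   noise rather than a panel-relevant deletion).
#' @return Data frame of raw candidates: `breakpoint1`, `breakpoint2`
#'   (0-based half-open), `length`, `support` (unique molecules),
#'   `support_reads` (read-level tally).
#' @export
enumerate_candidates <- function(rps, min_del_len = 10L) {
  gaps <- junction_gaps(rps, min_del_len)
  tally_gaps(gaps)
}

# one row per (pair, read, gap): the reference interval between consecutive
# aligned segments of one read of an unflagged pair
junction_gaps <- function(rps, min_del_len = 10L) {
  empty <- data.frame(pair_id = character(0), read = integer(0),
                      breakpoint1 = integer(0), breakpoint2 = integer(0))
  keep <- rps$pairs$pair_id[!rps$pairs$duplicate_flag]
  segs <- rps$segments[rps$segments$pair_id %in% keep, , drop = FALSE]
  if (nrow(segs) == 0L) return(empty)
  segs <- segs[order(segs$pair_id, segs$read, segs$ref_start), , drop = FALSE]
  grp <- paste(segs$pair_id, segs$read, sep = "\r")
  n <- nrow(segs)
  same <- grp[-1L] == grp[-n]
  if (!any(same)) return(empty)
  i <- which(same)                     # consecutive ref-sorted segment pairs
  gaps <- data.frame(pair_id = segs$pair_id[i], read = segs$read[i],
                     breakpoint1 = segs$ref_end[i],
                     breakpoint2 = segs$ref_start[i + 1L],
                     stringsAsFactors = FALSE)
  gaps[gaps$breakpoint2 - gaps$breakpoint1 >= min_del_len, , drop = FALSE]
}

tally_gaps <- function(gaps) {
  empty <- data.frame(breakpoint1 = integer(0), breakpoint2 = integer(0),
                      length = integer(0), support = integer(0),
                      support_reads = integer(0))
  if (nrow(gaps) == 0L) return(empty)
  key <- paste(gaps$breakpoint1, gaps$breakpoint2)
  reads <- table(key)
  # unique-molecule support: one count per pair per candidate
  mol <- table(key[!duplicated(paste(gaps$pair_id, key, sep = "\r"))])
  uk <- sort(unique(key))
  b <- do.call(rbind, strsplit(uk, " ", fixed = TRUE))
  out <- data.frame(breakpoint1 = as.integer(b[, 1L]),
                    breakpoint2 = as.integer(b[, 2L]),
                    support = as.integer(mol[uk]),
                    support_reads = as.integer(reads[uk]))
  out$length <- out$breakpoint2 - out$breakpoint1
  out <- out[order(out$breakpoint1, out$breakpoint2), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("breakpoint1", "breakpoint2", "length", "support",
          "support_reads")]
}

#' Canonicalize a microhomology-ambiguous junction
#'
#' When the bases adjacent to a candidate junction permit several
#' equivalent deletion placements, the placement that maximally extends the
#' first (read 5', primer-side) segment of a plus-strand junction read is
#' chosen, i.e. both breakpoints are shifted to their right-most equivalent
#' position. Applying one global convention maps every equivalent raw
#' candidate to the same canonical call.
#'
#' @param candidate List or one-row data frame with `breakpoint1` and
#'   `breakpoint2` (0-based half-open).
#' @param locus A [reference_locus()] carrying the sequence.
#' @return The candidate with canonical `breakpoint1`, `breakpoint2` and a
#'   `shift` field recording the applied right-shift.
#' @export
canonicalize_junction <- function(candidate, locus) {
  b1 <- candidate$breakpoint1; b2 <- candidate$breakpoint2
  if (b1 < 0L || b2 > locus$length)
    stop("candidate exceeds locus bounds", call. = FALSE)
  r <- junction_shift_range(locus, b1, b2)$right
  out <- candidate
  out$breakpoint1 <- b1 + r
  out$breakpoint2 <- b2 + r
  out$shift <- r
  out
}

#' Canonicalize and merge a raw candidate table
#'
#' Applies [canonicalize_junction()] to every raw candidate and sums the
#' support of candidates that collapse onto the same canonical junction.
#' Support tallies must already be per-molecule counts at distinct raw
#' placements (one placement per molecule), as produced when each molecule
#' is counted under a single alignment; within [call_deletion()] the merge
#' is instead performed at the per-read gap level so a molecule observed at
#' two equivalent placements still counts once.
#'
#' @param cand Raw candidate data frame as from [enumerate_candidates()].
#' @param locus A [reference_locus()] with sequence.
#' @return Canonical candidate table with merged support.
#' @export
canonicalize_candidates <- function(cand, locus) {
  if (nrow(cand) == 0L) return(cand)
  shifted <- canonical_breakpoints(cand$breakpoint1, cand$breakpoint2, locus)
  cand$breakpoint1 <- shifted$breakpoint1
  cand$breakpoint2 <- shifted$breakpoint2
  agg <- stats::aggregate(
    cand[, c("support", "support_reads"), drop = FALSE],
    by = cand[, c("breakpoint1", "breakpoint2"), drop = FALSE], sum)
  agg$length <- agg$breakpoint2 - agg$breakpoint1
  agg <- agg[order(agg$breakpoint1, agg$breakpoint2),
             c("breakpoint1", "breakpoint2", "length", "support",
               "support_reads")]
  rownames(agg) <- NULL
  agg
}

# vectorized canonicalization over (possibly repeated) breakpoint pairs
canonical_breakpoints <- function(b1, b2, locus) {
  key <- paste(b1, b2)
  uk <- !duplicated(key)
  shift <- vapply(which(uk), function(i)
    junction_shift_range(locus, b1[i], b2[i])$right, integer(1))
  names(shift) <- key[uk]
  s <- shift[key]
  list(breakpoint1 = b1 + unname(s), breakpoint2 = b2 + unname(s))
}

#' Retain the best-supported deletion
#'
#' Returns the canonical candidate with the largest unique-molecule
#' support, provided it meets the detection rule of at least one
#' supporting molecule. Ties are broken deterministically: larger support,
#' then smaller `breakpoint1`, then smaller length, so the result is
#' independent of input order.
#'
#' @param candidates Canonicalized candidate data frame.
#' @return A `deletion_call` object, or `NULL` for no-call.
#' @export
select_top <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  candidates <- candidates[candidates$support >= 1L, , drop = FALSE]
  if (nrow(candidates) == 0L) return(NULL)
  ord <- order(-candidates$support, candidates$breakpoint1,
               candidates$length)
  top <- candidates[ord[1L], ]
  structure(
    list(breakpoint1 = top$breakpoint1, breakpoint2 = top$breakpoint2,
         length = top$length, supporting_molecules = top$support,
         supporting_reads = top$support_reads),
    class = "deletion_call"
  )
}

#' @export
print.deletion_call <- function(x, ...) {
  cat(sprintf("<deletion_call> [%d,%d) %d bp | %d supporting molecule(s), %d read(s)\n",
              x$breakpoint1, x$breakpoint2, x$length,
              x$supporting_molecules, x$supporting_reads))
  invisible(x)
}

#' Call the top deletion in a sample
#'
#' Runs candidate enumeration, junction canonicalization (with
#' microhomology-equivalent support merged before selection) and
#' top-candidate retention on a deduplicated read-pair set.
#'
#' @inheritParams enumerate_candidates
#' @param locus A [reference_locus()] with sequence (defaults to the set's
#'   own locus).
#' @return A `deletion_call` or `NULL`; the canonical candidate table is
#'   attached as attribute `"candidates"`.
#' @export
call_deletion <- function(rps, locus = rps$locus, min_del_len = 10L) {
  gaps <- junction_gaps(rps, min_del_len = min_del_len)
  if (nrow(gaps) > 0L) {
    cb <- canonical_breakpoints(gaps$breakpoint1, gaps$breakpoint2, locus)
    gaps$breakpoint1 <- cb$breakpoint1
    gaps$breakpoint2 <- cb$breakpoint2
  }
  cand <- tally_gaps(gaps)
  call <- select_top(cand)
  if (!is.null(call)) attr(call, "candidates") <- cand
  call
}

#' Write a deletion call as a single-record VCF
#'
#' Emits a symbolic `<DEL>` record (1-based POS at the padding base before
#' the deleted region, `END` at its last deleted base, negative `SVLEN`)
#' with molecule-level support and, optionally, the combined VAF in INFO.
#'
#' @param call A `deletion_call`.
#' @param locus A [reference_locus()] with sequence.
#' @param path Output VCF path.
#' @param vaf Optional combined VAF (fraction) to record.
#' @param sample Sample name for the header line.
#' @return Invisibly, the path.
#' @export
write_vcf <- function(call, locus, path, vaf = NULL, sample = "sample") {
  stopifnot(inherits(call, "deletion_call"))
  pos1 <- call$breakpoint1                       # 1-based padding base
  ref_base <- base_at0(locus$sequence, call$breakpoint1 - 1L)
  info <- sprintf("SVTYPE=DEL;END=%d;SVLEN=%d;SUPPORT=%d",
                  call$breakpoint2, -call$length, call$supporting_molecules)
  if (!is.null(vaf) && is.finite(vaf))
    info <- paste0(info, sprintf(";VAF=%.6g", vaf))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", locus$name, locus$length),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"1-based end of the deleted region\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Deletion length (negative)\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting unique molecules\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Combined breakpoint VAF\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t<DEL>\t.\tPASS\t%s",
            locus$name, pos1, ref_base, info)
  ), path)
  invisible(path)
}
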