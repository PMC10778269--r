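#' Per-breakpoint allele-frequency evidence
#'
#' Builds the evidence record for one breakpoint from deletion-supporting
#' and non-supporting unique-molecule counts: `t = s + n` and
#' `VAF = s / t`, undefined (NA, flagged) when `t = 0`.
#'
#' @param s Deletion-supporting unique-pair count.
#' @param n Non-supporting unique-pair count.
#' @param breakpoint_index 1 or 2.
#' @return A `breakpoint_evidence` object with fields `breakpoint_index`,
#'   `s`, `n`, `t`, `vaf`, `defined`.
#' @examples
#' breakpoint_vaf(3, 7)$vaf  # 0.3
#' @export
breakpoint_vaf <- function(s, n, breakpoint_index = 1L) {
  if (s < 0 || n < 0) stop("counts must be non-negative", call. = FALSE)
  s <- as.integer(s); n <- as.integer(n)
  t <- s + n
  structure(
    list(breakpoint_index = as.integer(breakpoint_index), s = s, n = n,
         t = t, vaf = if (t > 0L) s / t else NA_real_, defined = t > 0L),
    class = "breakpoint_evidence"
  )
}

#' Combine two breakpoint estimates into one VAF
#'
#' Depth-weighted average of the per-breakpoint estimates:
#' `VAF = w1 VAF1 + w2 VAF2` with `w_i = t_i / (t1 + t2)`. A breakpoint
#' with no informative molecules gets weight zero; when both are empty the
#' estimate is undefined (no division is attempted).
#'
#' @param e1,e2 [breakpoint_vaf()] evidence for breakpoints 1 and 2.
#' @return A `vaf_estimate` object with fields `evidence1`, `evidence2`,
#'   `w1`, `w2`, `vaf`, `defined`.
#' @examples
#' combined_vaf(breakpoint_vaf(3, 7), breakpoint_vaf(1, 9))$vaf  # 0.2
#' @export
combined_vaf <- function(e1, e2) {
  stopifnot(inherits(e1, "breakpoint_evidence"),
            inherits(e2, "breakpoint_evidence"))
  tt <- e1$t + e2$t
  if (tt == 0L) {
    est <- list(evidence1 = e1, evidence2 = e2, w1 = NA_real_,
                w2 = NA_real_, vaf = NA_real_, defined = FALSE)
    return(structure(est, class = "vaf_estimate"))
  }
  w1 <- e1$t / tt; w2 <- e2$t / tt
  v1 <- if (e1$t > 0L) e1$vaf else 0
  v2 <- if (e2$t > 0L) e2$vaf else 0
  structure(
    list(evidence1 = e1, evidence2 = e2, w1 = w1, w2 = w2,
         vaf = w1 * v1 + w2 * v2, defined = TRUE),
    class = "vaf_estimate"
  )
}

#' @export
print.vaf_estimate <- function(x, ...) {
  fmt <- function(e) sprintf("s=%d n=%d t=%d VAF=%s", e$s, e$n, e$t,
                             ifelse(e$defined, sprintf("%.4f", e$vaf), "NA"))
  cat(sprintf("<vaf_estimate> bp1: %s | bp2: %s | w=(%.3f, %.3f) | VAF=%s\n",
              fmt(x$evidence1), fmt(x$evidence2),
              ifelse(is.na(x$w1), NA, x$w1), ifelse(is.na(x$w2), NA, x$w2),
              ifelse(x$defined, sprintf("%.4f", x$vaf), "NA")))
  invisible(x)
}

# total overlap (bp) of a set of intervals with [lo, hi)
interval_overlap <- function(start, end, lo, hi) {
  pmax(0L, pmin(end, hi) - pmax(start, lo))
}

#' Classify breakpoint-informative read pairs
#'
#' Applies the informative-read rules for breakpoint VAF estimation to
#' every unflagged pair, given a canonical deletion call. A pair is
#' assigned to the breakpoint whose non-deleted flank read 1 (the
#' gene-specific primer read) overlaps by at least `min_overlap` bases;
#' when read 1 itself spans the junction (both flanks overlap) the flank
#' containing read 1's 5' end is used. The pair is `supporting` when read
#' 2's alignment contains the canonical junction and overlaps the
#' non-deleted flank of the other breakpoint by at least `min_overlap`;
#' `non_supporting` when read 2 aligns contiguously through at least
#' `min_overlap` reference bases inside the deleted region (a contiguous
#' alignment crossing the whole deleted region into the distal flank is
#' non-supporting: allele identity is contiguity through the deletion);
#' `uninformative` otherwise.
#'
#' @param rps A deduplicated `read_pair_set`.
#' @param call A canonical `deletion_call` (or list with `breakpoint1`,
#'   `breakpoint2`).
#' @param locus A [reference_locus()] with sequence (for junction
#'   canonicalization of read-2 gaps).
#' @param min_overlap Minimum informative overlap in bp (default 19, the
#'   aligner seed length).
#' @param include_duplicates Classify flagged duplicates too (raw-read
#'   diagnostics).
#' @return Data frame `pair_id`, `breakpoint` (1, 2 or NA), `class`
#'   (factor: supporting / non_supporting / uninformative). The count of
#'   pairs whose read 1 spans the junction but which read 2 left
#'   unclassified as supporting is attached as attribute
#'   `"read1_junction_not_counted"`.
#' @export
classify_pairs <- function(rps, call, locus = rps$locus, min_overlap = 19L,
                           include_duplicates = FALSE) {
  pairs <- rps$pairs
  if (!include_duplicates)
    pairs <- pairs[!pairs$duplicate_flag, , drop = FALSE]
  b1 <- call$breakpoint1; b2 <- call$breakpoint2
  L <- locus$length
  out <- data.frame(pair_id = pairs$pair_id,
                    breakpoint = NA_integer_,
                    class = factor(rep("uninformative", nrow(pairs)),
                                   levels = c("supporting", "non_supporting",
                                              "uninformative")),
                    stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) {
    attr(out, "read1_junction_not_counted") <- 0L
    return(out)
  }
  segs <- rps$segments[rps$segments$pair_id %in% pairs$pair_id, , drop = FALSE]
  pf <- factor(segs$pair_id, levels = pairs$pair_id)

  ov_f1 <- interval_overlap(segs$ref_start, segs$ref_end, 0L, b1)
  ov_f2 <- interval_overlap(segs$ref_start, segs$ref_end, b2, L)
  ov_del <- interval_overlap(segs$ref_start, segs$ref_end, b1, b2)
  is_r1 <- segs$read == 1L
  sum_by_pair <- function(x) {
    m <- rowsum(x, pf)
    v <- rep(0L, nrow(pairs))
    v[match(rownames(m), pairs$pair_id)] <- m[, 1L]
    v
  }
  r1_f1 <- sum_by_pair(ifelse(is_r1, ov_f1, 0L))
  r1_f2 <- sum_by_pair(ifelse(is_r1, ov_f2, 0L))
  r2_f1 <- sum_by_pair(ifelse(!is_r1, ov_f1, 0L))
  r2_f2 <- sum_by_pair(ifelse(!is_r1, ov_f2, 0L))
  # contiguous alignment through deleted bases: per-segment, read 2
  r2_del_contig <- sum_by_pair(ifelse(!is_r1 & ov_del >= min_overlap, 1L, 0L))

  # which reads contain the canonical junction
  contains_junction <- function(which_read) {
    ss <- segs[which_read, , drop = FALSE]
    if (nrow(ss) == 0L) return(logical(nrow(pairs)))
    ss <- ss[order(ss$pair_id, ss$ref_start), , drop = FALSE]
    n <- nrow(ss)
    hit <- character(0)
    if (n >= 2L) {
      same <- ss$pair_id[-1L] == ss$pair_id[-n]
      i <- which(same)
      if (length(i)) {
        cb <- canonical_breakpoints(ss$ref_end[i], ss$ref_start[i + 1L],
                                    locus)
        hit <- unique(ss$pair_id[i][cb$breakpoint1 == b1 &
                                      cb$breakpoint2 == b2])
      }
    }
    pairs$pair_id %in% hit
  }
  r1_junc <- contains_junction(is_r1)
  r2_junc <- contains_junction(!is_r1)

  # breakpoint assignment from read 1
  a1 <- r1_f1 >= min_overlap
  a2 <- r1_f2 >= min_overlap
  both <- a1 & a2
  r1_5p_left <- !is.na(pairs$read1_pos) & pairs$read1_pos < b1
  bp <- ifelse(both, ifelse(r1_5p_left, 1L, 2L),
               ifelse(a1, 1L, ifelse(a2, 2L, NA_integer_)))

  distal_ok <- ifelse(is.na(bp), FALSE,
                      ifelse(bp == 1L, r2_f2 >= min_overlap,
                             r2_f1 >= min_overlap))
  supporting <- !is.na(bp) & r2_junc & distal_ok
  non_supporting <- !is.na(bp) & !supporting & r2_del_contig > 0L

  out$breakpoint <- bp
  out$class[supporting] <- "supporting"
  out$class[non_supporting] <- "non_supporting"
  out$class[is.na(bp)] <- "uninformative"
  attr(out, "read1_junction_not_counted") <-
    sum(r1_junc & out$class != "supporting")
  out
}

#' Classify a single read pair
#'
#' Single-pair convenience wrapper around [classify_pairs()].
#'
#' @inheritParams classify_pairs
#' @param pair_id The pair to classify.
#' @return List with `breakpoint` (1, 2 or NA) and `class`.
#' @export
classify_pair <- function(rps, pair_id, call, locus = rps$locus,
                          min_overlap = 19L) {
  sub <- rps
  sub$pairs <- rps$pairs[rps$pairs$pair_id == pair_id, , drop = FALSE]
  if (nrow(sub$pairs) == 0L) stop("unknown pair_id", call. = FALSE)
  res <- classify_pairs(sub, call, locus, min_overlap,
                        include_duplicates = TRUE)
  list(breakpoint = res$breakpoint[1L], class = as.character(res$class[1L]))
}

#' Quantify deletion VAF from breakpoint evidence
#'
#' Classifies all unflagged pairs against the canonical call and combines
#' the two breakpoint estimates into the final depth-weighted VAF.
#' Molecule-level (deduplicated) counts define the estimate; raw-read
#' counts over all pairs are attached as attribute `"raw_counts"` for
#' diagnostics.
#'
#' @inheritParams classify_pairs
#' @return A `vaf_estimate`.
#' @export
quantify_vaf <- function(rps, call, locus = rps$locus, min_overlap = 19L) {
  cls <- classify_pairs(rps, call, locus, min_overlap)
  cnt <- function(bp, what) sum(cls$breakpoint == bp & cls$class == what,
                                na.rm = TRUE)
  est <- combined_vaf(
    breakpoint_vaf(cnt(1L, "supporting"), cnt(1L, "non_supporting"), 1L),
    breakpoint_vaf(cnt(2L, "supporting"), cnt(2L, "non_supporting"), 2L))
  raw <- classify_pairs(rps, call, locus, min_overlap,
                        include_duplicates = TRUE)
  attr(est, "raw_counts") <- table(raw$breakpoint, raw$class)
  attr(est, "read1_junction_not_counted") <-
    attr(cls, "read1_junction_not_counted")
  est
}

#' Unique-molecule pileup VAF at a single position
#'
#' Counts alternative-base versus total unique molecules covering one
#' reference position. This is plumbing for point-variant checks; it is
#' not a general small-variant caller.
#'
#' @param rps A deduplicated `read_pair_set` whose pairs carry sequences.
#' @param locus A [reference_locus()].
#' @param position 0-based reference offset.
#' @param alt_base Alternative base (A/C/G/T).
#' @return Fraction of alt molecules, or NA when no molecule covers the
#'   position.
#' @export
snv_pileup_vaf <- function(rps, locus, position, alt_base) {
  if (!alt_base %in% DNA_BASES)
    stop("alt_base must be one of A/C/G/T", call. = FALSE)
  position <- as.integer(position)
  if (position < 0L || position >= locus$length)
    stop("position outside locus", call. = FALSE)
  keep <- rps$pairs$pair_id[!rps$pairs$duplicate_flag]
  segs <- rps$segments[rps$segments$pair_id %in% keep &
                         rps$segments$ref_start <= position &
                         rps$segments$ref_end > position, , drop = FALSE]
  if (nrow(segs) == 0L) return(NA_real_)
  # prefer read 1 when both mates cover the position
  segs <- segs[order(segs$pair_id, segs$read), , drop = FALSE]
  segs <- segs[!duplicated(segs$pair_id), , drop = FALSE]
  off <- ifelse(segs$strand == "+",
                segs$q_start + (position - segs$ref_start),
                segs$q_start + (segs$ref_end - 1L - position))
  idx <- match(segs$pair_id, rps$pairs$pair_id)
  rseq <- ifelse(segs$read == 1L, rps$pairs$read1_seq[idx],
                 rps$pairs$read2_seq[idx])
  base <- substr(rseq, off + 1L, off + 1L)
  minus <- segs$strand == "-"
  base[minus] <- chartr("ACGT", "TGCA", base[minus])
  mean(base == alt_base)
}
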