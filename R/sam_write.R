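#' Write a read-pair set to SAM
#'
#' Emits one SAM record per aligned segment record: single-segment reads as
#' plain matches, junction reads of deletions longer than
#' `small_del_threshold` as a soft-clipped primary plus a supplementary
#' record linked with an `SA` tag, and shorter deletions as a single record
#' with an in-read `D` gap. The UMI is carried in the `RX` tag and mirrored
#' as the last `:`-separated field of the query name.
#'
#' @param rps A `read_pair_set` from [simulate_library()] or [read_sam()].
#' @param path Output SAM path.
#' @param small_del_threshold In-read gap representation cutoff in bp.
#' @return Invisibly, the path written.
#' @export
write_sam <- function(rps, path, small_del_threshold = 50L) {
  locus <- rps$locus
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", locus$name, locus$length),
    "@PG\tID:ampdel\tPN:ampdel"
  )
  seg_by_pair <- split(rps$segments,
                       factor(rps$segments$pair_id, levels = rps$pairs$pair_id))
  recs <- character(0)
  for (i in seq_len(nrow(rps$pairs))) {
    p <- rps$pairs[i, ]
    segs <- seg_by_pair[[i]]
    qname <- paste0(p$pair_id, ":", p$umi)
    for (rd in 1:2) {
      s <- segs[segs$read == rd, , drop = FALSE]
      if (nrow(s) == 0L) next
      mate <- segs[segs$read != rd, , drop = FALSE]
      rseq <- if (rd == 1L) p$read1_seq else p$read2_seq
      recs <- c(recs, sam_records_for_read(
        qname, s, mate, rseq, p$umi, rd, locus$name, small_del_threshold))
    }
  }
  writeLines(c(lines, recs), path)
  invisible(path)
}

# CIGAR in reference orientation for one aligned segment of a read
ref_orient_cigar <- function(seg, read_len) {
  len <- seg$ref_end - seg$ref_start
  lead_ro <- seg$q_start
  trail_ro <- read_len - seg$q_start - len
  if (seg$strand == "-") { tmp <- lead_ro; lead_ro <- trail_ro; trail_ro <- tmp }
  paste0(if (lead_ro > 0L) paste0(lead_ro, "S"), len, "M",
         if (trail_ro > 0L) paste0(trail_ro, "S"))
}

sam_records_for_read <- function(qname, s, mate, rseq, umi, rd, rname,
                                 small_del_threshold) {
  read_len <- nchar(rseq)
  minus <- s$strand[1L] == "-"
  seq_out <- if (minus) revcomp(rseq) else rseq
  qual <- strrep("I", read_len)
  mate_minus <- nrow(mate) > 0L && mate$strand[1L] == "-"
  pnext <- if (nrow(mate)) min(mate$ref_start) + 1L else 0L
  span_lo <- min(s$ref_start, if (nrow(mate)) mate$ref_start else s$ref_start)
  span_hi <- max(s$ref_end, if (nrow(mate)) mate$ref_end else s$ref_end)
  tlen <- (span_hi - span_lo) * if (minus) -1L else 1L
  base_flag <- 1L + 2L + (if (minus) 16L else 0L) +
    (if (mate_minus) 32L else 0L) + (if (rd == 1L) 64L else 128L)
  tags <- paste0("RX:Z:", umi)

  s <- s[order(s$seg_order), , drop = FALSE]
  if (nrow(s) == 2L) {
    ref_sorted <- s[order(s$ref_start), , drop = FALSE]
    gap <- ref_sorted$ref_start[2L] - ref_sorted$ref_end[1L]
    if (gap <= small_del_threshold) {
      # single record with an in-read deletion gap
      cigar <- paste0(ref_sorted$ref_end[1L] - ref_sorted$ref_start[1L], "M",
                      gap, "D",
                      ref_sorted$ref_end[2L] - ref_sorted$ref_start[2L], "M")
      return(paste(qname, base_flag, rname, ref_sorted$ref_start[1L] + 1L, 60,
                   cigar, "=", pnext, tlen, seq_out, qual, tags, sep = "\t"))
    }
    cigars <- vapply(1:2, function(j) ref_orient_cigar(s[j, ], read_len), "")
    sa <- vapply(1:2, function(j)
      sprintf("SA:Z:%s,%d,%s,%s,60,0;", rname, s$ref_start[j] + 1L,
              s$strand[j], cigars[j]), "")
    return(vapply(1:2, function(j) {
      fl <- base_flag + if (j == 2L) 2048L else 0L
      paste(qname, fl, rname, s$ref_start[j] + 1L, 60, cigars[j], "=",
            pnext, tlen, seq_out, qual, sa[3L - j], tags, sep = "\t")
    }, ""))
  }
  cigar <- ref_orient_cigar(s[1L, ], read_len)
  paste(qname, base_flag, rname, s$ref_start[1L] + 1L, 60, cigar, "=",
        pnext, tlen, seq_out, qual, tags, sep = "\t")
}

#' Write paired FASTQ files
#'
#' Read sequences are written in sequencing (read 5'->3') orientation for
#' users who want to run a real aligner on the simulated library.
#'
#' @param rps A `read_pair_set`.
#' @param prefix Output prefix; files `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` are created.
#' @return Invisibly, the two paths.
#' @export
write_fastq <- function(rps, prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (rd in 1:2) {
    seqs <- if (rd == 1L) rps$pairs$read1_seq else rps$pairs$read2_seq
    keep <- nchar(seqs) > 0L
    ids <- paste0("@", rps$pairs$pair_id[keep], ":", rps$pairs$umi[keep],
                  "/", rd)
    writeLines(as.vector(rbind(ids, seqs[keep], "+",
                               strrep("I", nchar(seqs[keep])))), paths[rd])
  }
  invisible(paths)
}

#' Write the reference locus as FASTA
#'
#' @param locus A [reference_locus()].
#' @param path Output FASTA path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(locus, path) {
  dss <- Biostrings::DNAStringSet(structure(locus$sequence,
                                            names = locus$name))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
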