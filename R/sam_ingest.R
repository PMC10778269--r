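#' Decompose a CIGAR into reference-aligned segments
#'
#' Walks the CIGAR over reference coordinates and returns the aligned
#' segments of the record. Deletion/skip gaps (`D`/`N`) at least
#' `absorb_threshold` bp long split the record into separate segments;
#' shorter gaps are absorbed into a single segment (alignment micro-indels
#' are not structural-variant evidence). Soft/hard clips never produce
#' segments but do advance query offsets.
#'
#' @param pos0 0-based reference position of the first aligned base.
#' @param cigar CIGAR string.
#' @param absorb_threshold Minimum `D`/`N` gap length (bp) that splits a
#'   record into two segments.
#' @return Data frame with one row per segment: `ref_start`, `ref_end`
#'   (0-based half-open), `q_start`, `q_end` (0-based query offsets in
#'   reference orientation), and `match_len` (bases consuming both query
#'   and reference).
#' @examples
#' segments_from_cigar(0, "70M548D80M")  # [0,70) and [618,698)
#' @export
segments_from_cigar <- function(pos0, cigar, absorb_threshold = 5L) {
  if (is.na(cigar) || cigar == "*" || !grepl("^([0-9]+[MIDNSHP=X])+$", cigar))
    stop(sprintf("malformed CIGAR '%s'", cigar), call. = FALSE)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  ref <- as.integer(pos0); q <- 0L
  seg_ref_start <- seg_q_start <- NA_integer_
  seg_match <- 0L
  out <- list()
  close_seg <- function() {
    if (!is.na(seg_ref_start) && ref > seg_ref_start)
      out[[length(out) + 1L]] <<- data.frame(
        ref_start = seg_ref_start, ref_end = ref,
        q_start = seg_q_start, q_end = q, match_len = seg_match)
    seg_ref_start <<- NA_integer_
  }
  for (i in seq_along(ops)) {
    op <- ops[i]; n <- lens[i]
    if (op %in% c("M", "=", "X")) {
      if (is.na(seg_ref_start)) { seg_ref_start <- ref; seg_q_start <- q
                                  seg_match <- 0L }
      ref <- ref + n; q <- q + n; seg_match <- seg_match + n
    } else if (op %in% c("D", "N")) {
      if (n >= absorb_threshold) { close_seg(); ref <- ref + n }
      else ref <- ref + n                      # absorbed into current segment
    } else if (op == "I") {
      q <- q + n
    } else if (op %in% c("S", "H")) {
      close_seg(); q <- q + n
    }
  }
  close_seg()
  if (length(out) == 0L)
    stop(sprintf("CIGAR '%s' aligns no reference bases", cigar),
         call. = FALSE)
  do.call(rbind, out)
}

#' Read aligned UMI-tagged pairs from a SAM file
#'
#' Parses a SAM (or BAM) file with a single reference sequence in the
#' header into the internal read-pair model. Mates are joined by query
#' name; supplementary records are merged as additional segments of the
#' same read, ordered along the read 5'->3'; secondary and unmapped records
#' are dropped and counted. The UMI is taken from the `RX` tag, falling
#' back to the last `:`-separated field of the query name.
#'
#' @param path SAM or BAM path.
#' @param absorb_threshold Passed to [segments_from_cigar()].
#' @return A `read_pair_set`; skip counters are attached as attribute
#'   `"counts"` and reported via `message()`.
#' @export
read_sam <- function(path, absorb_threshold = 5L) {
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) path else
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (length(hdr) != 1L)
    stop("multi-reference SAM input is not supported", call. = FALSE)
  locus <- structure(
    list(name = names(hdr), sequence = NULL, length = unname(hdr)),
    class = "reference_locus"
  )
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "cigar", "strand", "seq"),
    tag = "RX",
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n_in <- length(res$qname)
  mapped <- !bitwAnd(res$flag, 4L)
  n_unmapped <- sum(!mapped)

  rec <- data.frame(
    qname = res$qname[mapped], flag = res$flag[mapped],
    pos0 = res$pos[mapped] - 1L, cigar = res$cigar[mapped],
    strand = as.character(res$strand)[mapped],
    seq = as.character(res$seq)[mapped],
    rx = if (is.null(res$tag$RX)) NA_character_ else res$tag$RX[mapped],
    stringsAsFactors = FALSE
  )
  rec$read <- ifelse(bitwAnd(rec$flag, 64L) > 0L, 1L, 2L)
  rec$supp <- bitwAnd(rec$flag, 2048L) > 0L

  pair_rows <- list(); seg_rows <- list()
  n_no_umi <- 0L
  rec_by_q <- split(rec, factor(rec$qname, levels = unique(rec$qname)))
  for (qn in names(rec_by_q)) {
    rr <- rec_by_q[[qn]]
    umi <- rr$rx[!is.na(rr$rx) & nzchar(rr$rx)][1L]
    if (is.na(umi)) {
      parts <- strsplit(qn, ":", fixed = TRUE)[[1L]]
      cand <- parts[length(parts)]
      if (grepl("^[ACGTN]+$", cand)) umi <- cand
    }
    if (is.na(umi) || !nzchar(umi)) { n_no_umi <- n_no_umi + 1L; next }
    pair_id <- sub(sprintf(":%s$", umi), "", qn)

    per_read <- lapply(1:2, function(rd) {
      rrd <- rr[rr$read == rd, , drop = FALSE]
      if (nrow(rrd) == 0L) return(NULL)
      read_len <- max(nchar(rrd$seq))
      segs <- do.call(rbind, lapply(seq_len(nrow(rrd)), function(j) {
        s <- segments_from_cigar(rrd$pos0[j], rrd$cigar[j], absorb_threshold)
        s$strand <- rrd$strand[j]
        # query offset along the read 5'->3'
        s$q_read <- if (rrd$strand[j] == "-")
          read_len - s$q_end else s$q_start
        s
      }))
      segs <- segs[order(segs$q_read), , drop = FALSE]
      segs$seg_order <- seq_len(nrow(segs))
      prim <- which(!rrd$supp)[1L]
      if (is.na(prim)) prim <- 1L
      rseq <- rrd$seq[prim]
      if (rrd$strand[prim] == "-") rseq <- revcomp(rseq)
      list(segs = segs, seq = rseq)
    })

    r1 <- per_read[[1L]]; r2 <- per_read[[2L]]
    r1_pos <- NA_integer_; r1_strand <- NA_character_
    if (!is.null(r1)) {
      first <- r1$segs[1L, ]
      r1_strand <- first$strand
      r1_pos <- if (first$strand == "-") first$ref_end - 1L else first$ref_start
    }
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      pair_id = pair_id, family_id = NA_character_, umi = umi,
      read1_pos = r1_pos, read1_strand = r1_strand, duplicate_flag = FALSE,
      genotype = NA_character_,
      read1_seq = if (is.null(r1)) "" else r1$seq,
      read2_seq = if (is.null(r2)) "" else r2$seq,
      stringsAsFactors = FALSE)
    for (rd in 1:2) {
      pr <- per_read[[rd]]
      if (is.null(pr)) next
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        pair_id = pair_id, read = rd, seg_order = pr$segs$seg_order,
        ref_start = pr$segs$ref_start, ref_end = pr$segs$ref_end,
        strand = pr$segs$strand, q_start = pr$segs$q_read,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    empty_pairs_df()
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else
    empty_segments_df()
  counts <- c(records = n_in, unmapped_records = n_unmapped,
              pairs_missing_umi = n_no_umi)
  if (n_unmapped + n_no_umi > 0L)
    message(sprintf("read_sam: dropped %d unmapped record(s), skipped %d pair(s) without UMI",
                    n_unmapped, n_no_umi))
  new_read_pair_set(pairs, segments, locus, counts = counts)
}

empty_pairs_df <- function() {
  data.frame(pair_id = character(0), family_id = character(0),
             umi = character(0), read1_pos = integer(0),
             read1_strand = character(0), duplicate_flag = logical(0),
             genotype = character(0), read1_seq = character(0),
             read2_seq = character(0), stringsAsFactors = FALSE)
}

empty_segments_df <- function() {
  data.frame(pair_id = character(0), read = integer(0),
             seg_order = integer(0), ref_start = integer(0),
             ref_end = integer(0), strand = character(0),
             q_start = integer(0), stringsAsFactors = FALSE)
}
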