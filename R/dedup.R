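#' Mark duplicate read pairs by position and UMI
#'
#' Groups pairs by the key (read 1 5' mapping position, read 1 strand,
#' exact UMI sequence) and leaves exactly one representative per group
#' unflagged: the pair with the largest total aligned length, ties broken
#' by lexicographically smallest `pair_id`. All downstream molecule counts
#' use unflagged pairs only, so one group is one UMI family ("variant
#' copy"). No UMI-error network collapse is performed: duplicates are
#' marked, not consensus-called, and UMIs must match exactly.
#'
#' @param rps A `read_pair_set`.
#' @return The same set with `duplicate_flag` set; a summary
#'   (`n_pairs`, `n_families`, `duplicate_fraction`) is attached as
#'   attribute `"dedup_summary"`.
#' @export
mark_duplicates <- function(rps) {
  pairs <- rps$pairs
  if (nrow(pairs) == 0L) {
    attr(rps, "dedup_summary") <- data.frame(
      n_pairs = 0L, n_families = 0L, duplicate_fraction = NA_real_)
    return(rps)
  }
  seg_len <- rps$segments$ref_end - rps$segments$ref_start
  m <- rowsum(seg_len, rps$segments$pair_id)
  alen <- rep(0, nrow(pairs))
  hit <- match(rownames(m), pairs$pair_id)
  alen[hit[!is.na(hit)]] <- m[!is.na(hit), 1L]
  usable <- !is.na(pairs$read1_pos)
  key <- ifelse(usable,
                paste(pairs$read1_pos, pairs$read1_strand, pairs$umi,
                      sep = "\r"),
                paste0("\r.unusable.", pairs$pair_id))
  ord <- order(key, -alen, pairs$pair_id)
  dup <- duplicated(key[ord])
  flag <- logical(nrow(pairs))
  flag[ord] <- dup
  pairs$duplicate_flag <- flag
  rps$pairs <- pairs
  n_fam <- length(unique(key[usable]))
  attr(rps, "dedup_summary") <- data.frame(
    n_pairs = nrow(pairs), n_families = n_fam,
    duplicate_fraction = mean(flag))
  rps
}
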