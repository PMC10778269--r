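# Shared fixtures and independent oracles. Everything here is deliberately
# naive (string comparisons, exhaustive loops) so it can serve as a
# cross-check for the vectorized implementation.

default_locus_spec <- function(seed = 1L, mh = 0L, start = 700L,
                               end = 1248L) {
  spec <- deletion_spec(start, end, microhomology_len = mh)
  locus <- install_microhomology(make_reference(seed, 2000L), spec)
  list(locus = locus, spec = spec, panel = make_panel(locus, spec))
}

# all equivalent placements of deleting [b1, b2), found by literal string
# equality of the resulting mutant sequence
bf_placements <- function(locus, b1, b2, window = 30L) {
  s <- locus$sequence
  del0 <- paste0(substr(s, 1L, b1), substring(s, b2 + 1L))
  shifts <- seq(-min(window, b1), min(window, locus$length - b2))
  keep <- vapply(shifts, function(k) {
    paste0(substr(s, 1L, b1 + k), substring(s, b2 + k + 1L)) == del0
  }, logical(1))
  shifts[keep]
}

bf_canonical <- function(locus, b1, b2) {
  r <- max(bf_placements(locus, b1, b2))
  c(b1 + r, b2 + r)
}

# exhaustive re-implementation of the caller: every inter-segment interval,
# canonicalized by the string oracle, tallied per unique molecule
bf_top_call <- function(rps, locus, min_del_len = 10L) {
  tallies <- list()
  pairs <- rps$pairs[!rps$pairs$duplicate_flag, , drop = FALSE]
  for (pid in pairs$pair_id) {
    seen <- character(0)
    for (rd in 1:2) {
      ss <- rps$segments[rps$segments$pair_id == pid &
                           rps$segments$read == rd, , drop = FALSE]
      if (nrow(ss) < 2L) next
      ss <- ss[order(ss$ref_start), , drop = FALSE]
      for (j in seq_len(nrow(ss) - 1L)) {
        b1 <- ss$ref_end[j]; b2 <- ss$ref_start[j + 1L]
        if (b2 - b1 < min_del_len) next
        cc <- bf_canonical(locus, b1, b2)
        key <- paste(cc[1L], cc[2L])
        if (!key %in% seen) {
          seen <- c(seen, key)
          tallies[[key]] <- (tallies[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  if (length(tallies) == 0L) return(NULL)
  b <- do.call(rbind, strsplit(names(tallies), " "))
  df <- data.frame(b1 = as.integer(b[, 1L]), b2 = as.integer(b[, 2L]),
                   support = unlist(tallies))
  df$len <- df$b2 - df$b1
  df <- df[order(-df$support, df$b1, df$len), , drop = FALSE]
  df[1L, ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built read-pair sets for geometry fixtures: each element of `reads`
# is list(read = 1/2, strand, segs = list(c(start, end), ...)) in read order
manual_rps <- function(locus, pair_specs) {
  pair_rows <- list(); seg_rows <- list()
  for (p in pair_specs) {
    r1 <- NULL
    for (rr in p$reads) {
      q <- 0L
      for (k in seq_along(rr$segs)) {
        sg <- rr$segs[[k]]
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          pair_id = p$id, read = rr$read, seg_order = k,
          ref_start = sg[1L], ref_end = sg[2L], strand = rr$strand,
          q_start = q, stringsAsFactors = FALSE)
        q <- q + (sg[2L] - sg[1L])
      }
      if (rr$read == 1L) r1 <- rr
    }
    first <- r1$segs[[1L]]
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      pair_id = p$id, family_id = NA_character_,
      umi = p$umi %||% "AAAA",
      read1_pos = if (r1$strand == "-") first[2L] - 1L else first[1L],
      read1_strand = r1$strand, duplicate_flag = FALSE,
      genotype = NA_character_, read1_seq = "", read2_seq = "",
      stringsAsFactors = FALSE)
  }
  ampdel:::new_read_pair_set(do.call(rbind, pair_rows),
                             do.call(rbind, seg_rows), locus)
}

# closed-form ordinary least squares, independent of stats::lm
bf_ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  r2 <- 1 - sum(resid^2) / sum((y - yb)^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}
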