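#' Construct a primer panel
#'
#' A panel is a set of single-primer-extension anchor points. Each primer
#' defines where read 1 of every derived fragment starts: a `+` primer
#' anchors read 1's 5' end at `pos` and extends rightwards along the
#' reference; a `-` primer anchors read 1's 5' end at `pos` and extends
#' leftwards.
#'
#' @param pos Integer vector of 0-based anchor offsets.
#' @param strand Character vector of "+"/"-", recycled to `length(pos)`.
#' @return A `primer_panel` data frame with columns `primer_id`, `pos`,
#'   `strand`.
#' @export
primer_panel <- function(pos, strand) {
  pos <- as.integer(pos)
  strand <- rep_len(as.character(strand), length(pos))
  if (!all(strand %in% c("+", "-")))
    stop("primer strand must be '+' or '-'", call. = FALSE)
  structure(
    data.frame(primer_id = sprintf("P%02d", seq_along(pos)),
               pos = pos, strand = strand, stringsAsFactors = FALSE),
    class = c("primer_panel", "data.frame")
  )
}

#' Default double-stranded panel flanking a deletion
#'
#' Places `length(offsets)` plus-strand primers upstream of the deletion's
#' left breakpoint and the mirror-image minus-strand primers downstream of
#' the right breakpoint, so each breakpoint is read across from its own
#' flank on its own strand. Offsets are distances from the breakpoint to the
#' read-1 anchor; they must leave at least the minimum overlap (19 bp) of
#' read 1 on the flank, and stay within one insert length of the junction so
#' read 2 can reach informative bases.
#'
#' @param locus A [reference_locus()].
#' @param spec A [deletion_spec()].
#' @param offsets Integer distances (bp) between each primer anchor and its
#'   breakpoint.
#' @return A [primer_panel()].
#' @export
make_panel <- function(locus, spec, offsets = c(45L, 70L)) {
  validate_deletion_spec(spec, locus)
  offsets <- as.integer(offsets)
  if (any(offsets < 19L) || any(offsets > 150L))
    stop("primer offsets must lie in [19, 150] bp", call. = FALSE)
  panel <- primer_panel(
    pos = c(spec$start - offsets, spec$end + offsets - 1L),
    strand = rep(c("+", "-"), each = length(offsets))
  )
  validate_panel(panel, locus, spec)
  panel
}

validate_panel <- function(panel, locus, spec = NULL) {
  if (any(panel$pos < 0L) || any(panel$pos >= locus$length))
    stop("primer anchors must lie inside the locus", call. = FALSE)
  if (!is.null(spec)) {
    d_left <- spec$start - panel$pos[panel$strand == "+"]
    d_right <- panel$pos[panel$strand == "-"] - (spec$end - 1L)
    if (!any(d_left >= 1L & d_left <= 150L))
      stop("no plus-strand primer within 150 bp upstream of the left flank",
           call. = FALSE)
    if (!any(d_right >= 1L & d_right <= 150L))
      stop("no minus-strand primer within 150 bp of the right flank",
           call. = FALSE)
  }
  invisible(TRUE)
}
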