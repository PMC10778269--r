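#' Library simulation parameters
#'
#' Bundles the wet-lab-facing knobs of the synthetic amplicon library
#' generator: input mass (which fixes the molecule pool through
#' genome-equivalent arithmetic), the spiked variant allele frequency, the
#' targeted unique-family depth per breakpoint, PCR duplication, read/insert
#' geometry and the per-base substitution error rate.
#'
#' @param input_mass_ng DNA input in nanograms; the molecule pool holds
#'   `2 * genome_equivalents(input_mass_ng)` allele copies of the locus.
#' @param vaf Fraction of the allele pool carrying the variant, in \[0, 1\].
#' @param target_umi_depth Mean number of unique UMI families per
#'   breakpoint-informative position; split evenly across the primers of
#'   each strand.
#' @param duplicate_rate Mean raw read pairs per UMI family (>= 1); each
#'   family emits `1 + Poisson(duplicate_rate - 1)` pairs.
#' @param read_length Read length in bp (2 x `read_length` sequencing).
#' @param insert_mean,insert_sd Fragment (insert) length model, Normal
#'   truncated to `[38, locus length]` so the 19 bp overlap rule stays
#'   satisfiable on both sides of a junction.
#' @param substitution_error_rate Per-base substitution probability applied
#'   independently to every sequenced base. Substitutions never alter the
#'   truth alignments, so they cannot fabricate junction-spanning reads.
#' @param umi_length UMI length in bases.
#' @param seed Integer seed; every stochastic step of the simulator draws
#'   from it.
#' @param chimera_rate Probability that a wild-type family is emitted as a
#'   junction-spanning artifact (off by default; used to probe the limit of
#'   blank under induced chimerism).
#' @param small_del_threshold Deletions at most this long are written to SAM
#'   as a single record with an in-read deletion gap; longer ones as a
#'   soft-clipped primary plus supplementary record pair.
#' @return A `library_config` object.
#' @export
library_config <- function(input_mass_ng = 20, vaf = 0,
                           target_umi_depth = 400, duplicate_rate = 2,
                           read_length = 150L, insert_mean = 110,
                           insert_sd = 10, substitution_error_rate = 1e-3,
                           umi_length = 12L, seed = 1L,
                           chimera_rate = 0, small_del_threshold = 50L) {
  if (vaf < 0 || vaf > 1) stop("vaf must lie in [0, 1]", call. = FALSE)
  if (input_mass_ng <= 0) stop("input_mass_ng must be positive", call. = FALSE)
  if (target_umi_depth < 1) stop("target_umi_depth must be >= 1", call. = FALSE)
  if (read_length < 19L)
    stop("read_length must be >= 19 bp (minimum informative overlap)",
         call. = FALSE)
  if (insert_mean < 38)
    stop("insert_mean must be >= 38 bp (19 bp on each side of a junction)",
         call. = FALSE)
  if (duplicate_rate < 1) stop("duplicate_rate must be >= 1", call. = FALSE)
  structure(
    list(input_mass_ng = input_mass_ng, vaf = vaf,
         target_umi_depth = target_umi_depth,
         duplicate_rate = duplicate_rate,
         read_length = as.integer(read_length),
         insert_mean = insert_mean, insert_sd = insert_sd,
         substitution_error_rate = substitution_error_rate,
         umi_length = as.integer(umi_length), seed = as.integer(seed),
         chimera_rate = chimera_rate,
         small_del_threshold = as.integer(small_del_threshold)),
    class = "library_config"
  )
}

new_read_pair_set <- function(pairs, segments, locus, families = NULL,
                              counts = NULL) {
  structure(
    list(pairs = pairs, segments = segments, locus = locus),
    families = families, counts = counts,
    class = "read_pair_set"
  )
}

#' @export
print.read_pair_set <- function(x, ...) {
  cat(sprintf("<read_pair_set> %d pairs (%d flagged duplicate), %d segments, locus %s (%d bp)\n",
              nrow(x$pairs), sum(x$pairs$duplicate_flag),
              nrow(x$segments), x$locus$name, x$locus$length))
  invisible(x)
}

DNA_BASES <- c("A", "C", "G", "T")

random_umis <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

revcomp <- function(x) {
  out <- x
  idx <- which(nchar(x) > 0L)
  if (length(idx))
    out[idx] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[idx])))
  out
}

# sprinkle substitution errors over read-orientation sequences
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }
  seqs
}

#' Simulate a UMI-tagged paired-end amplicon library
#'
#' Models a single-primer-extension capture of the toy locus: a pool of
#' `2 * genome_equivalents(input_mass_ng)` allele molecules, of which
#' `round(vaf * pool)` carry the deletion (or SNV) allele, is sampled
#' without replacement at each primer to form UMI families; each family
#' emits one or more duplicate read pairs with truth alignments. Mutant
#' reads crossing the deletion junction are split into two reference
#' segments, with microhomology-ambiguous bases assigned to the read's
#' first (5', primer-side) segment.
#'
#' @param locus A [reference_locus()].
#' @param spec A [deletion_spec()], or `NULL` for a deletion-free library
#'   (pure wild type, or SNV-only when `snv` is given).
#' @param panel A [primer_panel()].
#' @param config A [library_config()].
#' @param snv Optional `list(pos = <0-based offset>, alt = <base>)` placing
#'   a substitution on the variant allele instead of a deletion. Mutually
#'   exclusive with `spec`.
#' @return A `read_pair_set`: pair table (`pair_id`, `umi`, `read1_pos`,
#'   `read1_strand`, `duplicate_flag`, sequences) plus a segment table of
#'   0-based half-open reference intervals per read in read 5'->3' order.
#'   The realized family table (genotype, fragment length, duplicate count)
#'   is attached as attribute `"families"`.
#' @export
simulate_library <- function(locus, spec = NULL, panel, config, snv = NULL) {
  stopifnot(inherits(locus, "reference_locus"),
            inherits(config, "library_config"))
  if (!is.null(spec) && !is.null(snv))
    stop("provide either a deletion spec or an SNV, not both", call. = FALSE)
  if (!is.null(spec)) validate_deletion_spec(spec, locus)
  validate_panel(panel, locus, spec)
  if (is.null(spec) && is.null(snv) && config$vaf > 0)
    stop("vaf > 0 requires a variant (deletion spec or SNV)", call. = FALSE)

  set.seed(config$seed)
  pool <- 2L * genome_equivalents(config$input_mass_ng)
  n_mut <- as.integer(round(config$vaf * pool))
  if (config$vaf > 0 && n_mut == 0L)
    warning("variant copy count rounds to 0 at this VAF; ",
            "library contains no variant molecules (sampling dropout)")

  # haplotypes
  hap_wt <- locus$sequence
  del_len <- 0L; j0 <- NA_integer_; sh_l <- 0L; sh_r <- 0L
  if (!is.null(spec)) {
    hap_mut <- apply_deletion(locus, spec)
    del_len <- spec$length
    j0 <- spec$start
    rng <- junction_shift_range(locus, spec$start, spec$end)
    sh_l <- rng$left; sh_r <- rng$right
  } else if (!is.null(snv)) {
    if (!snv$alt %in% DNA_BASES) stop("snv alt must be A/C/G/T", call. = FALSE)
    hap_mut <- hap_wt
    base_at0(hap_mut, as.integer(snv$pos)) <- snv$alt
  } else hap_mut <- hap_wt

  # families: sample molecules without replacement per primer
  n_same_strand <- table(panel$strand)[panel$strand]
  fam_per_primer <- pmax(1L, as.integer(round(
    config$target_umi_depth / as.integer(n_same_strand))))
  fam <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    nf <- min(fam_per_primer[i], pool)
    mols <- sample.int(pool, nf)
    mut <- mols <= n_mut
    out <- data.frame(primer_id = panel$primer_id[i],
                      primer_pos = panel$pos[i],
                      primer_strand = panel$strand[i], molecule = mols,
                      genotype = ifelse(mut, "mut", "wt"),
                      stringsAsFactors = FALSE)
    # a mutant molecule lacks [start, end): primers inside it cannot bind
    if (!is.null(spec) && panel$pos[i] >= spec$start && panel$pos[i] < spec$end)
      out <- out[!mut, , drop = FALSE]
    out
  }))
  nfam <- nrow(fam)
  if (config$chimera_rate > 0 && !is.null(spec)) {
    flip <- fam$genotype == "wt" &
      stats::runif(nfam) < config$chimera_rate
    fam$genotype[flip] <- "chimera"
  }
  fam$family_id <- sprintf("F%05d", seq_len(nfam))
  fam$umi <- random_umis(nfam, config$umi_length)
  mutlike <- fam$genotype != "wt"

  # fragment geometry in haplotype coordinates
  hap_len <- ifelse(mutlike, locus$length - del_len, locus$length)
  p_hap <- fam$primer_pos
  if (!is.null(spec))
    p_hap <- ifelse(mutlike & fam$primer_pos >= spec$end,
                    fam$primer_pos - del_len, fam$primer_pos)
  L <- as.integer(round(stats::rnorm(nfam, config$insert_mean,
                                     config$insert_sd)))
  L <- pmax(L, 38L)
  plus <- fam$primer_strand == "+"
  L <- ifelse(plus, pmin(L, hap_len - p_hap), pmin(L, p_hap + 1L))
  fam$frag_len <- L
  fam$n_read_pairs <- 1L + stats::rpois(nfam, config$duplicate_rate - 1)

  fa <- ifelse(plus, p_hap, p_hap - L + 1L)
  fb <- fa + L
  m <- pmin(config$read_length, L)
  # read anchored at the fragment's plus end vs minus end
  plus_end <- list(a = fa, b = fa + m, strand = "+")
  minus_end <- list(a = fb - m, b = fb, strand = "-")

  # expand families to read pairs
  pidx <- rep.int(seq_len(nfam), fam$n_read_pairs)
  pair_id <- sprintf("%s:R%02d", fam$family_id[pidx],
                     sequence(fam$n_read_pairs))

  read_geom <- function(which_read) {
    # read 1 sits at the primer anchor: fragment plus end for "+" primers
    use_plus_end <- if (which_read == 1L) plus else !plus
    list(a = ifelse(use_plus_end, plus_end$a, minus_end$a),
         b = ifelse(use_plus_end, plus_end$b, minus_end$b),
         strand = ifelse(use_plus_end, "+", "-"))
  }

  seg_tables <- list(); seq_by_read <- list()
  spans_junction_fam <- rep(FALSE, nfam)
  for (rd in 1:2) {
    g <- read_geom(rd)
    a <- g$a; b <- g$b; strand <- g$strand
    if (!is.null(spec)) {
      span <- mutlike & a < j0 & b > j0
      k <- ifelse(strand == "+", sh_r, -sh_l)
      cut <- j0 + k
      two <- span & cut > a & cut < b
      shift <- ifelse(mutlike & ((!span & a >= j0) | (span & cut <= a)),
                      del_len, 0L)
    } else {
      span <- two <- rep(FALSE, nfam)
      cut <- rep(NA_integer_, nfam)
      shift <- rep(0L, nfam)
    }
    spans_junction_fam <- spans_junction_fam | two

    one <- !two
    segs <- rbind(
      data.frame(fidx = which(one), ref_start = (a + shift)[one],
                 ref_end = (b + shift)[one],
                 q_start = rep(0L, sum(one)),
                 seg_order = rep(1L, sum(one)), stringsAsFactors = FALSE),
      data.frame(fidx = which(two), ref_start = a[two],
                 ref_end = cut[two],
                 q_start = ifelse(strand[two] == "+", 0L, (b - cut)[two]),
                 seg_order = ifelse(strand[two] == "+", 1L, 2L),
                 stringsAsFactors = FALSE),
      data.frame(fidx = which(two), ref_start = (cut + del_len)[two],
                 ref_end = (b + del_len)[two],
                 q_start = ifelse(strand[two] == "+", (cut - a)[two], 0L),
                 seg_order = ifelse(strand[two] == "+", 2L, 1L),
                 stringsAsFactors = FALSE)
    )
    segs$strand <- strand[segs$fidx]
    seg_tables[[rd]] <- segs

    hs <- ifelse(mutlike, hap_mut, hap_wt)
    rseq <- substring(hs, a + 1L, b)
    rseq[strand == "-"] <- revcomp(rseq[strand == "-"])
    seq_by_read[[rd]] <- rseq
  }

  fam$junction_spanning <- spans_junction_fam

  # per-pair tables (duplicates of one family share coordinates, not errors)
  read1 <- read_geom(1L)
  r1_first_5p <- ifelse(read1$strand == "+", read1$a, read1$b - 1L)
  # map haplotype 5' anchor back to reference for mutant molecules
  if (!is.null(spec))
    r1_first_5p <- ifelse(mutlike & r1_first_5p >= j0,
                          r1_first_5p + del_len, r1_first_5p)
  pairs <- data.frame(
    pair_id = pair_id,
    family_id = fam$family_id[pidx],
    umi = fam$umi[pidx],
    read1_pos = r1_first_5p[pidx],
    read1_strand = read1$strand[pidx],
    duplicate_flag = FALSE,
    genotype = fam$genotype[pidx],
    read1_seq = inject_errors(seq_by_read[[1L]][pidx],
                              config$substitution_error_rate),
    read2_seq = inject_errors(seq_by_read[[2L]][pidx],
                              config$substitution_error_rate),
    stringsAsFactors = FALSE
  )

  pairs_of_fam <- split(seq_along(pidx), factor(pidx, levels = seq_len(nfam)))
  segments <- do.call(rbind, lapply(1:2, function(rd) {
    st <- seg_tables[[rd]]
    # replicate each family's segments across its duplicate pairs
    rep_idx <- pairs_of_fam[st$fidx]
    n_rep <- lengths(rep_idx)
    out <- st[rep.int(seq_len(nrow(st)), n_rep), , drop = FALSE]
    out$pair_idx <- unlist(rep_idx)
    out$read <- rd
    out
  }))
  segments <- data.frame(
    pair_id = pair_id[segments$pair_idx], read = segments$read,
    seg_order = segments$seg_order, ref_start = segments$ref_start,
    ref_end = segments$ref_end, strand = segments$strand,
    q_start = segments$q_start, stringsAsFactors = FALSE
  )
  segments <- segments[order(segments$pair_id, segments$read,
                             segments$seg_order), , drop = FALSE]
  rownames(segments) <- NULL

  fam$molecule <- NULL
  new_read_pair_set(pairs, segments, locus,
                    families = fam,
                    counts = c(pool = pool, n_mut = n_mut))
}
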