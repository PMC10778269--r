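#' Diploid genome equivalents of a DNA mass
#'
#' Converts an input mass to diploid human genome equivalents using a
#' haploid genome mass of 3.3 pg (6.6 pg diploid); 20 ng of DNA thus
#' corresponds to about 3030 diploid genome equivalents.
#'
#' @param mass_ng DNA mass in nanograms (> 0).
#' @param diploid_pg Diploid genome mass in picograms.
#' @return Integer genome-equivalent count (rounded for reporting).
#' @examples
#' genome_equivalents(20)  # 3030
#' @export
genome_equivalents <- function(mass_ng, diploid_pg = 6.6) {
  if (!is.numeric(mass_ng) || mass_ng <= 0)
    stop("mass_ng must be positive", call. = FALSE)
  as.integer(round(mass_ng * 1000 / diploid_pg))
}

#' Theoretical detection limit from genome equivalents
#'
#' The best possible sensitivity of a single-variant assay is one variant
#' copy among the sampled genome equivalents: `100 / genome_equiv` percent
#' VAF.
#'
#' @param genome_equiv Diploid genome-equivalent count (>= 1).
#' @return List with `value` (unrounded % VAF) and `reported` (one
#'   significant figure).
#' @examples
#' theoretical_lod_percent(3030)$reported  # 0.03
#' @export
theoretical_lod_percent <- function(genome_equiv) {
  if (!is.numeric(genome_equiv) || genome_equiv < 1)
    stop("genome_equiv must be >= 1", call. = FALSE)
  v <- 100 / genome_equiv
  list(value = v, reported = signif(v, 1))
}

#' Coverage-based realistic detection threshold
#'
#' One variant read among the mean read coverage: `100 / mean_coverage`
#' percent VAF (about 0.12% at 837x).
#'
#' @param mean_coverage Mean fold coverage (>= 1).
#' @return Percent VAF threshold.
#' @export
coverage_threshold_percent <- function(mean_coverage) {
  if (!is.numeric(mean_coverage) || mean_coverage < 1)
    stop("mean_coverage must be >= 1", call. = FALSE)
  100 / mean_coverage
}

#' Simulate, call and quantify one library
#'
#' Convenience pipeline: [simulate_library()], [mark_duplicates()],
#' [call_deletion()] and, when a deletion is called, [quantify_vaf()].
#'
#' @inheritParams simulate_library
#' @param truth Optional `deletion_spec` used to decide whether the call
#'   recovers the simulated deletion (canonical breakpoints compared).
#' @return List with `rps`, `call`, `estimate` (or NULL), `detected`
#'   (logical), `supporting_molecules`.
#' @export
run_sample <- function(locus, spec, panel, config, truth = spec) {
  rps <- simulate_library(locus, spec, panel, config)
  rps <- mark_duplicates(rps)
  call <- call_deletion(rps, locus)
  detected <- FALSE; est <- NULL; support <- 0L
  if (!is.null(call)) {
    if (!is.null(truth)) {
      canon <- canonicalize_junction(
        list(breakpoint1 = truth$start, breakpoint2 = truth$end), locus)
      detected <- call$breakpoint1 == canon$breakpoint1 &&
        call$breakpoint2 == canon$breakpoint2
    } else detected <- TRUE
    if (detected) {
      support <- call$supporting_molecules
      est <- quantify_vaf(rps, call, locus)
    }
  }
  list(rps = rps, call = call, estimate = est, detected = detected,
       supporting_molecules = support)
}

#' Run a dilution-series evaluation
#'
#' Simulates `replicates` libraries at every VAF level of the ladder,
#' running deduplication, deletion calling and VAF quantification on each,
#' and aggregates per level: the observed VAF is the mean of defined
#' estimates and a level is detected when any replicate yields at least
#' one molecule supporting the true deletion.
#'
#' @param ladder_percent Numeric vector of expected VAF levels in percent.
#' @param replicates Libraries per level (>= 1).
#' @param locus,spec,panel Simulation inputs; see [simulate_library()].
#' @param config Baseline [library_config()]; its `vaf` and `seed` are
#'   overridden per level/replicate.
#' @param seed Base seed; replicate seeds are drawn consecutively from it.
#' @return Data frame of dilution points: `expected_vaf_percent`,
#'   `observed_vaf_percent`, `supporting_families`, `detected`,
#'   `n_detected_replicates`. Per-replicate detail is attached as
#'   attribute `"replicates"`.
#' @export
run_dilution_series <- function(ladder_percent, replicates, locus, spec,
                                panel, config, seed = config$seed) {
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (any(ladder_percent < 0))
    stop("ladder levels must be >= 0", call. = FALSE)
  detail <- list()
  counter <- 0L
  for (lv in ladder_percent) {
    for (rep_i in seq_len(replicates)) {
      counter <- counter + 1L
      cfg <- config
      cfg$vaf <- lv / 100
      cfg$seed <- as.integer(seed + counter)
      res <- suppressWarnings(run_sample(locus, spec, panel, cfg))
      detail[[counter]] <- data.frame(
        expected_vaf_percent = lv, replicate = rep_i,
        supporting_families = res$supporting_molecules,
        observed_vaf_percent = if (!is.null(res$estimate) &&
                                   res$estimate$defined)
          100 * res$estimate$vaf else NA_real_,
        detected = res$detected & res$supporting_molecules >= 1L)
    }
  }
  detail <- do.call(rbind, detail)
  agg <- lapply(split(detail, factor(detail$expected_vaf_percent,
                                     levels = unique(ladder_percent))),
                function(d) data.frame(
                  expected_vaf_percent = d$expected_vaf_percent[1L],
                  observed_vaf_percent =
                    if (any(!is.na(d$observed_vaf_percent)))
                      mean(d$observed_vaf_percent, na.rm = TRUE)
                    else NA_real_,
                  supporting_families = sum(d$supporting_families),
                  detected = any(d$detected),
                  n_detected_replicates = sum(d$detected)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  attr(out, "replicates") <- detail
  out
}

#' Estimate the limit of detection from a dilution table
#'
#' The LoD is the lowest nonzero expected level detected with at least one
#' variant copy, provided every higher level is also detected. When
#' detection is interrupted (an isolated detection below an undetected
#' level), the lowest level above which detection is uninterrupted is
#' returned with a warning.
#'
#' @param table Dilution table from [run_dilution_series()] (columns
#'   `expected_vaf_percent`, `detected`).
#' @return LoD in percent VAF, or NA (with a warning) when no level is
#'   detected.
#' @export
estimate_lod <- function(table) {
  tb <- table[table$expected_vaf_percent > 0, , drop = FALSE]
  if (nrow(tb) == 0L) stop("table contains no nonzero level", call. = FALSE)
  tb <- tb[order(tb$expected_vaf_percent), , drop = FALSE]
  if (!any(tb$detected)) {
    warning("no level detected; LoD undefined")
    return(NA_real_)
  }
  undet <- which(!tb$detected)
  if (length(undet) == 0L) return(tb$expected_vaf_percent[1L])
  lod_idx <- max(undet) + 1L
  if (lod_idx > nrow(tb)) {
    warning("no uninterrupted detection regime; LoD undefined")
    return(NA_real_)
  }
  if (any(tb$detected[seq_len(max(undet))]))
    warning("detection interrupted below the returned LoD; ",
            "reporting the lowest level with uninterrupted detection")
  tb$expected_vaf_percent[lod_idx]
}

#' Estimate the limit of blank from wild-type libraries
#'
#' Simulates variant-negative (VAF 0) libraries and reports the maximum
#' number of unique molecules erroneously supporting the deletion across
#' runs, together with the corresponding percent VAF. Under the default
#' substitution-only error model no junction-spanning alignment can arise,
#' so the expected LoB is 0.
#'
#' @param runs Number of wild-type libraries (>= 1).
#' @param locus,spec,panel,config Simulation inputs; `spec` is the
#'   deletion being screened for (it is not spiked in).
#' @param seed Base seed; one seed per run drawn consecutively.
#' @return List with `max_supporting` (molecules), `percent_vaf`, and the
#'   per-run counts `per_run`.
#' @export
estimate_lob <- function(runs, locus, spec, panel, config,
                         seed = config$seed) {
  if (runs < 1) stop("runs must be >= 1", call. = FALSE)
  canon <- canonicalize_junction(
    list(breakpoint1 = spec$start, breakpoint2 = spec$end), locus)
  per_run <- integer(runs)
  pct <- numeric(runs)
  for (i in seq_len(runs)) {
    cfg <- config
    cfg$vaf <- 0
    cfg$seed <- as.integer(seed + i)
    rps <- simulate_library(locus, spec, panel, cfg)
    rps <- mark_duplicates(rps)
    cand <- canonicalize_candidates(enumerate_candidates(rps), locus)
    hit <- cand$breakpoint1 == canon$breakpoint1 &
      cand$breakpoint2 == canon$breakpoint2
    per_run[i] <- if (any(hit)) cand$support[hit][1L] else 0L
    if (per_run[i] > 0L) {
      est <- quantify_vaf(rps, canon, locus)
      pct[i] <- if (est$defined) 100 * est$vaf else 0
    }
  }
  list(max_supporting = max(per_run),
       percent_vaf = max(pct),
       per_run = per_run)
}

#' Linearity of observed versus expected VAF
#'
#' Ordinary least squares of observed on expected percent VAF over the
#' dilution levels with a defined observed estimate.
#'
#' @param table Dilution table with `expected_vaf_percent` and
#'   `observed_vaf_percent`.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
linearity <- function(table) {
  tb <- table[!is.na(table$observed_vaf_percent), , drop = FALSE]
  if (nrow(tb) < 3L)
    stop("need at least 3 levels with a defined observed VAF", call. = FALSE)
  fit <- stats::lm(observed_vaf_percent ~ expected_vaf_percent, data = tb)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       n = nrow(tb))
}

#' Build a confusion table of paired method calls
#'
#' @param reference Logical vector: positive by the reference method.
#' @param alternative Logical vector: positive by the method under test.
#' @return A `method_comparison` object with counts `tp`, `fn`, `tn`,
#'   `fp`.
#' @export
method_comparison <- function(reference, alternative) {
  stopifnot(length(reference) == length(alternative))
  structure(
    list(tp = sum(reference & alternative),
         fn = sum(reference & !alternative),
         tn = sum(!reference & !alternative),
         fp = sum(!reference & alternative)),
    class = "method_comparison"
  )
}

#' Sensitivity and specificity against a reference method
#'
#' Sensitivity is the fraction of reference-positive samples classified
#' positive by the alternative method, `TP / (TP + FN)`; specificity is
#' `TN / (TN + FP)`. An empty margin leaves the corresponding metric
#' undefined (NA), not zero.
#'
#' @param cmp A [method_comparison()] (or list with `tp`, `fn`, `tn`,
#'   `fp`).
#' @return List with `sensitivity` and `specificity`.
#' @examples
#' sensitivity_specificity(list(tp = 10, fn = 7, tn = 6, fp = 0))
#' @export
sensitivity_specificity <- function(cmp) {
  pos <- cmp$tp + cmp$fn
  neg <- cmp$tn + cmp$fp
  list(sensitivity = if (pos > 0) cmp$tp / pos else NA_real_,
       specificity = if (neg > 0) cmp$tn / neg else NA_real_)
}
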