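fixture_call <- list(breakpoint1 = 700L, breakpoint2 = 1248L)

pair_geom <- function(id, r1segs, r2segs, r1strand = "+") {
  list(id = id, umi = "AAAA",
       reads = list(list(read = 1L, strand = r1strand, segs = r1segs),
                    list(read = 2L, strand = if (r1strand == "+") "-" else "+",
                         segs = r2segs)))
}

geometry_locus <- function() {
  spec <- deletion_spec(700, 1248)
  install_microhomology(make_reference(8, 2000), spec)
}

test_that("breakpoint assignment and support follow the read-2 rules", {
  loc <- geometry_locus()
  rps <- manual_rps(loc, list(
    # mutant: read 1 on left flank (100 bp), read 2 split with 60 bp distal
    pair_geom("mut1", list(c(600L, 700L)),
              list(c(640L, 700L), c(1248L, 1308L))),
    # wild type: read 2 fully inside the deleted region
    pair_geom("wt1", list(c(600L, 700L)), list(c(700L, 810L))),
    # read 2 reaches the distal flank by only 18 bp: below the seed length
    pair_geom("short1", list(c(600L, 700L)),
              list(c(652L, 700L), c(1248L, 1266L))),
    # contiguous read 2 crossing the whole deleted region into the far flank
    pair_geom("cross1", list(c(630L, 700L)), list(c(680L, 1290L))),
    # breakpoint 2 mutant from the minus-strand primer
    pair_geom("mut2", list(c(1248L, 1348L)),
              list(c(648L, 700L), c(1248L, 1306L)), r1strand = "-"),
    # read 1 overlap of the flank below 19 bp: uninformative
    pair_geom("thin1", list(c(682L, 700L)), list(c(700L, 800L)))))
  cls <- classify_pairs(rps, fixture_call, loc)
  got <- setNames(paste(cls$breakpoint, cls$class), cls$pair_id)
  expect_equal(got[["mut1"]], "1 supporting")
  expect_equal(got[["wt1"]], "1 non_supporting")
  expect_equal(got[["short1"]], "1 uninformative")
  expect_equal(got[["cross1"]], "1 non_supporting")
  expect_equal(got[["mut2"]], "2 supporting")
  expect_equal(got[["thin1"]], "NA uninformative")

  one <- classify_pair(rps, "mut1", fixture_call, loc)
  expect_equal(one$breakpoint, 1L)
  expect_equal(one$class, "supporting")
})

test_that("read 1 spanning the junction is assigned by its 5' flank", {
  loc <- geometry_locus()
  rps <- manual_rps(loc, list(
    pair_geom("span1", list(c(620L, 700L), c(1248L, 1290L)),
              list(c(650L, 700L), c(1248L, 1310L)))))
  cls <- classify_pairs(rps, fixture_call, loc)
  expect_equal(cls$breakpoint, 1L)   # 5' end at 620, left flank
  expect_equal(as.character(cls$class), "supporting")
})

test_that("per-breakpoint VAF follows s/t with undefined zero-depth", {
  expect_equal(breakpoint_vaf(0, 10)$vaf, 0)
  expect_equal(breakpoint_vaf(10, 0)$vaf, 1)
  e <- breakpoint_vaf(3, 7)
  expect_equal(e$vaf, 0.3)
  expect_equal(e$t, 10L)
  expect_false(breakpoint_vaf(0, 0)$defined)
  expect_error(breakpoint_vaf(-1, 5), "non-negative")
})

test_that("combined VAF is the depth-weighted average of Eq-style counts", {
  est <- combined_vaf(breakpoint_vaf(3, 7), breakpoint_vaf(1, 9))
  expect_equal(c(est$w1, est$w2), c(0.5, 0.5))
  expect_equal(est$vaf, 0.2)

  est2 <- combined_vaf(breakpoint_vaf(2, 2), breakpoint_vaf(3, 9))
  expect_equal(c(est2$w1, est2$w2), c(0.25, 0.75))
  expect_equal(est2$vaf, 0.3125)

  # empty breakpoint gets zero weight
  est3 <- combined_vaf(breakpoint_vaf(5, 5), breakpoint_vaf(0, 0))
  expect_equal(est3$vaf, 0.5)
  expect_equal(est3$w2, 0)
  expect_false(combined_vaf(breakpoint_vaf(0, 0),
                            breakpoint_vaf(0, 0))$defined)
})

test_that("combined VAF stays within the per-breakpoint range", {
  set.seed(99)
  for (i in 1:50) {
    s1 <- rpois(1, 5); n1 <- rpois(1, 10)
    s2 <- rpois(1, 3); n2 <- rpois(1, 12)
    if (s1 + n1 == 0 && s2 + n2 == 0) next
    e1 <- breakpoint_vaf(s1, n1); e2 <- breakpoint_vaf(s2, n2)
    est <- combined_vaf(e1, e2)
    vs <- c(e1$vaf, e2$vaf)
    vs <- vs[!is.na(vs)]
    expect_gte(est$vaf + 1e-12, min(vs))
    expect_lte(est$vaf - 1e-12, max(vs))
    if (e1$t == e2$t && e1$t > 0)
      expect_equal(est$vaf, mean(vs))
  }
})

test_that("each unique pair informs at most one breakpoint", {
  fx <- default_locus_spec(seed = 12L)
  cfg <- library_config(vaf = 0.3, target_umi_depth = 150, seed = 12)
  rps <- mark_duplicates(simulate_library(fx$locus, fx$spec, fx$panel, cfg))
  call <- call_deletion(rps)
  cls <- classify_pairs(rps, call)
  expect_false(any(duplicated(cls$pair_id)))
  tab <- table(cls$breakpoint, useNA = "ifany")
  est <- quantify_vaf(rps, call)
  expect_equal(est$evidence1$t + est$evidence2$t,
               sum(cls$class != "uninformative"))
})

test_that("pileup VAF counts alt molecules at one position", {
  fx <- default_locus_spec()
  snv_pos <- 700L   # inside the plus-strand primers' fragment footprint
  ref_base <- substr(fx$locus$sequence, snv_pos + 1L, snv_pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  cfg <- library_config(vaf = 0, target_umi_depth = 100, seed = 6,
                        substitution_error_rate = 0)
  # wild-type library: no alt support
  rps0 <- mark_duplicates(simulate_library(fx$locus, NULL, fx$panel, cfg))
  v0 <- snv_pileup_vaf(rps0, fx$locus, snv_pos, alt)
  if (!is.na(v0)) expect_equal(v0, 0)
  # spiked SNV at 5%
  cfg5 <- library_config(vaf = 0.05, target_umi_depth = 400, seed = 6,
                         substitution_error_rate = 0)
  rps5 <- mark_duplicates(simulate_library(
    fx$locus, NULL, fx$panel, cfg5, snv = list(pos = snv_pos, alt = alt)))
  v5 <- snv_pileup_vaf(rps5, fx$locus, snv_pos, alt)
  keep <- rps5$pairs$pair_id[!rps5$pairs$duplicate_flag]
  cov <- rps5$segments$pair_id %in% keep &
    rps5$segments$ref_start <= snv_pos & rps5$segments$ref_end > snv_pos
  depth <- length(unique(rps5$segments$pair_id[cov]))
  expect_lt(abs(v5 - 0.05), 3 * sqrt(0.05 * 0.95 / depth) + 1e-9)
  expect_error(snv_pileup_vaf(rps5, fx$locus, snv_pos, "N"), "A/C/G/T")
})
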