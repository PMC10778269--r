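split_pair <- function(id, segs1, segs2 = NULL, strand1 = "+",
                       umi = "AAAA") {
  reads <- list(list(read = 1L, strand = strand1, segs = segs1))
  if (!is.null(segs2))
    reads <- c(reads, list(list(read = 2L,
                                strand = if (strand1 == "+") "-" else "+",
                                segs = segs2)))
  list(id = id, umi = umi, reads = reads)
}

test_that("inter-segment intervals become candidates with tallied support", {
  loc <- make_reference(1, 2000)
  rps <- manual_rps(loc, list(
    split_pair("c1", list(c(0L, 70L), c(618L, 698L)))))
  cand <- enumerate_candidates(rps)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$breakpoint1, 70L)
  expect_equal(cand$breakpoint2, 618L)
  expect_equal(cand$length, 548L)
  expect_equal(cand$support, 1L)

  # no split reads -> no candidates
  none <- enumerate_candidates(manual_rps(loc, list(
    split_pair("c2", list(c(0L, 150L))))))
  expect_equal(nrow(none), 0L)
})

test_that("distinct unlinked placements stay distinct; pairs count once", {
  loc <- make_reference(4, 2000)
  # force non-equivalence of the two placements
  specs <- c(
    lapply(1:5, function(i) split_pair(sprintf("d%02d", i),
                                       list(c(0L, 70L), c(618L, 698L)))),
    lapply(6:8, function(i) split_pair(sprintf("d%02d", i),
                                       list(c(0L, 71L), c(619L, 698L)))))
  rps <- manual_rps(loc, specs)
  cand <- enumerate_candidates(rps)
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$support[cand$breakpoint1 == 70L], 5L)
  expect_equal(cand$support[cand$breakpoint1 == 71L], 3L)

  # a pair whose read 1 and read 2 both span the junction supports it once
  both <- manual_rps(loc, list(
    split_pair("e1", list(c(600L, 700L), c(1248L, 1300L)),
               list(c(650L, 700L), c(1248L, 1320L)))))
  expect_equal(enumerate_candidates(both)$support, 1L)
  expect_equal(enumerate_candidates(both)$support_reads, 2L)
})

test_that("microhomology-equivalent candidates merge to one canonical call", {
  spec <- deletion_spec(73, 621, microhomology_len = 3)
  loc <- install_microhomology(make_reference(5, 2000), spec)
  # raw placement (70, 618) shifts right-most to (73, 621)
  cc <- canonicalize_junction(list(breakpoint1 = 70L, breakpoint2 = 618L),
                              loc)
  expect_equal(c(cc$breakpoint1, cc$breakpoint2), c(73L, 621L))
  expect_equal(cc$breakpoint1 - 70L, 3L)
  expect_equal(unname(bf_canonical(loc, 70L, 618L)), c(73L, 621L))
  # identity when no microhomology links the breakpoints
  plain <- deletion_spec(900, 1100)
  loc2 <- install_microhomology(make_reference(5, 2000), plain)
  cc2 <- canonicalize_junction(list(breakpoint1 = 900L,
                                    breakpoint2 = 1100L), loc2)
  expect_equal(c(cc2$breakpoint1, cc2$breakpoint2), c(900L, 1100L))
  expect_error(canonicalize_junction(list(breakpoint1 = -1L,
                                          breakpoint2 = 50L), loc),
               "bounds")

  spec2 <- deletion_spec(72, 620, microhomology_len = 2)
  loc3 <- install_microhomology(make_reference(6, 2000), spec2)
  rps <- manual_rps(loc3, list(
    split_pair("m1", list(c(0L, 70L), c(618L, 700L))),
    split_pair("m2", list(c(0L, 72L), c(620L, 700L)), strand1 = "+")))
  call <- call_deletion(rps, loc3)
  expect_equal(call$breakpoint1, 72L)
  expect_equal(call$breakpoint2, 620L)
  expect_equal(call$supporting_molecules, 2L)
})

test_that("top selection applies the deterministic tie-break", {
  cand <- data.frame(breakpoint1 = c(100L, 300L),
                     breakpoint2 = c(200L, 400L),
                     length = c(100L, 100L), support = c(5L, 3L),
                     support_reads = c(5L, 3L))
  expect_equal(select_top(cand)$breakpoint1, 100L)
  expect_null(select_top(cand[0, ]))

  tie <- data.frame(breakpoint1 = c(300L, 100L),
                    breakpoint2 = c(400L, 200L),
                    length = c(100L, 100L), support = c(4L, 4L),
                    support_reads = c(4L, 4L))
  for (perm in list(1:2, 2:1))
    expect_equal(select_top(tie[perm, ])$breakpoint1, 100L)
})

test_that("call is independent of input pair order", {
  fx <- default_locus_spec(seed = 31L, mh = 2L)
  cfg <- library_config(vaf = 0.4, target_umi_depth = 30, seed = 31)
  rps <- mark_duplicates(simulate_library(fx$locus, fx$spec, fx$panel, cfg))
  ref_call <- call_deletion(rps)
  for (s in 1:3) {
    set.seed(s)
    perm <- sample(nrow(rps$pairs))
    shuffled <- rps
    shuffled$pairs <- rps$pairs[perm, ]
    seg_perm <- order(match(rps$segments$pair_id, rps$pairs$pair_id[perm]))
    shuffled$segments <- rps$segments[seg_perm, ]
    pc <- call_deletion(shuffled)
    expect_equal(pc$breakpoint1, ref_call$breakpoint1)
    expect_equal(pc$supporting_molecules, ref_call$supporting_molecules)
  }
})

test_that("caller matches the exhaustive brute-force oracle on small sets", {
  for (s in 1:6) {
    fx <- default_locus_spec(seed = 40L + s, mh = (s %% 4))
    cfg <- library_config(input_mass_ng = 0.2, vaf = 0.4,
                          target_umi_depth = 10, seed = 40L + s,
                          duplicate_rate = 1.5)
    rps <- mark_duplicates(simulate_library(fx$locus, fx$spec, fx$panel,
                                            cfg))
    expect_lte(sum(!rps$pairs$duplicate_flag), 50L)
    call <- call_deletion(rps)
    oracle <- bf_top_call(rps, fx$locus)
    if (is.null(oracle)) {
      expect_null(call)
    } else {
      expect_equal(call$breakpoint1, oracle$b1)
      expect_equal(call$breakpoint2, oracle$b2)
      expect_equal(call$supporting_molecules, oracle$support)
    }
  }
})

test_that("VCF emission round-trips through a standard VCF reader", {
  skip_if_not_installed("VariantAnnotation")
  fx <- default_locus_spec()
  cfg <- library_config(vaf = 0.5, target_umi_depth = 50, seed = 3)
  rps <- mark_duplicates(simulate_library(fx$locus, fx$spec, fx$panel, cfg))
  call <- call_deletion(rps)
  est <- quantify_vaf(rps, call)
  path <- tempfile(fileext = ".vcf")
  write_vcf(call, fx$locus, path, vaf = est$vaf)
  v <- VariantAnnotation::readVcf(path)
  expect_equal(unname(BiocGenerics::start(v)[1]), call$breakpoint1)
  info <- VariantAnnotation::info(v)
  expect_equal(info$END[1], call$breakpoint2)
  expect_equal(info$SVLEN[1], -548L)
  expect_equal(info$SUPPORT[1], call$supporting_molecules)
  expect_equal(info$VAF[1], est$vaf, tolerance = 1e-5)
})
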