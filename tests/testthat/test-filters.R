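test_that("consensus keeps exactly the PASS-in-both intersection", {
  a_pass <- do.call(rbind, lapply(1:10, function(i) {
    make_variant(pos = 100L + i, filter_status = if (i <= 7) "PASS" else "LowQual")
  }))
  # caller B shares positions 101..108; PASS at 101..105 and 108
  b <- do.call(rbind, lapply(1:8, function(i) {
    make_variant(pos = 100L + i, caller = "callerB",
                 filter_status = if (i <= 5 || i == 8) "PASS" else "t_lod")
  }))
  cons <- consensus_snvs(a_pass, b)
  # oracle: set intersection of PASS keys
  oracle <- intersect(
    variant_key(a_pass$chrom, a_pass$pos, a_pass$ref, a_pass$alt)[a_pass$filter_status == "PASS"],
    variant_key(b$chrom, b$pos, b$ref, b$alt)[b$filter_status == "PASS"]
  )
  expect_setequal(variant_key(cons$chrom, cons$pos, cons$ref, cons$alt), oracle)
  expect_equal(nrow(cons), 5L)
  expect_true(all(cons$caller == "callerA"))  # evidence from caller A
  # PASS in A but not B is discarded
  expect_false(106L %in% cons$pos)
})

test_that("duplicate keys within one caller are an error", {
  dup <- rbind(make_variant(pos = 100L), make_variant(pos = 100L))
  expect_error(consensus_snvs(dup, make_variant(pos = 100L)), "duplicate")
})

test_that("panel of normals applies depth, fraction, and recurrence rules", {
  pile <- data.frame(
    normal_id = c("N1", "N2", "N3", "N4", "N5", "N6", "N7", "N8", "N9"),
    chrom = "chr1",
    pos = c(10L, 20L, 20L, 30L, 30L, 30L, 30L, 30L, 40L),
    ref = "C", alt = "T",
    depth = c(9L, 50L, 50L, 100L, 100L, 100L, 100L, 100L, 12L),
    alt_count_q20 = c(2L, 3L, 3L, 4L, 4L, 4L, 4L, 4L, 2L),
    stringsAsFactors = FALSE
  )
  pon <- build_pon(pile)
  # pos 10: depth 9 < 10, the single normal is ignored -> not blacklisted
  expect_false("chr1:10:C:T" %in% pon$blacklist)
  # pos 20: fraction 0.06 in exactly 2 normals at depth >= 10 -> blacklisted
  expect_true("chr1:20:C:T" %in% pon$blacklist)
  # pos 30: fraction 0.04 in 5 normals -> below 5%, not blacklisted
  expect_false("chr1:30:C:T" %in% pon$blacklist)
  # pos 40: 1 qualifying normal only
  expect_false("chr1:40:C:T" %in% pon$blacklist)
})

test_that("PoN growth is monotone in the normal panel", {
  withr::with_seed(42, {
    base <- data.frame(
      normal_id = rep(sprintf("N%d", 1:6), each = 10),
      chrom = "chr1", pos = rep(1:10 * 100L, 6), ref = "C", alt = "A",
      depth = sample(5:60, 60, replace = TRUE),
      stringsAsFactors = FALSE
    )
    base$alt_count_q20 <- rbinom(60, base$depth, 0.06)
    for (k in 2:5) {
      smaller <- build_pon(base[base$normal_id %in% sprintf("N%d", 1:k), ])
      bigger <- build_pon(base[base$normal_id %in% sprintf("N%d", 1:(k + 1)), ])
      expect_true(all(smaller$blacklist %in% bigger$blacklist))
    }
  })
})

test_that("COSMIC rescue saves blacklisted sites only with full evidence", {
  pon <- structure(list(blacklist = "chr1:100:C:T"), class = "panel_of_normals")
  rescued <- make_variant(pos = 100L, cosmic_overlap_count = 5,
                          af_1000g = 1e-4, af_exac = 1e-4)
  out <- apply_pon_with_rescue(rescued, pon)
  expect_equal(out$decision, "retained")
  expect_match(out$reasons, "RESCUED_COSMIC")

  # strict > 1 on the COSMIC count
  low_cosmic <- make_variant(pos = 100L, cosmic_overlap_count = 1,
                             af_1000g = 1e-4, af_exac = 1e-4)
  expect_equal(apply_pon_with_rescue(low_cosmic, pon)$decision, "removed")

  # missing population AF fails the conjunction (no observed evidence)
  no_af <- make_variant(pos = 100L, cosmic_overlap_count = 5, af_1000g = 1e-4)
  expect_equal(apply_pon_with_rescue(no_af, pon)$decision, "removed")

  # boundary: AF exactly 0.005 still rescues (inclusive <=)
  at_af <- make_variant(pos = 100L, cosmic_overlap_count = 2,
                        af_1000g = 0.005, af_exac = 0.005)
  expect_equal(apply_pon_with_rescue(at_af, pon)$decision, "retained")

  # non-blacklisted variant with no annotations passes through
  clean <- make_variant(pos = 999L)
  out2 <- apply_pon_with_rescue(clean, pon)
  expect_equal(out2$decision, "retained")
  expect_equal(out2$reasons, "")
})

test_that("gate mode demands the COSMIC criteria of every variant", {
  pon <- structure(list(blacklist = character()), class = "panel_of_normals")
  cfg <- run_config(cosmic_mode = "gate")
  v <- rbind(
    make_variant(pos = 1L, cosmic_overlap_count = 5, af_1000g = 1e-4, af_exac = 1e-4),
    make_variant(pos = 2L)
  )
  out <- apply_pon_with_rescue(v, pon, cfg)
  expect_equal(out$decision, c("retained", "removed"))
})

test_that("indel rules use inclusive boundaries and record every failure", {
  mask <- genomic_mask("chr1", 1000L, 2000L)
  calls <- rbind(
    make_variant(pos = 10L, ref = "AT", alt = "A", tumor_depth = 80L,
                 tumor_alt_count = 4L, vaf = 0.05),             # boundary pass
    make_variant(pos = 20L, ref = "AT", alt = "A", tumor_alt_count = 3L),  # low alt
    make_variant(pos = 30L, ref = "AT", alt = "A", tumor_alt_count = 20L,
                 normal_alt_count = 1L),                        # normal alt
    make_variant(pos = 40L, ref = "AT", alt = "A", tumor_depth = 200L,
                 tumor_alt_count = 8L),                         # vaf 0.04
    make_variant(pos = 1500L, ref = "AT", alt = "A", tumor_alt_count = 20L)  # repeat
  )
  out <- filter_indels(calls, mask)
  expect_equal(out$decision,
               c("retained", "removed", "removed", "removed", "removed"))
  expect_equal(out$reasons[2], "LOW_ALT")
  expect_equal(out$reasons[3], "NORMAL_ALT")
  expect_equal(out$reasons[4], "LOW_VAF")
  expect_equal(out$reasons[5], "REPEAT_REGION")
  # removed => at least one reason; retained => none
  expect_true(all(nzchar(out$reasons[out$decision == "removed"])))
  expect_true(all(!nzchar(out$reasons[out$decision == "retained"])))
})

test_that("germline sets and the pseudo-PoN remove known keys", {
  calls <- rbind(
    make_variant(pos = 10L, ref = "AT", alt = "A", tumor_alt_count = 20L),
    make_variant(pos = 20L, ref = "AT", alt = "A", tumor_alt_count = 20L)
  )
  germ <- variant_key("chr1", 10L, "AT", "A")
  ppon <- build_indel_pseudo_pon(data.frame(
    sample_id = c("Sa", "Sb"), chrom = "chr1", pos = 20L, ref = "AT", alt = "A",
    filter_status = c("HighVafNormal", "HighAltCountNormal"),
    stringsAsFactors = FALSE
  ))
  out <- filter_indels(calls, known_germline = germ, pseudo_pon = ppon)
  expect_equal(out$reasons, c("KNOWN_GERMLINE", "PSEUDO_PON"))
})

test_that("pseudo-PoN counts only the two qualifying statuses in >= 2 samples", {
  one_qual <- data.frame(
    sample_id = c("Sa", "Sb"), chrom = "chr1", pos = 5L, ref = "AT", alt = "A",
    filter_status = c("HighVafNormal", "LowCoverage"), stringsAsFactors = FALSE
  )
  expect_equal(length(build_indel_pseudo_pon(one_qual)$blacklist), 0L)
  # same sample twice does not count as two samples
  same_sample <- data.frame(
    sample_id = c("Sa", "Sa"), chrom = "chr1", pos = 5L, ref = "AT", alt = "A",
    filter_status = c("HighVafNormal", "HighAltCountNormal"),
    stringsAsFactors = FALSE
  )
  expect_equal(length(build_indel_pseudo_pon(same_sample)$blacklist), 0L)
  expect_equal(length(build_indel_pseudo_pon(one_qual[0, ])$blacklist), 0L)
})

test_that("germline deleteriousness boundaries match the rule set", {
  v <- rbind(
    make_variant(pos = 1L, af_exac = 0.05, impact = "HIGH"),       # discarded
    make_variant(pos = 2L, impact = "HIGH", af_exac = 0.001),      # deleterious
    make_variant(pos = 3L, consequence = "missense_variant", cadd_score = 25,
                 af_exac = 0.001),                                 # tolerated
    make_variant(pos = 4L, consequence = "missense_variant", cadd_score = 25.1,
                 af_exac = 0.001),                                 # deleterious
    make_variant(pos = 5L, impact = "HIGH"),                       # missing AF: kept
    make_variant(pos = 6L, consequence = "synonymous_variant", af_exac = 0.001)
  )
  out <- classify_germline(v)
  expect_equal(out$germline_status,
               c("discarded", "deleterious", "tolerated", "deleterious",
                 "deleterious", "tolerated"))
})

test_that("SMG filters cap indels per gene and require > 2 carriers", {
  tab <- data.frame(
    sample_id = c("S1", "S1", "S1", "S2", "S3", "S4", "S5"),
    gene = c("X", "X", "X", "X", "X", "Y", "Y"),
    chrom = "chr1",
    pos = c(300L, 100L, 200L, 50L, 60L, 70L, 80L),
    variant_class = c("indel", "indel", "indel", "SNV", "SNV", "SNV", "SNV"),
    silent = FALSE, stringsAsFactors = FALSE
  )
  res <- smg_filters(tab, candidate_genes = c("X", "Y"))
  s1x <- res$mutations[res$mutations$sample_id == "S1", ]
  expect_equal(nrow(s1x), 1L)
  expect_equal(s1x$pos, 100L)  # deterministic keep: lowest coordinate
  # X has 3 distinct carriers (> 2), Y only 2
  expect_equal(res$eligible_genes, "X")

  empty <- smg_filters(tab[0, ], candidate_genes = "X")
  expect_equal(nrow(empty$mutations), 0L)
  expect_equal(empty$eligible_genes, character())
})
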