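test_that("operon extraction handles both strands and reports truth sequence", {
  gm <- make_reference_operon("NCIB3610", seed = 4, strand = "-")
  op <- extract_comQXPA(gm)
  expect_true(op$complete)
  expect_identical(op$comP_cds, gm$truth$comP_cds)
  # the extracted operon equals the reverse complement of the embedded span
  feats <- as.data.frame(gm$features)
  span <- substr(gm$contigs[[1]], min(feats$start), max(feats$end))
  expect_identical(op$operon_seq, quorumcomp:::revcomp(span))
})

test_that("missing and fragmented operons are flagged, not fatal", {
  g <- make_reference_operon("NCIB3610", seed = 4)
  g_noQ <- g
  g_noQ$features <- g$features[g$features$gene != "comQ"]
  # drop gene symbols so the similarity fallback cannot re-find comQ
  op <- extract_comQXPA(g_noQ)
  expect_true("comQ missing" %in% op$flags)
  expect_false(op$complete)
  expect_identical(op$comP_cds, g$truth$comP_cds)

  # move comA onto a second contig: fragmented but comP still analysed
  g_frag <- g
  g_frag$contigs <- c(g$contigs,
                      contig_2 = quorumcomp:::feature_seq(
                        g, quorumcomp:::find_feature(g, "comA")))
  keep <- g$features$gene != "comA"
  extra <- quorumcomp:::cds_feature("contig_2", 1,
                                    nchar(g_frag$contigs[["contig_2"]]),
                                    "+", "comA", "comA protein", "comA_1")
  g_frag$features <- suppressWarnings(c(g$features[keep], extra))
  op2 <- extract_comQXPA(g_frag)
  expect_true("fragmented" %in% op2$flags)
  expect_identical(op2$comP_cds, g$truth$comP_cds)
  expect_identical(classify_comP(op2)$status, "intact")
})

test_that("gene identification falls back to protein similarity", {
  g <- make_reference_operon("NCIB3610", seed = 9)
  g$features$gene <- NA_character_  # annotation-name drift
  op <- extract_comQXPA(g)
  expect_true(op$complete)
  expect_identical(op$comP_cds, g$truth$comP_cds)
})

test_that("classify_comP recovers every mutation class on a small panel", {
  for (cl in names(expected_comp_class)) {
    if (cl == "none") next
    for (seed in 1:5) {
      g <- random_comp_mutant(cl, seed)
      call <- classify_comP(extract_comQXPA(g))
      expect_identical(call$status, "disrupted")
      expect_identical(call$classes, unname(expected_comp_class[[cl]]),
                       label = sprintf("%s seed %d", cl, seed))
    }
  }
  for (seed in 1:5) {
    g <- random_comp_mutant("none", seed)
    expect_identical(classify_comP(extract_comQXPA(g))$status, "intact")
  }
})

test_that("classification is invariant under operon strand", {
  spec <- mutation_spec("frameshift_indel", position = 700, size = 2)
  calls <- lapply(c("+", "-"), function(s) {
    g <- mutate_comP(make_reference_operon("NCIB3610", 13, strand = s), spec)
    classify_comP(extract_comQXPA(g))
  })
  expect_identical(calls[[1]], calls[[2]])
})

test_that("intact alleles of other pherotypes are not miscalled", {
  for (p in c("RO-E-2", "RS-D-2")) {
    call <- classify_comP(extract_comQXPA(make_reference_operon(p, 2)))
    expect_identical(call$status, "intact")
    expect_false(call$hotspot$present)
  }
})

test_that("predicted variant length agrees with an independent translation", {
  refs <- reference_set()
  expect_identical(predicted_variant_length(refs$comP[["NCIB3610"]])$length_aa,
                   nchar(refs$proteins$comP))
  # stop substituted at codon k
  g <- mutate_comP(make_reference_operon("NCIB3610", 1),
                   mutation_spec("nonsense", position = 321))
  cds <- quorumcomp:::feature_seq(g, quorumcomp:::find_feature(g, "comP"))
  expect_identical(predicted_variant_length(cds)$length_aa, 320L)
  # poly-T slip: compare to a direct Biostrings translation oracle
  gs <- mutate_comP(make_reference_operon("NCIB3610", 1),
                    mutation_spec("polyT_slip", size = 1))
  cds <- quorumcomp:::feature_seq(gs, quorumcomp:::find_feature(gs, "comP"))
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, (nchar(cds) %/% 3) * 3)),
    if.fuzzy.codon = "X")))
  oracle <- as.integer(regexpr("*", aa, fixed = TRUE)) - 1L
  pl <- predicted_variant_length(cds)
  expect_identical(pl$length_aa, oracle)
  expect_false(pl$runs_off)
  # no start codon -> undetermined
  expect_true(predicted_variant_length(sub("^ATG", "CCC", cds))$undetermined)
  # no stop before the end -> runs off
  ro <- predicted_variant_length("ATGAAACCCGGG")
  expect_true(ro$runs_off)
  expect_identical(ro$length_aa, 4L)
})

test_that("hotspot detection reports run length and slippage", {
  refs <- reference_set()
  hs <- detect_polyT_hotspot(refs$comP[["NCIB3610"]])
  expect_true(hs$present)
  expect_identical(hs$run_length, 8L)
  expect_false(hs$indel_in_run)
  g <- mutate_comP(make_reference_operon("NCIB3610", 6),
                   mutation_spec("polyT_slip", size = 1))
  hs2 <- detect_polyT_hotspot(
    quorumcomp:::feature_seq(g, quorumcomp:::find_feature(g, "comP")))
  expect_identical(hs2$run_length, 9L)
  expect_true(hs2$indel_in_run)
  expect_false(detect_polyT_hotspot(refs$comP[["RO-E-2"]])$present)
})

test_that("hotspot detection is stable under distant sequence change", {
  # mutations far from the locus leave the call unchanged
  base <- classify_comP(extract_comQXPA(make_reference_operon("NCIB3610", 1)))
  g <- mutate_comP(make_reference_operon("NCIB3610", 77),
                   mutation_spec("nonsense", position = 690))
  hs <- classify_comP(extract_comQXPA(g))$hotspot
  expect_identical(hs, base$hotspot)
})

test_that("pherotype assignment needs both identity and margin", {
  refs <- reference_set()
  self <- assign_pherotype(refs$proteins$comQ[["RO-E-2"]])
  expect_identical(self$label, "RO-E-2")
  expect_equal(self$identity, 100)
  near <- quorumcomp:::translate_cds(quorumcomp:::with_seed(3,
    quorumcomp:::mutate_protein_cds(refs$comQ[["NCIB3610"]], prop = 0.05)))
  call <- assign_pherotype(near)
  expect_identical(call$label, "NCIB3610")
  expect_gt(call$identity, 90)
  far <- quorumcomp:::translate_cds(quorumcomp:::with_seed(3,
    quorumcomp:::mutate_protein_cds(refs$comQ[["NCIB3610"]], prop = 0.4)))
  expect_identical(assign_pherotype(far)$label, "unassigned")
  expect_identical(assign_pherotype(NULL)$label, "undetermined")
})
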