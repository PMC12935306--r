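test_that("reference operon generation is deterministic and pherotype-aware", {
  g1 <- make_reference_operon("NCIB3610", seed = 1)
  g2 <- make_reference_operon("NCIB3610", seed = 1)
  expect_identical(g1$contigs, g2$contigs)
  expect_identical(as.data.frame(g1$features), as.data.frame(g2$features))
  expect_false(identical(g1$contigs,
                         make_reference_operon("NCIB3610", seed = 2)$contigs))
  expect_error(make_reference_operon("not-a-pherotype", seed = 1),
               "RO-E-2")
})

test_that("the NCIB3610-like comP carries one maximal 8-T run; other pherotypes do not", {
  refs <- reference_set()
  cds <- refs$comP[["NCIB3610"]]
  runs <- gregexpr("T+", cds)[[1]]
  lens <- attr(runs, "match.length")
  expect_identical(max(lens), 8L)
  expect_identical(sum(lens == 8L), 1L)
  expect_identical(as.integer(runs[lens == 8L]), refs$hotspot$offset)
  for (p in c("RO-E-2", "RS-D-2")) {
    five_third <- substr(refs$comP[[p]], 1, nchar(refs$comP[[p]]) %/% 3)
    expect_lt(max(attr(gregexpr("T+", five_third)[[1]], "match.length")), 8L)
  }
})

test_that("engineered mutations edit the comP CDS as specified", {
  g <- make_reference_operon("NCIB3610", seed = 1)
  ref_cds <- g$truth$comP_cds

  gn <- mutate_comP(g, mutation_spec("nonsense", position = 200))
  cds <- quorumcomp:::feature_seq(gn, quorumcomp:::find_feature(gn, "comP"))
  expect_identical(substr(cds, 598, 600), "TAA")
  expect_identical(gn$truth$mutations[[1]]$class_label, "nonsense")

  gp <- mutate_comP(g, mutation_spec("polyT_slip", size = 1))
  cds <- quorumcomp:::feature_seq(gp, quorumcomp:::find_feature(gp, "comP"))
  expect_match(cds, "[^T]T{9}[^T]")

  gd <- mutate_comP(g, mutation_spec("inframe_3prime_deletion",
                                     position = 633, size = 17))
  cds <- quorumcomp:::feature_seq(gd, quorumcomp:::find_feature(gd, "comP"))
  expect_identical(nchar(ref_cds) - nchar(cds), 51L)

  gi <- mutate_comP(g, mutation_spec("insertion_element", position = 1000))
  cds <- quorumcomp:::feature_seq(gi, quorumcomp:::find_feature(gi, "comP"))
  expect_identical(nchar(cds) - nchar(ref_cds), 1204L)  # cassette + 4-nt TSD
  expect_gte(nchar(reference_set()$is_cassette), 800L)

  expect_error(mutate_comP(g, mutation_spec("inframe_3prime_deletion",
                                            position = 768, size = 10)),
               "beyond")
})

test_that("edits preserve the reading frame of every other annotated CDS", {
  for (cl in c("nonsense", "inframe_3prime_deletion", "insertion_element",
               "frameshift_indel", "polyT_slip")) {
    g <- random_comp_mutant(cl, seed = 11)
    for (i in seq_along(g$features)) {
      f <- g$features[i]
      len <- nchar(quorumcomp:::feature_seq(g, f))
      if (f$gene %in% "comP" &&
          expected_comp_class[[cl]] == "frameshift") {
        expect_false(len %% 3L == 0L)
      } else if (!f$gene %in% "comP") {
        expect_identical(len %% 3L, 0L)
      }
    }
    # downstream comA sequence is untouched by the comP edit
    comA <- quorumcomp:::feature_seq(g, quorumcomp:::find_feature(g, "comA"))
    expect_identical(comA, reference_set()$comA)
  }
})

test_that("edits on minus-strand genomes give the same CDS as on plus", {
  spec <- mutation_spec("inframe_3prime_deletion", position = 633, size = 17)
  gp <- mutate_comP(make_reference_operon("NCIB3610", 5, strand = "+"), spec)
  gm <- mutate_comP(make_reference_operon("NCIB3610", 5, strand = "-"), spec)
  expect_identical(
    quorumcomp:::feature_seq(gp, quorumcomp:::find_feature(gp, "comP")),
    quorumcomp:::feature_seq(gm, quorumcomp:::find_feature(gm, "comP")))
})

test_that("rapP module generator encodes the requested residue and truncation", {
  refs <- reference_set()
  for (v in c("N", "T")) {
    g <- make_rapP_module(v, "complete", "plasmid", seed = 4)
    rap_feat <- g$features[g$features$ID == "cds_rap"]
    aa <- quorumcomp:::translate_cds(quorumcomp:::feature_seq(g, rap_feat))
    expect_identical(substr(aa, 236, 236), v)
    expect_identical(nchar(aa), nchar(refs$proteins$rapP))
  }
  gt <- make_rapP_module("T", "five_prime_truncated", "chromosome", seed = 4)
  aa <- quorumcomp:::translate_cds(
    quorumcomp:::feature_seq(gt, gt$features[gt$features$ID == "cds_rap"]))
  expect_identical(nchar(aa), nchar(refs$proteins$rapP) - 150L)
  expect_false(substr(aa, 1, 1) == "M")
  ga <- make_rapP_module("T", "absent", "plasmid", seed = 4)
  expect_false(any(ga$features$ID %in% c("cds_rap", "cds_phr")))
  expect_identical(make_rapP_module("N", "complete", "plasmid", 9)$contigs,
                   make_rapP_module("N", "complete", "plasmid", 9)$contigs)
})

test_that("synthetic DE tables record their truth pass-set", {
  de <- make_de_table(200, toxin_ids = sprintf("gene%04d", 1:20), seed = 3)
  # independent brute-force row scan
  manual <- character()
  for (i in seq_len(nrow(de$table))) {
    if (de$table$FDR[i] < 0.01 && abs(de$table$logFC[i]) > 1) {
      manual <- c(manual, de$table$gene[i])
    }
  }
  expect_setequal(de$truth_pass, manual)
  expect_identical(make_de_table(50, seed = 8)$table,
                   make_de_table(50, seed = 8)$table)

  flat <- make_de_table(10, effects = data.frame(
    gene = sprintf("gene%04d", 1:10), logFC = rep(3, 10), FDR = rep(0.5, 10)))
  expect_length(flat$truth_pass, 0L)
  one <- make_de_table(10, effects = data.frame(
    gene = "gene0004", logFC = -1.5, FDR = 0.001))
  expect_true("gene0004" %in% one$truth_pass)
  expect_error(make_de_table(10, effects = data.frame(
    gene = c("gene0001", "gene0001"), logFC = c(1, 2), FDR = c(0.1, 0.1))),
    "duplicate")
})

test_that("rendered image pairs map fields affinely and record truth", {
  f1 <- matrix(0, 40, 40); f1[10:20, 10:20] <- 0.7
  f2 <- matrix(0, 40, 40); f2[25:35, 25:35] <- 0.35
  pair <- render_fluorescence_image(f1, f2, noise_sd = 0, bleed = 0,
                                    offset = 0)
  expect_equal(pair$challenger, f1 * (0.8 / 0.7))
  expect_equal(pair$partner, f2 * (0.8 / 0.7))
  expect_equal(pair$truth$percent_challenger, 100 * sum(f1) / sum(f1 + f2))
  blank <- render_fluorescence_image(f1, matrix(0, 40, 40))
  expect_equal(blank$truth$percent_challenger, 100)
  expect_error(render_fluorescence_image(f1, matrix(0, 10, 10)), "shape")
  expect_error(render_fluorescence_image(matrix(0, 4, 4), matrix(0, 4, 4)),
               "zero")
})

test_that("genomes round-trip through FASTA + GFF3", {
  g <- mutate_comP(make_reference_operon("NCIB3610", 3, strand = "-"),
                   mutation_spec("nonsense", position = 450))
  dir <- withr::local_tempdir()
  paths <- write_genome(g, dir)
  g2 <- read_genome(paths[["fasta"]], paths[["gff3"]])
  expect_identical(g2$contigs, g$contigs)
  expect_identical(
    quorumcomp:::feature_seq(g2, quorumcomp:::find_feature(g2, "comP")),
    quorumcomp:::feature_seq(g, quorumcomp:::find_feature(g, "comP")))
})
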