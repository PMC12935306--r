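#' Packaged reference templates for the quorum-sensing screens
#'
#' Builds (once per session, deterministically) the synthetic reference set
#' used by the genome generators and the screening functions: a comQXPA
#' operon template per pherotype, the ComP reference protein and its
#' conserved-3' boundary, the poly-T mutation hotspot locus, RapP/PhrP
#' references, and an IS-element-like insertion cassette.
#'
#' The NCIB-3610-like comP template carries a single maximal run of eight
#' thymidines in its 5' coding region (the slipped-strand mispairing
#' hotspot); the other pherotype templates share the conserved 3' two thirds
#' of comP but diverge over the 5' third, which removes the poly-T tract.
#' Template coding sequences are synthetic stand-ins generated from a fixed
#' internal seed, not real isolate sequence; real references can be passed to
#' every screening function in the same structure.
#'
#' @param boundary_codon reference ComP codon index where the conserved 3'
#'   region is taken to start (default 300).
#' @return A list of class `reference_set` with elements `pherotypes`,
#'   `comQ` (named character of CDSs per pherotype), `comX`, `comP` (named
#'   per pherotype), `comA`, `proteins` (per-gene reference proteins, ComQ as
#'   a named vector per pherotype), `hotspot` (list: `offset` 1-based nt
#'   offset in the NCIB3610-like comP CDS, `run_length` 8, `flank` nt of
#'   context used for anchoring), `boundary_codon`, `rapP`, `phrP`,
#'   `rap_paralog`, `is_cassette`.
#' @export
reference_set <- function(boundary_codon = 300L) {
  key <- sprintf("refs_%d", boundary_codon)
  if (!is.null(.qc_cache[[key]])) return(.qc_cache[[key]])
  refs <- with_seed(904151L, build_reference_set(boundary_codon))
  .qc_cache[[key]] <- refs
  refs
}

.qc_cache <- new.env(parent = emptyenv())

build_reference_set <- function(boundary_codon) {
  pherotypes <- c("NCIB3610", "RO-E-2", "RS-D-2")

  # ComQ is the pherotype discriminator: one independent template per label.
  comQ <- vapply(pherotypes, function(p) random_cds(299L), character(1))
  comX <- random_cds(55L)
  comA <- random_cds(214L)

  # ComP: 769 codons + stop. Conserved 3' region shared across pherotypes;
  # 5' third divergent. The NCIB3610-like allele carries the 8-T hotspot.
  n_aa <- 769L
  conserved <- substr(random_cds(n_aa), (boundary_codon - 1L) * 3L + 1L, n_aa * 3L + 3L)
  comP <- vapply(pherotypes, function(p) {
    five <- substr(random_cds(n_aa), 1L, (boundary_codon - 1L) * 3L)
    cap_t_runs(paste0(five, conserved))
  }, character(1))

  # Engineer the hotspot into codons 13-15 of the NCIB3610-like template:
  # ...GCC TTT TTT TTA... -> a maximal run of exactly eight T's at nt 37.
  s <- comP[["NCIB3610"]]
  substr(s, 34L, 45L) <- "GCCTTTTTTTTA"
  stopifnot(max_base_run(s) == 8L)
  comP[["NCIB3610"]] <- s
  hotspot <- list(offset = 37L, run_length = 8L, flank = 25L)

  # RapP (381 aa) with asparagine at residue 236 in the signal-responsive
  # reference; PhrP short pro-peptide; a diverged Rap paralog used to test
  # detection specificity (~45% identity to RapP).
  rapP <- random_cds(381L)
  substr(rapP, (236L - 1L) * 3L + 1L, 236L * 3L) <- "AAC"
  phrP <- random_cds(44L)
  rap_paralog <- mutate_protein_cds(rapP, prop = 0.55)

  # IS-element-like cassette: 1200 nt with 20-nt terminal inverted repeats.
  ir <- paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE), collapse = "")
  core <- random_filler(1160L)
  is_cassette <- cap_t_runs(paste0(ir, core, revcomp(ir)))

  refs <- list(
    pherotypes = pherotypes,
    comQ = comQ, comX = comX, comP = comP, comA = comA,
    proteins = list(
      comQ = vapply(comQ, translate_cds, character(1)),
      comX = translate_cds(comX),
      comP = translate_cds(comP[["NCIB3610"]]),
      comA = translate_cds(comA),
      rapP = translate_cds(rapP),
      phrP = translate_cds(phrP)
    ),
    hotspot = hotspot,
    boundary_codon = boundary_codon,
    rapP = rapP, phrP = phrP, rap_paralog = rap_paralog,
    is_cassette = is_cassette
  )
  class(refs) <- "reference_set"
  refs
}

# Substitute a proportion of codons for random different sense codons,
# keeping start and stop; used to build diverged paralogs / near-identical
# test proteins.
mutate_protein_cds <- function(cds, prop) {
  n_aa <- nchar(cds) %/% 3L - 1L
  k <- max(1L, round(prop * (n_aa - 1L)))
  at <- sample(seq(2L, n_aa), k)
  codons <- sense_codons()
  for (i in at) {
    cur <- substr(cds, (i - 1L) * 3L + 1L, i * 3L)
    substr(cds, (i - 1L) * 3L + 1L, i * 3L) <- sample(setdiff(codons, cur), 1L)
  }
  cds
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
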