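#' Detect and classify a rapP-phrP quorum-sensing module
#'
#' Scans every annotated CDS for protein similarity to the reference RapP.
#' A candidate must reach `min_identity` percent identity (local alignment)
#' over at least `min_coverage` of the reference length, which separates
#' rapP from other Rap-family paralogs (which score well below the cutoff).
#' A candidate is `complete` when coverage reaches `complete_coverage` with
#' an intact start codon; `five_prime_truncated` when the missing region is
#' N-terminal and amounts to at least 5% of the reference. phrP is searched
#' among CDS within `phr_window` nt downstream on the same strand at
#' `phr_min_identity` percent identity. Absence is a valid (non-error)
#' result.
#'
#' @param genome a genome object.
#' @param refs a [reference_set()].
#' @param min_identity percent identity cutoff for a rapP candidate (80).
#' @param min_coverage minimum fraction of the reference covered (0.6).
#' @param complete_coverage coverage needed to call the module complete (0.95).
#' @param phr_window downstream search window for phrP, nt (500).
#' @param phr_min_identity percent identity cutoff for phrP (60).
#' @return list of class `rapp_call`: `presence` (`"complete"`,
#'   `"five_prime_truncated"`, `"absent"`), `phrP_downstream`,
#'   `residue_236` (`"N"`, `"T"`, `"other"`, `"undetermined"`, `NA` when
#'   absent), `replicon`, `identity`, `coverage`.
#' @export
detect_rapP_module <- function(genome, refs = reference_set(),
                               min_identity = 80, min_coverage = 0.6,
                               complete_coverage = 0.95, phr_window = 500L,
                               phr_min_identity = 60) {
  ref_aa <- refs$proteins$rapP
  ref_len <- nchar(ref_aa)
  gr <- genome$features
  absent_call <- structure(
    list(presence = "absent", phrP_downstream = NA, residue_236 = NA_character_,
         replicon = NA_character_, identity = NA_real_, coverage = NA_real_),
    class = "rapp_call")
  if (length(gr) == 0L) return(absent_call)

  best <- NULL
  for (i in seq_along(gr)) {
    aa <- translate_cds(feature_seq(genome, gr[i]))
    if (nchar(aa) < 0.2 * ref_len || nchar(aa) > 2 * ref_len) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(aa), Biostrings::AAString(ref_aa),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "local")
    cov <- IRanges::width(Biostrings::subject(aln)@range) / ref_len
    idy <- Biostrings::pid(aln, type = "PID1")
    if (idy >= min_identity && cov >= min_coverage &&
        (is.null(best) || idy * cov > best$idy * best$cov)) {
      best <- list(i = i, aa = aa, idy = idy, cov = cov,
                   ref_from = IRanges::start(Biostrings::subject(aln)@range))
    }
  }
  if (is.null(best)) return(absent_call)

  feat <- gr[best$i]
  n_missing_nterm <- best$ref_from - 1L
  presence <- if (best$cov >= complete_coverage &&
                  substr(best$aa, 1L, 1L) == "M" &&
                  n_missing_nterm < 0.05 * ref_len) {
    "complete"
  } else if (n_missing_nterm >= 0.05 * ref_len) {
    "five_prime_truncated"
  } else {
    "complete"
  }

  # phrP within the downstream window, same contig and strand.
  contig <- as.character(GenomicRanges::seqnames(feat))
  strand <- as.character(GenomicRanges::strand(feat))
  same <- which(as.character(GenomicRanges::seqnames(gr)) == contig &
                  as.character(GenomicRanges::strand(gr)) == strand)
  phr <- FALSE
  for (i in setdiff(same, best$i)) {
    gap <- if (strand == "-") {
      GenomicRanges::start(feat) - GenomicRanges::end(gr[i])
    } else {
      GenomicRanges::start(gr[i]) - GenomicRanges::end(feat)
    }
    if (gap < 0 || gap > phr_window) next
    aa <- translate_cds(feature_seq(genome, gr[i]))
    if (abs(nchar(aa) - nchar(refs$proteins$phrP)) > 30L) next
    if (global_pid(aa, refs$proteins$phrP) >= phr_min_identity) { phr <- TRUE; break }
  }

  structure(list(
    presence = presence,
    phrP_downstream = phr,
    residue_236 = check_residue_236(best$aa, refs),
    replicon = replicon_context(genome, contig),
    identity = best$idy, coverage = best$cov), class = "rapp_call")
}

#' Signal-responsiveness state of RapP residue 236
#'
#' Position 236 is defined in reference RapP numbering via pairwise
#' alignment, not by raw index, so the call is robust to indels elsewhere
#' in the protein. A gap (or no coverage) at the aligned column yields
#' `"undetermined"`.
#'
#' @param rapP_protein query RapP amino-acid sequence (character).
#' @param refs a [reference_set()].
#' @return `"N"`, `"T"`, `"other"` or `"undetermined"`.
#' @export
check_residue_236 <- function(rapP_protein, refs = reference_set()) {
  ref_aa <- refs$proteins$rapP
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(rapP_protein), Biostrings::AAString(ref_aa),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "local")
  ref_off <- IRanges::start(Biostrings::subject(aln)@range) - 1L
  sa <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  ref_pos <- ref_off + cumsum(sa != "-")
  col <- which(sa != "-" & ref_pos == 236L)
  if (length(col) == 0L) return("undetermined")
  res <- pa[col[1L]]
  switch(res, "-" = "undetermined", "N" = "N", "T" = "T", "other")
}

#' Infer the replicon context of a located gene
#'
#' A contig is `plasmid_like` when its name or annotation marks it as a
#' plasmid, or when it is shorter than 20% of the largest contig in an
#' assembly of at most 5 contigs; `chromosomal` when it is the largest
#' contig; otherwise `unknown`.
#'
#' @param genome a genome object.
#' @param contig name of the contig carrying the gene.
#' @return `"plasmid_like"`, `"chromosomal"` or `"unknown"`.
#' @export
replicon_context <- function(genome, contig) {
  lens <- nchar(genome$contigs)
  if (grepl("plasmid|pBS32", contig, ignore.case = TRUE)) return("plasmid_like")
  largest <- names(lens)[which.max(lens)]
  if (contig == largest) return("chromosomal")
  if (length(lens) <= 5L && lens[[contig]] < 0.2 * max(lens)) {
    return("plasmid_like")
  }
  "unknown"
}
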