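#' Locate the comQXPA operon in an annotated genome
#'
#' Finds the comQ, comX, comP and comA coding sequences by annotated gene
#' symbol, falling back to protein similarity against the reference proteins
#' (>= 40% identity with query/reference length ratio >= 0.7) to survive
#' annotation-name drift. The operon nucleotide sequence from the start of
#' comQ to the end of comA is extracted on the operon strand (minus-strand
#' operons are reverse-complemented). Missing or fragmented genes are
#' flagged, not fatal: comP is still analysed whenever its CDS is whole.
#'
#' @param genome a genome object from [read_genome()] or a generator.
#' @param refs a [reference_set()].
#' @return list of class `operon_record`: `genome_id`, `genes` (per-gene
#'   list of `contig`, `start`, `end`, `strand`, or `NULL` when missing),
#'   `flags` (character: `"<gene> missing"`, `"fragmented"`), `complete`
#'   (logical: all four genes syntenic in order Q,X,P,A on one strand),
#'   `operon_seq`, `comP_cds`, `comQ_protein`.
#' @export
extract_comQXPA <- function(genome, refs = reference_set()) {
  gene_names <- c("comQ", "comX", "comP", "comA")
  ref_prot <- list(comQ = refs$proteins$comQ[["NCIB3610"]],
                   comX = refs$proteins$comX,
                   comP = refs$proteins$comP,
                   comA = refs$proteins$comA)
  gr <- genome$features
  ann <- tolower(ifelse(is.na(gr$gene), "", gr$gene))

  located <- stats::setNames(vector("list", 4L), gene_names)
  for (g in gene_names) {
    hit <- which(ann == tolower(g))
    if (length(hit) == 0L) {
      # similarity fallback over unnamed CDS features
      cand <- which(ann == "")
      for (i in cand) {
        aa <- translate_cds(feature_seq(genome, gr[i]))
        rl <- nchar(ref_prot[[g]])
        if (nchar(aa) < 0.7 * rl || nchar(aa) > 1.5 * rl) next
        if (global_pid(aa, ref_prot[[g]]) >= 40) { hit <- i; break }
      }
    }
    if (length(hit) >= 1L) {
      f <- gr[hit[1L]]
      located[[g]] <- list(contig = as.character(GenomicRanges::seqnames(f)),
                           start = GenomicRanges::start(f),
                           end = GenomicRanges::end(f),
                           strand = as.character(GenomicRanges::strand(f)))
    }
  }

  flags <- character()
  for (g in gene_names) {
    if (is.null(located[[g]])) flags <- c(flags, paste(g, "missing"))
  }
  present <- located[!vapply(located, is.null, logical(1))]
  contigs <- unique(vapply(present, `[[`, character(1), "contig"))
  strands <- unique(vapply(present, `[[`, character(1), "strand"))
  syntenic <- length(present) == 4L && length(contigs) == 1L &&
    length(strands) == 1L
  if (length(present) >= 2L && (length(contigs) > 1L || length(strands) > 1L)) {
    flags <- c(flags, "fragmented")
  }
  ordered <- FALSE
  if (syntenic) {
    starts <- vapply(located, `[[`, numeric(1), "start")
    ordered <- if (strands == "+") all(diff(starts) > 0) else all(diff(starts) < 0)
    if (!ordered) flags <- c(flags, "order violated")
  }

  operon_seq <- NA_character_
  if (syntenic && ordered) {
    span <- range(c(vapply(located, `[[`, numeric(1), "start"),
                    vapply(located, `[[`, numeric(1), "end")))
    s <- substr(genome$contigs[[contigs]], span[1], span[2])
    if (strands == "-") s <- revcomp(s)
    operon_seq <- s
  }

  comP_cds <- NULL
  if (!is.null(located$comP)) {
    f <- located$comP
    s <- substr(genome$contigs[[f$contig]], f$start, f$end)
    comP_cds <- if (f$strand == "-") revcomp(s) else s
  }
  comQ_protein <- NULL
  if (!is.null(located$comQ)) {
    f <- located$comQ
    s <- substr(genome$contigs[[f$contig]], f$start, f$end)
    comQ_protein <- translate_cds(if (f$strand == "-") revcomp(s) else s)
  }

  structure(list(genome_id = genome$genome_id, genes = located,
                 flags = flags, complete = syntenic && ordered,
                 operon_seq = operon_seq, comP_cds = comP_cds,
                 comQ_protein = comQ_protein),
            class = "operon_record")
}

# Global nucleotide alignment used for codon-aware comP comparison.
# Penalties favour mismatches over gaps so that the polymorphic 5' region
# aligns gaplessly, while true indels (which are flanked by identity) still
# open gaps.
align_comP <- function(query, ref) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(ref),
    substitutionMatrix = mat, gapOpening = 12, gapExtension = 1,
    type = "global")
}

#' Classify a comP allele as intact or disrupted
#'
#' Codon-aware comparison of the query comP CDS against the reference comP,
#' screening for the four disruption classes: (i) internal nonsense
#' mutations causing premature truncation (a stop codon before 95% of the
#' reference protein length, upstream of any indel); (ii) frameshift-
#' inducing indels (net intra-CDS indel length not divisible by 3, IS-scale
#' insertions excluded); (iii) in-frame deletions (>= 1 codon, length
#' divisible by 3) at or beyond the conserved-3'-region boundary; and (iv)
#' insertion elements (intra-CDS insertions >= `insertion_min` nt). Classes
#' may co-occur; an allele with no class is called intact. Point
#' substitutions are deliberately not called disruptive.
#'
#' @param operon an `operon_record` (or a raw comP CDS character string).
#' @param refs a [reference_set()].
#' @param truncation_frac premature-stop cutoff as a fraction of the
#'   reference protein length (default 0.95).
#' @param insertion_min minimum insertion width (nt) called as an insertion
#'   element (default 100).
#' @param boundary_codon conserved-3'-region boundary; defaults to the
#'   reference set's value.
#' @return list of class `comp_call`: `status` (`"intact"`, `"disrupted"`,
#'   `"undetermined"`), `classes`, `predicted_length_aa`, `runs_off`,
#'   `hotspot` (see [detect_polyT_hotspot()]), `identity`, `reason`.
#' @export
classify_comP <- function(operon, refs = reference_set(),
                          truncation_frac = 0.95, insertion_min = 100L,
                          boundary_codon = refs$boundary_codon) {
  cds <- if (is.character(operon)) operon else operon$comP_cds
  if (is.null(cds) || is.na(cds) || !nzchar(cds)) {
    return(structure(list(status = "undetermined", classes = character(),
                          predicted_length_aa = NA_integer_, runs_off = NA,
                          hotspot = list(present = FALSE, run_length = NA_integer_,
                                         indel_in_run = NA),
                          identity = NA_real_, reason = "comP missing"),
                     class = "comp_call"))
  }
  ref_cds <- refs$comP[["NCIB3610"]]
  ref_aa_len <- nchar(refs$proteins$comP)
  aln <- align_comP(cds, ref_cds)
  ins <- Biostrings::insertion(aln)[[1]]   # query-space inserted ranges
  del <- Biostrings::deletion(aln)[[1]]    # ref-space ranges absent in query

  classes <- character()
  big_ins <- ins[IRanges::width(ins) >= insertion_min]
  if (length(big_ins) > 0L) classes <- c(classes, "insertion_element")
  small_ins <- ins[IRanges::width(ins) < insertion_min]
  net <- sum(IRanges::width(small_ins)) - sum(IRanges::width(del))
  if (net %% 3L != 0L) classes <- c(classes, "frameshift")
  boundary_nt <- (boundary_codon - 1L) * 3L + 1L
  inframe_del <- del[IRanges::width(del) %% 3L == 0L &
                       IRanges::width(del) >= 3L &
                       IRanges::start(del) >= boundary_nt]
  if (length(inframe_del) > 0L) classes <- c(classes, "inframe_3prime_deletion")

  # Nonsense: first stop codon in the query's own frame upstream of the
  # first indel (stops caused by a frameshift are not counted again here).
  first_break <- min(c(IRanges::start(ins), IRanges::start(del),
                       nchar(cds) + 1L))
  prefix_codons <- (first_break - 1L) %/% 3L
  stop_at <- first_stop_codon(substr(cds, 1L, prefix_codons * 3L))
  if (!is.na(stop_at) && stop_at <= floor(truncation_frac * ref_aa_len)) {
    classes <- c(classes, "nonsense")
  }

  pl <- predicted_variant_length(cds, refs)
  structure(list(
    status = if (length(classes) > 0L) "disrupted" else "intact",
    classes = classes,
    predicted_length_aa = pl$length_aa,
    runs_off = pl$runs_off,
    hotspot = detect_polyT_hotspot(cds, refs),
    identity = Biostrings::pid(aln, type = "PID1"),
    reason = NA_character_), class = "comp_call")
}

# 1-based index of the first stop codon in frame 1, or NA.
first_stop_codon <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return(NA_integer_)
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  hit <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Predicted length of the variant ComP protein
#'
#' Translates the variant CDS from its annotated start codon, in the
#' variant's own reading frame (so frameshifts are read through into the
#' shifted frame), up to the first stop codon. The reported length excludes
#' the stop.
#'
#' @param cds comP CDS nucleotide sequence (character).
#' @param refs a [reference_set()] (unused except for interface symmetry).
#' @return list: `length_aa` (integer, `NA` when the start codon is absent),
#'   `runs_off` (`TRUE` when no stop codon is reached before the sequence
#'   end, in which case `length_aa` is the translated span), `undetermined`.
#' @export
predicted_variant_length <- function(cds, refs = reference_set()) {
  if (substr(cds, 1L, 3L) != "ATG") {
    return(list(length_aa = NA_integer_, runs_off = NA, undetermined = TRUE))
  }
  k <- first_stop_codon(cds)
  if (is.na(k)) {
    list(length_aa = nchar(cds) %/% 3L, runs_off = TRUE, undetermined = FALSE)
  } else {
    list(length_aa = k - 1L, runs_off = FALSE, undetermined = FALSE)
  }
}

#' Detect the comP poly-thymidine mutation hotspot
#'
#' Anchors the reference 8-T tract by local alignment of its flanked window
#' against the query comP CDS, then reports the maximal T-run length
#' observed at the locus and whether it differs from the reference run
#' (an indel within the run, the slipped-strand mispairing signature).
#' The hotspot is reported absent when the locus does not align (the 5'
#' region of other pherotypes).
#'
#' @param cds comP CDS nucleotide sequence.
#' @param refs a [reference_set()].
#' @param min_identity,min_coverage local-alignment acceptance thresholds
#'   for the anchor window.
#' @return list: `present`, `run_length`, `indel_in_run`.
#' @export
detect_polyT_hotspot <- function(cds, refs = reference_set(),
                                 min_identity = 85, min_coverage = 0.8) {
  hs <- refs$hotspot
  ref_cds <- refs$comP[["NCIB3610"]]
  win_start <- max(1L, hs$offset - hs$flank)
  win_end <- min(nchar(ref_cds), hs$offset + hs$run_length + hs$flank - 1L)
  window <- substr(ref_cds, win_start, win_end)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(window), Biostrings::DNAString(cds),
    substitutionMatrix = mat, gapOpening = 8, gapExtension = 2,
    type = "local")
  cov <- IRanges::width(Biostrings::pattern(aln)@range) / nchar(window)
  if (cov < min_coverage || Biostrings::pid(aln, type = "PID1") < min_identity) {
    return(list(present = FALSE, run_length = NA_integer_, indel_in_run = NA))
  }
  qr <- Biostrings::subject(aln)@range
  region <- substr(cds, max(1L, IRanges::start(qr) - 2L),
                   min(nchar(cds), IRanges::end(qr) + 2L))
  run <- max_base_run(region, "T")
  list(present = TRUE, run_length = run,
       indel_in_run = run != hs$run_length)
}

#' Assign a ComQ pherotype
#'
#' Global pairwise alignment of the query ComQ protein against each
#' reference ComQ; the best label is assigned when its identity reaches
#' `min_identity` and exceeds the runner-up by at least `min_margin`
#' percentage points.
#'
#' @param comQ_protein query ComQ amino-acid sequence (character).
#' @param refs a [reference_set()].
#' @param min_identity assignment threshold (default 90).
#' @param min_margin required margin over the runner-up (default 5).
#' @return list of class `pherotype_call`: `label` (or `"unassigned"` /
#'   `"undetermined"`), `identity`, `runner_up`.
#' @export
assign_pherotype <- function(comQ_protein, refs = reference_set(),
                             min_identity = 90, min_margin = 5) {
  if (is.null(comQ_protein) || !nzchar(comQ_protein)) {
    return(structure(list(label = "undetermined", identity = NA_real_,
                          runner_up = NA_real_), class = "pherotype_call"))
  }
  ids <- vapply(refs$proteins$comQ, function(r) global_pid(comQ_protein, r),
                numeric(1))
  ord <- order(ids, decreasing = TRUE)
  best <- ids[ord[1L]]
  second <- if (length(ids) > 1L) ids[ord[2L]] else 0
  label <- if (best >= min_identity && best - second >= min_margin) {
    names(ids)[ord[1L]]
  } else {
    "unassigned"
  }
  structure(list(label = label, identity = unname(best),
                 runner_up = unname(second)), class = "pherotype_call")
}
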