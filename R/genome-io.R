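#' Write a genome as FASTA + GFF3
#'
#' @param genome a `synthetic_genome` (or any object with `$contigs` named
#'   character and `$features` GRanges).
#' @param dir output directory (created if needed).
#' @param basename file stem; defaults to the genome id.
#' @return invisibly, a named character vector with elements `fasta`, `gff3`.
#' @export
write_genome <- function(genome, dir, basename = genome$genome_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(basename, ".fasta"))
  gff3 <- file.path(dir, paste0(basename, ".gff3"))
  seqs <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(seqs, fasta)
  gr <- genome$features
  sl <- stats::setNames(nchar(genome$contigs), names(genome$contigs))
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  GenomeInfoDb::seqlengths(gr) <- sl
  suppressWarnings(rtracklayer::export(gr, gff3, format = "gff3"))
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Read a genome from FASTA + GFF3
#'
#' Only CDS (or typeless) features are retained; the `gene` and `product`
#' attributes are preserved when present.
#'
#' @param fasta path to a FASTA file of contigs.
#' @param gff3 path to the matching GFF3 annotation.
#' @param genome_id identifier; defaults to the FASTA file stem.
#' @return a `synthetic_genome`-structured object (with empty `$truth`).
#' @export
read_genome <- function(fasta, gff3,
                        genome_id = sub("\\.[^.]*$", "", basename(fasta))) {
  if (!file.exists(fasta)) stop("FASTA not found: ", fasta, call. = FALSE)
  if (!file.exists(gff3)) stop("GFF3 not found: ", gff3, call. = FALSE)
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                   error = function(e) stop(sprintf("cannot parse FASTA '%s': %s",
                                                    fasta, conditionMessage(e)),
                                            call. = FALSE))
  gr <- tryCatch(rtracklayer::import(gff3),
                 error = function(e) stop(sprintf("cannot parse GFF3 '%s': %s",
                                                  gff3, conditionMessage(e)),
                                          call. = FALSE))
  # FASTA headers may carry descriptions; contig name = first token.
  contigs <- stats::setNames(as.character(seqs),
                             sub("\\s.*$", "", names(seqs)))
  if (!is.null(gr$type)) {
    keep <- as.character(gr$type) %in% c("CDS", "cds")
    if (any(keep)) gr <- gr[keep]
  }
  if (is.null(gr$gene)) gr$gene <- NA_character_
  if (is.null(gr$product)) gr$product <- NA_character_
  if (is.null(gr$ID)) gr$ID <- sprintf("cds_%d", seq_along(gr))
  bad <- !(as.character(GenomicRanges::seqnames(gr)) %in% names(contigs)) |
    GenomicRanges::end(gr) > nchar(contigs)[as.character(GenomicRanges::seqnames(gr))]
  if (any(bad)) {
    stop(sprintf("GFF3 '%s': %d feature(s) lie outside the supplied contigs",
                 gff3, sum(bad)), call. = FALSE)
  }
  new_synthetic_genome(genome_id, contigs, gr, truth = list())
}
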