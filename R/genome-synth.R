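#' Synthetic annotated genomes with known ground truth
#'
#' The generators in this file emulate annotated bacterial genome assemblies
#' (FASTA contigs + CDS features) containing a comQXPA quorum-sensing operon
#' and, optionally, a rapP-phrP module, with engineered mutations of each
#' disruption class. Every generated genome records the exact edits applied
#' (`$truth`), so the screening functions can be validated against a known
#' answer.
#'
#' @name genome-synth
NULL

new_synthetic_genome <- function(genome_id, contigs, features, truth = list()) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  structure(
    list(genome_id = genome_id, contigs = contigs, features = features,
         truth = truth),
    class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %s: %d contig(s) (%s nt), %d feature(s)\n",
              x$genome_id, length(x$contigs),
              paste(nchar(x$contigs), collapse = "+"),
              length(x$features)))
  invisible(x)
}

# One CDS feature row.
cds_feature <- function(contig, start, end, strand, gene, product, id) {
  GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand,
    type = "CDS", ID = id, gene = gene, product = product)
}

# Extract a feature's CDS sequence (reverse-complemented on the minus strand).
feature_seq <- function(genome, feat) {
  s <- substr(genome$contigs[[as.character(GenomicRanges::seqnames(feat))]],
              GenomicRanges::start(feat), GenomicRanges::end(feat))
  if (as.character(GenomicRanges::strand(feat)) == "-") s <- revcomp(s)
  s
}

find_feature <- function(genome, gene) {
  hit <- which(!is.na(genome$features$gene) & genome$features$gene == gene)
  if (length(hit) == 0L) return(NULL)
  genome$features[hit[1L]]
}

#' Generate a reference comQXPA operon genome
#'
#' Builds a single-contig genome carrying a syntenic comQ-comX-comP-comA
#' operon of the requested pherotype template, flanked by random filler
#' sequence at ~43% GC. The NCIB3610-like template's comP contains exactly
#' one maximal run of eight thymidines (the slipped-strand hotspot) at a
#' recorded offset; the other pherotype templates diverge over the 5' third
#' of comP and carry no equivalent tract.
#'
#' @param pherotype_id one of `reference_set()$pherotypes`.
#' @param seed integer seed controlling the filler sequence.
#' @param strand `"+"` or `"-"`: strand on which the operon is placed.
#' @param flank filler length (nt) on each side of the operon.
#' @param refs a [reference_set()].
#' @return A `synthetic_genome` whose `$truth` records the pherotype, the
#'   comP CDS, the hotspot offset, and an (initially empty) mutation list.
#' @export
make_reference_operon <- function(pherotype_id, seed, strand = "+",
                                  flank = 1500L, refs = reference_set()) {
  if (!pherotype_id %in% refs$pherotypes) {
    stop(sprintf("unknown pherotype_id '%s'; valid labels: %s", pherotype_id,
                 paste(refs$pherotypes, collapse = ", ")), call. = FALSE)
  }
  with_seed(seed, {
    spacer <- 40L
    genes <- list(
      comQ = refs$comQ[[pherotype_id]],
      comX = refs$comX,
      comP = refs$comP[[pherotype_id]],
      comA = refs$comA)
    contig <- random_filler(flank)
    feats <- list()
    for (g in names(genes)) {
      start <- nchar(contig) + 1L
      contig <- paste0(contig, genes[[g]])
      feats[[g]] <- c(start = start, end = nchar(contig))
      if (g != "comA") contig <- paste0(contig, random_filler(spacer))
    }
    contig <- paste0(contig, random_filler(flank))
    contig_name <- "contig_1"
    L <- nchar(contig)
    gr <- do.call(c, lapply(names(feats), function(g) {
      st <- feats[[g]][["start"]]; en <- feats[[g]][["end"]]
      if (strand == "-") { st2 <- L - en + 1L; en <- L - feats[[g]][["start"]] + 1L; st <- st2 }
      cds_feature(contig_name, st, en, strand, g,
                  product = paste0(g, " quorum-sensing protein"),
                  id = paste0(g, "_1"))
    }))
    if (strand == "-") contig <- revcomp(contig)
    contigs <- stats::setNames(contig, contig_name)
    truth <- list(
      pherotype = pherotype_id,
      comP_cds = genes$comP,
      hotspot = if (pherotype_id == "NCIB3610") refs$hotspot else NULL,
      mutations = list())
    new_synthetic_genome(
      sprintf("synth_%s_s%d%s", gsub("[^A-Za-z0-9]", "", pherotype_id), seed,
              if (strand == "-") "m" else ""),
      contigs, gr, truth)
  })
}

#' Describe one engineered comP mutation
#'
#' @param class_label one of `"nonsense"`, `"frameshift_indel"`,
#'   `"inframe_3prime_deletion"`, `"insertion_element"`, `"polyT_slip"`,
#'   `"none"`.
#' @param position 1-based codon offset (nonsense, in-frame deletion) or
#'   nucleotide offset (frameshift, insertion element) in the reference comP
#'   CDS; ignored for `polyT_slip` (anchored at the hotspot) and `"none"`.
#' @param size edit size: nt for indels/insertions, codons for in-frame
#'   deletions, inserted T count for `polyT_slip`.
#' @param op `"insert"` or `"delete"` for `frameshift_indel`.
#' @param seed seed for random inserted bases.
#' @return list of class `mutation_spec`.
#' @export
mutation_spec <- function(class_label, position = NA_integer_,
                          size = NA_integer_, op = "insert", seed = 1L) {
  classes <- c("nonsense", "frameshift_indel", "inframe_3prime_deletion",
               "insertion_element", "polyT_slip", "none")
  class_label <- match.arg(class_label, classes)
  if (class_label != "none") {
    if (class_label %in% c("frameshift_indel", "inframe_3prime_deletion",
                           "polyT_slip") && (is.na(size) || size <= 0)) {
      stop("size must be > 0", call. = FALSE)
    }
    if (class_label == "frameshift_indel" && size %% 3L == 0L) {
      stop("frameshift_indel size must not be divisible by 3", call. = FALSE)
    }
  }
  structure(list(class_label = class_label, position = as.integer(position),
                 size = as.integer(size), op = op, seed = as.integer(seed)),
            class = "mutation_spec")
}

#' Apply an engineered mutation to a genome's comP allele
#'
#' Edits the comP CDS in place (strand-aware), shifts the coordinates of all
#' features downstream of the edit, and appends the mutation to the genome's
#' ground truth. `insertion_element` inserts the packaged IS-like cassette
#' (1200 nt, 20-nt terminal inverted repeats) with a 4-nt target-site
#' duplication.
#'
#' @param genome a `synthetic_genome` containing an intact comP feature.
#' @param spec a [mutation_spec()].
#' @param refs a [reference_set()].
#' @return The edited `synthetic_genome`.
#' @export
mutate_comP <- function(genome, spec, refs = reference_set()) {
  stopifnot(inherits(spec, "mutation_spec"))
  if (spec$class_label == "none") {
    genome$truth$mutations <- c(genome$truth$mutations, list(spec))
    return(genome)
  }
  feat <- find_feature(genome, "comP")
  if (is.null(feat)) stop("genome has no comP feature", call. = FALSE)
  cds <- feature_seq(genome, feat)
  len <- nchar(cds)

  edit <- with_seed(spec$seed, switch(
    spec$class_label,
    nonsense = {
      pos <- (spec$position - 1L) * 3L + 1L
      list(pos = pos, del = 3L, ins = "TAA")
    },
    frameshift_indel = {
      if (identical(spec$op, "delete")) {
        list(pos = spec$position, del = spec$size, ins = "")
      } else {
        list(pos = spec$position, del = 0L,
             ins = paste(sample(c("A", "C", "G"), spec$size, replace = TRUE),
                         collapse = ""))
      }
    },
    inframe_3prime_deletion = {
      list(pos = (spec$position - 1L) * 3L + 1L, del = spec$size * 3L, ins = "")
    },
    insertion_element = {
      p <- spec$position
      if (p < 5L) stop("insertion position too close to CDS start", call. = FALSE)
      tsd <- substr(cds, p - 3L, p)
      list(pos = p + 1L, del = 0L, ins = paste0(refs$is_cassette, tsd))
    },
    polyT_slip = {
      off <- refs$hotspot$offset
      run <- regexpr("T+", substr(cds, off, off + 20L))
      if (run != 1L || attr(run, "match.length") < refs$hotspot$run_length) {
        stop("comP carries no poly-T hotspot at the reference offset ",
             "(non-NCIB3610-like template?)", call. = FALSE)
      }
      list(pos = off, del = 0L, ins = strrep("T", spec$size))
    }))

  if (edit$pos < 4L || edit$pos + edit$del - 1L > len - 3L) {
    stop("edit would extend beyond the comP CDS interior", call. = FALSE)
  }
  genome <- apply_cds_edit(genome, feat, edit$pos, edit$del, edit$ins)
  genome$truth$mutations <- c(genome$truth$mutations, list(spec))
  genome
}

# Replace CDS[pos .. pos+del-1] with ins (del = 0 inserts before CDS[pos]),
# in genome coordinates, shifting downstream features.
apply_cds_edit <- function(genome, feat, pos, del, ins) {
  contig_name <- as.character(GenomicRanges::seqnames(feat))
  contig <- genome$contigs[[contig_name]]
  minus <- as.character(GenomicRanges::strand(feat)) == "-"
  fstart <- GenomicRanges::start(feat); fend <- GenomicRanges::end(feat)
  if (minus) {
    gl <- fend - pos - del + 2L
    ins_g <- if (nzchar(ins)) revcomp(ins) else ""
  } else {
    gl <- fstart + pos - 1L
    ins_g <- ins
  }
  genome$contigs[[contig_name]] <-
    paste0(substr(contig, 1L, gl - 1L), ins_g,
           substr(contig, gl + del, nchar(contig)))
  delta <- nchar(ins) - del

  gr <- genome$features
  on_contig <- as.character(GenomicRanges::seqnames(gr)) == contig_name
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  after <- on_contig & st >= gl + del
  spans <- on_contig & !after & en >= gl
  st[after] <- st[after] + delta
  en[after | spans] <- en[after | spans] + delta
  GenomicRanges::ranges(gr) <- IRanges::IRanges(start = st, end = en)
  genome$features <- gr
  genome
}

#' Generate a genome fragment carrying (or lacking) a rapP-phrP module
#'
#' Emits a two-contig assembly (a 40-kb chromosome-like contig and a 6-kb
#' plasmid-like contig named `plasmid_pBS32`). The rapP CDS (with the
#' requested residue-236 codon: N = AAC, T = ACC) and a downstream phrP on
#' the same strand within 500 nt are placed on the contig selected by
#' `replicon`. The 5'-truncated variant lacks the first 150 codons and the
#' annotated start. A diverged Rap-family paralog (~45% identity to the
#' RapP reference) is always present on the chromosome contig, so detection
#' must discriminate rapP from paralogs by similarity. Features carry
#' product descriptions but no `rapP`/`phrP` gene symbols.
#'
#' @param variant `"N"` or `"T"`: residue 236 of RapP.
#' @param completeness `"complete"`, `"five_prime_truncated"` or `"absent"`.
#' @param replicon `"plasmid"` or `"chromosome"`.
#' @param seed integer seed.
#' @param refs a [reference_set()].
#' @return A `synthetic_genome`; `$truth` records `presence`, `residue_236`,
#'   `replicon` and `phrP_downstream`.
#' @export
make_rapP_module <- function(variant = c("N", "T"),
                             completeness = c("complete",
                                              "five_prime_truncated",
                                              "absent"),
                             replicon = c("plasmid", "chromosome"),
                             seed = 1L, refs = reference_set()) {
  variant <- match.arg(variant)
  completeness <- match.arg(completeness)
  replicon <- match.arg(replicon)
  with_seed(seed, {
    chrom <- random_filler(40000L)
    plasmid <- random_filler(6000L)
    feats <- list()

    # Rap-family paralog on the chromosome, always.
    par_at <- 30000L
    chrom <- paste0(substr(chrom, 1L, par_at - 1L), refs$rap_paralog,
                    substr(chrom, par_at, nchar(chrom)))
    feats[[1]] <- cds_feature("chromosome", par_at,
                              par_at + nchar(refs$rap_paralog) - 1L, "+",
                              gene = NA_character_,
                              product = "response regulator aspartate phosphatase family protein",
                              id = "cds_par")

    truth <- list(presence = completeness,
                  residue_236 = if (completeness == "absent") NA_character_ else variant,
                  replicon = if (completeness == "absent") NA_character_ else replicon,
                  phrP_downstream = completeness != "absent")

    if (completeness != "absent") {
      rap <- refs$rapP
      codon <- if (variant == "N") "AAC" else "ACC"
      substr(rap, (236L - 1L) * 3L + 1L, 236L * 3L) <- codon
      if (completeness == "five_prime_truncated") {
        rap <- substr(rap, 150L * 3L + 1L, nchar(rap))
      }
      module <- paste0(rap, random_filler(80L), refs$phrP)
      target <- if (replicon == "plasmid") "plasmid" else "chromosome"
      at <- if (replicon == "plasmid") 2000L else 10000L
      seqs <- list(chromosome = chrom, plasmid = plasmid)
      seqs[[target]] <- paste0(substr(seqs[[target]], 1L, at - 1L), module,
                               substr(seqs[[target]], at, nchar(seqs[[target]])))
      chrom <- seqs$chromosome; plasmid <- seqs$plasmid
      cname <- if (replicon == "plasmid") "plasmid_pBS32" else "chromosome"
      rap_end <- at + nchar(rap) - 1L
      feats[[2]] <- cds_feature(cname, at, rap_end, "+", NA_character_,
                                "response regulator aspartate phosphatase", "cds_rap")
      phr_start <- rap_end + 81L
      feats[[3]] <- cds_feature(cname, phr_start,
                                phr_start + nchar(refs$phrP) - 1L, "+",
                                NA_character_,
                                "phosphatase regulator inhibitor pro-peptide", "cds_phr")
      # The paralog sits upstream of any chromosome-placed module, so its
      # coordinates are unaffected; assert to be safe.
      stopifnot(par_at + nchar(refs$rap_paralog) < 40000L || replicon == "plasmid")
    }
    contigs <- c(chromosome = chrom, plasmid_pBS32 = plasmid)
    gr <- suppressWarnings(do.call(c, feats))
    new_synthetic_genome(
      sprintf("synth_rapP_%s_%s_%s_s%d", variant, completeness, replicon, seed),
      contigs, gr, truth)
  })
}

#' Generate a synthetic differential-expression table
#'
#' @param n_genes number of genes.
#' @param toxin_ids character subset of the generated gene ids to label as
#'   toxin/antibiotic-associated.
#' @param effects optional data.frame with columns `gene`, `logFC`, `FDR`
#'   overriding the random values for those genes.
#' @param seed integer seed.
#' @return list of class `synthetic_de_table`: `$table` (data.frame `gene`,
#'   `logFC`, `FDR`), `$toxin_ids`, and `$truth_pass` (genes with
#'   FDR < 0.01 and |logFC| > 1).
#' @export
make_de_table <- function(n_genes, toxin_ids = character(), effects = NULL,
                          seed = 1L) {
  genes <- sprintf("gene%04d", seq_len(n_genes))
  if (anyDuplicated(genes)) stop("duplicate gene ids", call. = FALSE)
  if (!all(toxin_ids %in% genes)) {
    stop("toxin_ids must be a subset of the generated gene ids", call. = FALSE)
  }
  tab <- with_seed(seed, data.frame(
    gene = genes,
    logFC = stats::rnorm(n_genes, sd = 1.2),
    FDR = stats::runif(n_genes)^2,
    stringsAsFactors = FALSE))
  if (!is.null(effects)) {
    if (anyDuplicated(effects$gene)) stop("duplicate gene ids", call. = FALSE)
    i <- match(effects$gene, tab$gene)
    if (anyNA(i)) stop("effects reference unknown genes", call. = FALSE)
    tab$logFC[i] <- effects$logFC
    tab$FDR[i] <- effects$FDR
  }
  structure(list(
    table = tab,
    toxin_ids = toxin_ids,
    truth_pass = tab$gene[tab$FDR < 0.01 & abs(tab$logFC) > 1]),
    class = "synthetic_de_table")
}
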