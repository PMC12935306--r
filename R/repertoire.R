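#' LXG-toxin top-match identity matrix
#'
#' For each reference LXG protein and each isolate, reports the maximum
#' global pairwise percent identity between the reference and any
#' LXG-flagged protein of that isolate (flagging comes from an externally
#' produced domain hit table, e.g. a PF04740 profile-HMM search). Identity
#' is matches over alignment length including gap columns. Isolates with no
#' hits yield `NA`.
#'
#' @param ref_proteins named character vector of reference LXG proteins.
#' @param proteomes named list (by isolate id) of named character vectors of
#'   proteins.
#' @param hits data.frame with columns `genome`, `protein` (and optionally
#'   `family`, `evalue`): the externally produced domain hit table.
#' @return numeric matrix, rows = references, columns = isolates.
#' @export
top_match_identity <- function(ref_proteins, proteomes, hits) {
  stopifnot(all(c("genome", "protein") %in% names(hits)))
  isolates <- names(proteomes)
  m <- matrix(NA_real_, nrow = length(ref_proteins), ncol = length(isolates),
              dimnames = list(names(ref_proteins), isolates))
  for (iso in isolates) {
    ids <- hits$protein[hits$genome == iso]
    if (length(ids) == 0L) next
    missing <- setdiff(ids, names(proteomes[[iso]]))
    if (length(missing) > 0L) {
      stop(sprintf("hit table names protein(s) not in proteome '%s': %s",
                   iso, paste(missing, collapse = ", ")), call. = FALSE)
    }
    for (r in names(ref_proteins)) {
      m[r, iso] <- max(vapply(ids, function(p) {
        global_pid(proteomes[[iso]][[p]], ref_proteins[[r]])
      }, numeric(1)))
    }
  }
  m
}

#' Filter a differential-expression table for the toxin panel
#'
#' A transcript passes when `FDR < fdr_max` and `|logFC| > abs_lfc_min`
#' (both strict, log fold changes base 2). The report restricts rows to the
#' configured toxin gene list and adds global counts.
#'
#' @param de_table data.frame with columns `gene`, `logFC`, `FDR`.
#' @param toxin_ids character vector of toxin/antibiotic-associated genes.
#' @param fdr_max FDR cutoff (default 0.01, strict).
#' @param abs_lfc_min absolute log2 fold-change cutoff (default 1, strict).
#' @return list of class `toxin_panel`: `panel` (toxin rows with `pass` and
#'   `direction`), `pass_genes` (all passing genes), `n_pass_total`,
#'   `n_pass_toxin`, `fdr_max`, `abs_lfc_min`.
#' @export
toxin_panel_filter <- function(de_table, toxin_ids = character(),
                               fdr_max = 0.01, abs_lfc_min = 1) {
  need <- c("gene", "logFC", "FDR")
  miss <- setdiff(need, names(de_table))
  if (length(miss) > 0L) {
    stop("de_table lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(fdr_max > 0, fdr_max <= 1, abs_lfc_min >= 0)
  pass <- de_table$FDR < fdr_max & abs(de_table$logFC) > abs_lfc_min
  panel <- de_table[de_table$gene %in% toxin_ids, need, drop = FALSE]
  panel$pass <- panel$FDR < fdr_max & abs(panel$logFC) > abs_lfc_min
  panel$direction <- ifelse(panel$logFC > 0, "up", "down")
  panel$direction[!panel$pass] <- NA_character_
  structure(list(panel = panel,
                 pass_genes = de_table$gene[pass],
                 n_pass_total = sum(pass),
                 n_pass_toxin = sum(panel$pass),
                 fdr_max = fdr_max, abs_lfc_min = abs_lfc_min),
            class = "toxin_panel")
}

#' Operon-level regulation summary
#'
#' An operon is flagged uniformly down-regulated more than 2-fold when every
#' member has `logFC <= -1` (and analogously up with `logFC >= 1`). Members
#' absent from the table are reported as not measured and block the flag.
#'
#' @param de_table data.frame with columns `gene`, `logFC`.
#' @param operon_gene_sets named list of character vectors (operon members).
#' @return data.frame with one row per operon: `operon`, `n_members`,
#'   `n_measured`, `uniform_down_2fold`, `uniform_up_2fold`,
#'   `members_failing` (comma-separated members blocking a flag, including
#'   unmeasured ones).
#' @export
operon_regulation_summary <- function(de_table, operon_gene_sets) {
  stopifnot(all(c("gene", "logFC") %in% names(de_table)))
  if (length(operon_gene_sets) == 0L ||
      any(lengths(operon_gene_sets) == 0L)) {
    stop("operon gene sets must be nonempty", call. = FALSE)
  }
  rows <- lapply(names(operon_gene_sets), function(op) {
    genes <- operon_gene_sets[[op]]
    lfc <- de_table$logFC[match(genes, de_table$gene)]
    measured <- !is.na(lfc)
    down <- all(measured) && all(lfc <= -1)
    up <- all(measured) && all(lfc >= 1)
    # members blocking the operon's dominant direction
    n_down <- sum(lfc <= -1, na.rm = TRUE)
    n_up <- sum(lfc >= 1, na.rm = TRUE)
    blockers <- if (n_down >= n_up) {
      genes[measured & !(lfc <= -1)]
    } else {
      genes[measured & !(lfc >= 1)]
    }
    failing <- c(if (any(!measured)) paste0(genes[!measured], " (not measured)"),
                 if (!down && !up) blockers)
    data.frame(operon = op, n_members = length(genes),
               n_measured = sum(measured),
               uniform_down_2fold = down, uniform_up_2fold = up,
               members_failing = paste(failing, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
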