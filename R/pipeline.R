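#' Screen a directory of annotated genomes
#'
#' Pairs `*.fasta`/`*.fa` files with same-stem `*.gff3`/`*.gff` annotation,
#' runs the comQXPA/comP screen, pherotype assignment and the rapP-phrP
#' screen on each genome, and writes a merged per-genome TSV plus a
#' machine-readable JSON report with summary counts per category. A genome
#' that fails to parse is skipped with a warning; "absent" biology is never
#' an error. An empty input directory yields an empty report with a
#' warning.
#'
#' @param input_dir directory of paired FASTA + GFF3 files.
#' @param out_dir output directory (`NULL` = write nothing).
#' @param refs a [reference_set()].
#' @param ... threshold overrides passed to [classify_comP()].
#' @return list of class `screen_report`: `report` (data.frame, one row per
#'   genome), `summary` (category counts), `skipped` (character), `paths`.
#' @export
run_screen <- function(input_dir, out_dir = NULL, refs = reference_set(),
                       ...) {
  fastas <- list.files(input_dir, pattern = "\\.(fasta|fa|fna)$",
                       full.names = TRUE)
  pairs <- list(); unpaired <- character()
  for (f in fastas) {
    stem <- sub("\\.[^.]*$", "", f)
    gff <- c(paste0(stem, ".gff3"), paste0(stem, ".gff"))
    gff <- gff[file.exists(gff)]
    if (length(gff) == 0L) unpaired <- c(unpaired, basename(f))
    else pairs[[basename(stem)]] <- c(fasta = f, gff3 = gff[1])
  }
  if (length(unpaired) > 0L) {
    warning("skipping unpaired FASTA file(s): ",
            paste(unpaired, collapse = ", "))
  }
  if (length(pairs) == 0L) {
    warning("no paired FASTA/GFF3 genomes found in ", input_dir)
  }

  skipped <- character()
  rows <- list()
  for (id in names(pairs)) {
    row <- tryCatch({
      g <- read_genome(pairs[[id]][["fasta"]], pairs[[id]][["gff3"]],
                       genome_id = id)
      screen_genome_row(g, refs, ...)
    }, error = function(e) {
      warning(sprintf("skipping genome '%s': %s", id, conditionMessage(e)))
      NULL
    })
    if (is.null(row)) skipped <- c(skipped, id) else rows[[id]] <- row
  }
  report <- if (length(rows) > 0L) do.call(rbind, rows) else empty_screen_report()
  rownames(report) <- NULL
  summary <- summarise_screen(report)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(out_dir, "screen_report.tsv")
    js <- file.path(out_dir, "screen_report.json")
    utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(list(report = report, summary = summary,
                              skipped = skipped,
                              manifest = run_manifest(unlist(pairs))),
                         js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(tsv = tsv, json = js)
  }
  structure(list(report = report, summary = summary, skipped = skipped,
                 paths = paths), class = "screen_report")
}

# One merged report row for a single genome.
screen_genome_row <- function(genome, refs, ...) {
  op <- extract_comQXPA(genome, refs)
  cc <- classify_comP(op, refs, ...)
  ph <- assign_pherotype(op$comQ_protein, refs)
  rp <- detect_rapP_module(genome, refs)
  data.frame(
    genome_id = genome$genome_id,
    operon_complete = op$complete,
    operon_flags = paste(op$flags, collapse = ";"),
    comP_status = cc$status,
    comP_classes = paste(cc$classes, collapse = ";"),
    comP_predicted_length_aa = cc$predicted_length_aa %||% NA_integer_,
    comP_identity = cc$identity,
    hotspot_present = isTRUE(cc$hotspot$present),
    hotspot_run_length = cc$hotspot$run_length %||% NA_integer_,
    hotspot_indel_in_run = cc$hotspot$indel_in_run,
    pherotype = ph$label,
    pherotype_identity = ph$identity,
    rapP_presence = rp$presence,
    rapP_residue_236 = rp$residue_236,
    rapP_phrP_downstream = rp$phrP_downstream,
    rapP_replicon = rp$replicon,
    stringsAsFactors = FALSE)
}

empty_screen_report <- function() {
  data.frame(genome_id = character(), operon_complete = logical(),
             operon_flags = character(), comP_status = character(),
             comP_classes = character(),
             comP_predicted_length_aa = integer(),
             comP_identity = numeric(), hotspot_present = logical(),
             hotspot_run_length = integer(),
             hotspot_indel_in_run = logical(), pherotype = character(),
             pherotype_identity = numeric(), rapP_presence = character(),
             rapP_residue_236 = character(),
             rapP_phrP_downstream = logical(), rapP_replicon = character(),
             stringsAsFactors = FALSE)
}

# Census-style category counts matching the screen's reporting scheme.
summarise_screen <- function(report) {
  count <- function(x) as.list(table(x, useNA = "no"))
  list(
    n_genomes = nrow(report),
    comP_status = count(report$comP_status),
    comP_classes = count(unlist(strsplit(report$comP_classes[
      nzchar(report$comP_classes)], ";"))),
    hotspot_indel_in_run = sum(report$hotspot_indel_in_run %in% TRUE),
    pherotype = count(report$pherotype),
    rapP_presence = count(report$rapP_presence),
    rapP_residue_236 = count(report$rapP_residue_236),
    rapP_replicon = count(report$rapP_replicon))
}

run_manifest <- function(input_files = character()) {
  sums <- if (length(input_files) > 0L) {
    as.list(tools::md5sum(input_files))
  } else {
    list()
  }
  list(tool = "quorumcomp",
       version = as.character(utils::packageVersion("quorumcomp")),
       timestamp = format(Sys.time(), tz = "UTC"),
       input_md5 = sums)
}

#' Read and validate a simulation configuration file
#'
#' @param path YAML configuration file; see
#'   `system.file("extdata", "default_sim.yaml", package = "quorumcomp")`.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (field in c("grid", "strains", "layout", "t_end")) {
    if (is.null(cfg[[field]])) {
      stop("config is missing required field '", field, "'", call. = FALSE)
    }
  }
  for (field in c("nx", "ny", "h")) {
    if (is.null(cfg$grid[[field]])) {
      stop("config is missing required field 'grid.", field, "'",
           call. = FALSE)
    }
  }
  if (length(cfg$strains) != 2L) {
    stop("config field 'strains' must list exactly two strains",
         call. = FALSE)
  }
  for (field in c("n_per_strain", "seed")) {
    if (is.null(cfg$layout[[field]])) {
      stop("config is missing required field 'layout.", field, "'",
           call. = FALSE)
    }
  }
  grid <- sim_grid(nx = as.integer(cfg$grid$nx), ny = as.integer(cfg$grid$ny),
                   h = cfg$grid$h, radius = cfg$grid$radius %||% NULL)
  strains <- lapply(cfg$strains, function(s) {
    strain_params(s$name %||% "strain", r = s$r %||% 1, d = s$d %||% 1)
  })
  layout <- make_founder_layout(
    n_per_strain = cfg$layout$n_per_strain,
    inoculum_radius = cfg$layout$inoculum_radius %||% 5,
    spot_radius = cfg$layout$spot_radius %||% 1,
    b0 = cfg$layout$b0 %||% 0.5,
    seed = cfg$layout$seed, grid = grid)
  sim_config(grid, strains, layout, dt = cfg$dt %||% NULL,
             t_end = cfg$t_end,
             stop_area_frac = cfg$stop_area_frac %||% 0.9,
             occupied_threshold = cfg$occupied_threshold %||% 0.05,
             snapshot_every = cfg$snapshot_every %||% NULL)
}

#' Run a simulation from a configuration file and write its artifacts
#'
#' Validates the configuration before any compute, runs the simulation, and
#' writes: per-channel 16-bit TIFF snapshots of the final state, a merged
#' pseudo-colour PNG (strain 1 green, strain 2 magenta, overlap grey), an
#' outcome TSV, and a JSON run manifest.
#'
#' @param config path to a YAML configuration file, or a [sim_config()].
#' @param out_dir output directory.
#' @return the `sim_result`, invisibly, with `$paths` added.
#' @export
run_simulation <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_sim_config(config) else config
  stopifnot(inherits(cfg, "sim_config"))
  res <- simulate_biofilm(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  top <- max(res$state$B1, res$state$B2, 1e-12)
  p_b1 <- file.path(out_dir, "final_B1.tiff")
  p_b2 <- file.path(out_dir, "final_B2.tiff")
  p_png <- file.path(out_dir, "final_merged.png")
  p_tsv <- file.path(out_dir, "outcome.tsv")
  p_man <- file.path(out_dir, "manifest.json")
  tiff::writeTIFF(res$state$B1 / top, p_b1, bits.per.sample = 16L)
  tiff::writeTIFF(res$state$B2 / top, p_b2, bits.per.sample = 16L)
  png::writePNG(merge_channels(res$state$B1, res$state$B2), p_png)
  oc <- res$outcome
  utils::write.table(
    data.frame(t_final = res$state$t, steps = res$steps,
               f1 = oc$f1, f2 = oc$f2,
               percent_challenger_remaining = oc$percent_challenger_remaining,
               area_frac1 = oc$area_frac1, area_frac2 = oc$area_frac2),
    p_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  man <- run_manifest(if (is.character(config)) config else character())
  man$seed <- cfg$layout$seed
  man$dt <- cfg$dt
  jsonlite::write_json(man, p_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  res$paths <- c(B1 = p_b1, B2 = p_b2, merged = p_png, outcome = p_tsv,
                 manifest = p_man)
  invisible(res)
}
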