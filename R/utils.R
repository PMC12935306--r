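#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so generators are deterministic without clobbering
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# The 61 sense codons of the standard code.
sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# Random filler DNA at ~43% GC, returned as a single string.
random_filler <- function(n) {
  p_gc <- 0.43
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - p_gc) / 2, p_gc / 2, p_gc / 2, (1 - p_gc) / 2)),
        collapse = "")
}

# Replace the interior of any run of >= 7 T's with C until none remain.
# C never occurs in a stop codon, so this cannot introduce premature stops.
cap_t_runs <- function(s, max_run = 6L) {
  pat <- sprintf("T{%d,}", max_run + 1L)
  while (grepl(pat, s)) {
    m <- regexpr(pat, s)
    mid <- as.integer(m) + (max_run %/% 2L)
    substr(s, mid, mid) <- "C"
  }
  s
}

# Random CDS of n_aa codons: ATG start, random sense codons, TAA stop,
# homopolymer T runs capped so the only long poly-T tract is an engineered one.
random_cds <- function(n_aa) {
  body <- paste(sample(sense_codons(), n_aa - 1L, replace = TRUE), collapse = "")
  cap_t_runs(paste0("ATG", body, "TAA"))
}

# Translate a nucleotide string; returns an AA string without the trailing '*'.
translate_cds <- function(nt) {
  nt <- as.character(nt)
  n <- nchar(nt) %/% 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n * 3L)),
    if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

# Longest run of a given base in a string (0 when absent).
max_base_run <- function(s, base = "T") {
  hits <- gregexpr(sprintf("%s+", base), s)[[1]]
  if (hits[1] == -1L) return(0L)
  max(attr(hits, "match.length"))
}

#' Percent identity between two sequences by global alignment
#'
#' Identity is defined as matches divided by alignment length including gap
#' columns (Biostrings `pid` type `"PID1"`).
#'
#' @param a,b character or XString sequences (both nucleotide or both protein).
#' @param type `"protein"` or `"dna"`.
#' @return numeric percent identity in `[0, 100]`.
#' @keywords internal
global_pid <- function(a, b, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (type == "protein") {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(as.character(a)), Biostrings::AAString(as.character(b)),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(as.character(a)), Biostrings::DNAString(as.character(b)),
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
      type = "global")
  }
  Biostrings::pid(aln, type = "PID1")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
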