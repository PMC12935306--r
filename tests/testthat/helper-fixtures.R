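# Shared fixtures: small simulator configurations and randomized mutant
# genomes with known truth, built in code at test time.

two_strains <- function(r1 = 1, r2 = 1, d1 = 1, d2 = d1) {
  list(strain_params("B1", r = r1, d = d1), strain_params("B2", r = r2, d = d2))
}

uniform_state <- function(n, b1, b2 = 0) {
  structure(list(B1 = matrix(b1, n, n), B2 = matrix(b2, n, n), t = 0),
            class = "biofilm_state")
}

# A quick two-strain competition used to make density fields for the image
# fixtures.
quick_fields <- function(rho = 1.2, seed = 2) {
  grid <- sim_grid(128, 128, h = 0.5, radius = 25)
  cfg <- sim_config(grid, two_strains(1, rho),
                    make_founder_layout(20, inoculum_radius = 4,
                                        spot_radius = 0.8, b0 = 0.5,
                                        seed = seed, grid = grid),
                    t_end = 20)
  simulate_biofilm(cfg)$state
}

# Expected classify_comP class for each generator mutation class (a poly-T
# slip is a frameshift-inducing indel).
expected_comp_class <- c(
  nonsense = "nonsense",
  frameshift_indel = "frameshift",
  inframe_3prime_deletion = "inframe_3prime_deletion",
  insertion_element = "insertion_element",
  polyT_slip = "frameshift",
  none = "")

# Randomized valid mutant genome of a given class; parameters are drawn
# from `seed` so panels vary in position, size, edit type and strand.
random_comp_mutant <- function(class_label, seed) {
  set.seed(seed + 7000L)
  strand <- if (seed %% 2L == 0L) "+" else "-"
  g <- make_reference_operon("NCIB3610", seed = seed, strand = strand)
  if (class_label == "none") return(g)
  spec <- switch(class_label,
    nonsense = mutation_spec("nonsense", position = sample(20:700, 1),
                             seed = seed),
    frameshift_indel = mutation_spec("frameshift_indel",
                                     position = sample(100:2100, 1),
                                     size = sample(c(1L, 2L, 4L, 5L), 1),
                                     op = sample(c("insert", "delete"), 1),
                                     seed = seed),
    inframe_3prime_deletion = {
      p <- sample(310:740, 1)
      mutation_spec("inframe_3prime_deletion", position = p,
                    size = sample.int(min(25L, 765L - p), 1), seed = seed)
    },
    insertion_element = mutation_spec("insertion_element",
                                      position = sample(50:2200, 1),
                                      seed = seed),
    polyT_slip = mutation_spec("polyT_slip", size = sample(1:2, 1),
                               seed = seed))
  mutate_comP(g, spec)
}

rapp_panel_design <- function(seeds = 1:3) {
  expand.grid(variant = c("N", "T"),
              completeness = c("complete", "five_prime_truncated", "absent"),
              replicon = c("plasmid", "chromosome"),
              seed = seeds, stringsAsFactors = FALSE)
}
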