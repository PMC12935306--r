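# quorumcomp

Tools for studying **intraspecies competition in *Bacillus subtilis* colony
biofilms**: why strains with slightly faster growth competitively exclude
close relatives, and how disruption of quorum-sensing genes (the *comQXPA*
cassette and the *rapP–phrP* module) produces that advantage. The package is
aimed at microbiologists and bioinformaticians who (a) want a mechanistic
model of two-strain biofilm competition, (b) quantify competition outcomes
from fluorescence images or growth curves, or (c) screen annotated genome
assemblies for disrupted quorum-sensing alleles.

## What it computes

**Biofilm competition model.** Two strains growing in one colony are
described by the nondimensional reaction–diffusion system

$$\partial_t B_i = d_i \nabla\cdot(\phi(B)\nabla B_i) + r_i B_i (1 - B),
\qquad B = B_1 + B_2, \qquad \phi(B) = \max(0, 1 - B),$$

logistic growth against a shared carrying capacity plus negative
density-dependent diffusion (the colony interior freezes as it fills; only
the front keeps moving), on a disc domain with zero-flux boundaries. The
control parameter is the relative growth rate ρ = r₂/r₁. The simulator
(`simulate_biofilm()`, `sweep_relative_growth()`) shows that small ρ
differences translate into large differences in final relative strain
density — competitive exclusion.

**Outcome quantification.** `quantify_relative_density()` turns two-channel
fluorescence images into "% challenger remaining" (Otsu colony mask, median
background, integrated intensity); `biofilm_footprint()` measures colony
area; `fit_doubling_time()` fits doubling times from OD600 series over an
automatically selected exponential window.

**Genome screens.** `extract_comQXPA()` + `classify_comP()` locate the
quorum-sensing operon and classify each *comP* allele as intact or
disrupted under four criteria — internal nonsense mutations, frameshift
indels, in-frame deletions in the conserved 3′ region, and insertion
elements — with the predicted variant-protein length and detection of the
8-T slipped-strand hotspot (`detect_polyT_hotspot()`).
`assign_pherotype()` classifies ComQ pherotypes; `detect_rapP_module()`
censuses *rapP–phrP* (complete / 5′-truncated / absent, residue-236 N/T
signal-responsiveness state, plasmid vs chromosomal context).
`top_match_identity()` and `toxin_panel_filter()` summarise LXG/T7SS toxin
repertoires and differential-expression toxin panels (FDR < 0.01,
|log2FC| > 1).

**Synthetic data with ground truth.** `make_reference_operon()`,
`mutate_comP()`, `make_rapP_module()`, `render_fluorescence_image()` and
`make_de_table()` generate annotated genomes (FASTA + GFF3), images and
expression tables with every applied mutation recorded, so the whole
pipeline is testable offline. Template sequences are synthetic stand-ins;
real references can be supplied to every screen.

## Worked example

```r
library(quorumcomp)

# 1. Competition outcome as a function of relative growth rate
grid   <- sim_grid(80, 80, h = 0.5, radius = 16)
layout <- make_founder_layout(15, inoculum_radius = 3.5, spot_radius = 0.8,
                              b0 = 0.5, seed = 1, grid = grid)
cfg <- sim_config(grid, list(strain_params("B1", r = 1),
                             strain_params("B2", r = 1)), layout, t_end = 20)
sweep_relative_growth(cfg, c(0.8, 1.0, 1.2, 1.3))
#>   rho f2_final percent_challenger_remaining
#> 1 0.8    0.322                         67.8
#> 2 1.0    0.493                         50.7
#> 3 1.2    0.649                         35.1
#> 4 1.3    0.709                         29.1

# 2. Screen a genome carrying the ComP delta-633-649 in-frame deletion
g <- mutate_comP(make_reference_operon("NCIB3610", seed = 1),
                 mutation_spec("inframe_3prime_deletion", position = 633,
                               size = 17))
call <- classify_comP(extract_comQXPA(g))
cat(call$status, "|", call$classes, "|", call$predicted_length_aa, "aa\n")
#> disrupted | inframe_3prime_deletion | 752 aa

# 3. Doubling time from an OD600 series
t <- seq(0, 360, by = 30)
fit_doubling_time(t, 0.01 * 2^(t / 60))$doubling_time_min
#> [1] 60
```

Reading the output: at equal growth rates (ρ = 1.0) the two strains coexist
near 50:50; a 1.3× growth advantage already hands strain 2 most of the
colony (f₂ = 0.71 on this small desk-scale grid, higher still at the default
256² domain where the front has longer to run). The screened allele is
called disrupted by the in-frame 3′-deletion criterion and its predicted
protein is 752 aa — exactly 17 residues shorter than the 769-aa reference.
The growth fit returns the seeded 60-min doubling time exactly.

Directory-level screening (`run_screen()`) writes a merged per-genome
TSV/JSON report with census counts per category; `run_simulation()` runs a
YAML-configured simulation (see
`system.file("extdata", "default_sim.yaml", package = "quorumcomp")`) and
writes snapshots, an outcome table and a run manifest.

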