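---
title: "Models and methods behind quorumcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quorumcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quorumcomp)
```

`quorumcomp` studies intraspecies competition in *Bacillus subtilis* colony
biofilms from three angles: a mechanistic spatial model of two strains
growing in one biofilm, image- and growth-curve-based quantification of
competitive outcomes, and comparative-genomics screens of the quorum-sensing
loci (*comQXPA*, *rapP–phrP*) whose disruption shifts those outcomes. This
vignette explains the models, the defaults and why they were chosen, what
the synthetic-data generators emulate, and the package's known limitations.

## The two-strain biofilm model

The simulator integrates the nondimensional reaction–diffusion system

$$\frac{\partial B_i}{\partial t}
  = d_i \,\nabla\!\cdot\!\big(\phi(B)\,\nabla B_i\big) + r_i B_i (1 - B),
  \qquad B = B_1 + B_2,\quad i = 1, 2,$$

on a disc domain $\Omega$ with zero-flux boundaries. Each strain grows
logistically against the *shared* carrying capacity (nondimensionalised to
1) and spreads by negative density-dependent diffusion: the default
diffusivity $\phi(B) = \max(0, 1 - B)$ vanishes as the community approaches
capacity, so mature regions of the colony freeze while the expansion front
stays motile. This captures the essential biology — founder cells at the
front settle the territory, and interior composition is largely locked in —
without nutrient fields, mechanics, or vertical structure, all of which are
deliberately out of scope. `phi` is a plain function argument of
`sim_config()`, so alternative diffusivity laws can be substituted without
touching the integrator.

Units: lengths and times are nondimensional. The time scale is fixed by
strain 1 ($r_1 = 1$); the biologically interesting control parameter is the
relative growth rate $\rho = r_2/r_1$, applied to strain 2. Both motilities
default to $d_i = 1$; the model's qualitative conclusions concern growth-rate
asymmetry at equal motility, and no published value constrains $d$ in these
units.

### Discretisation and why it is trustworthy

Space: second-order central flux form on a regular grid; the face
diffusivity is the arithmetic mean of $\phi$ at the two adjacent cells;
fluxes across $\partial\Omega$ are zeroed, which makes zero-growth mass
conservation exact up to floating-point roundoff (the test suite requires
relative drift $< 10^{-10}$ per step). Time: explicit forward Euler.
`biofilm_step()` refuses any `dt` above the diffusion stability bound
$h^2/(4\max_i d_i)$ (valid because $\phi \le 1$).

The default step is $0.5\times\min\{h^2/(4\max d_i),\, 1/\max r_i\}$. With
equal motilities this makes the scheme positivity- and capacity-preserving
by construction, not by clipping: (i) the diffusion update of each strain is
a convex combination of neighbouring values whenever
$dt \le h^2/(4d\phi_{\max})$; (ii) because both strains share the same face
coefficients when $d_1 = d_2$, the *total* density after diffusion is a
convex combination of neighbouring totals, hence $\le 1$; (iii) the shared
logistic factor $(1-B)$ cannot push the total past 1 when
$dt\,r_{\max} \le 1$. With unequal motilities the capacity bound is no
longer guaranteed by this argument, which is why the property tests and the
defaults use equal $d$. A roundoff guard zeroes negative densities only
below $10^{-12}$ and aborts otherwise.

Default problem sizes: a disc of radius 60 on a $256^2$ grid ($h = 0.5$),
founders placed uniformly in a central disc of radius 5 (50 spots per strain
at density 0.5, emulating a 1:1 mixed inoculum), integration to $t = 50$ or
until the occupied area ($B > 0.05$) reaches 90% of $\Omega$. A full run
takes seconds on one CPU in plain vectorised R; the property and
convergence tests use smaller grids (48²–96²) with the same physics. Grid
refinement at fixed physical domain changes the final relative density by
less than 0.01 in the tested configurations.

### What the model reproduces

With equal growth rates, mirror-symmetric founder layouts split the final
colony exactly 50:50, and generic 1:1 random layouts stay near coexistence.
A strain with $\rho = 1.3$ overtakes the expansion front and ends with the
large majority of total biomass — competitive exclusion from a small
growth-rate difference, the model's central claim. The final relative
density $f_2$ increases monotonically in $\rho$; `sweep_relative_growth()`
tabulates this curve with the layout held fixed. $f_2$ is used as the
outcome statistic; `percent_challenger_remaining` is $100 f_{\text{challenger}}$
with the challenger defaulting to strain 1, matching how competition assays
report "% challenger remaining".

## Quantifying competition outcomes

`relative_density_from_fields()` is the exact statistic on model fields:
$f_i = \sum B_i / \sum(B_1+B_2)$.

`quantify_relative_density()` is the image-based analogue for two-channel
fluorescence rasters. Each channel is Otsu-thresholded on its own intensity
range (making the result invariant under rescaling both channels); the
union of the two masks defines the colony; the per-channel background is
the median of the off-colony pixels; each strain's signal is its
background-subtracted intensity integrated over the colony mask. Two
design points deserve explanation:

* **Why integrate intensity rather than count pixels?** Relative strain
  density weights brighter (denser) regions; pixel counting saturates where
  strains interleave below pixel resolution. `mode = "pixels"` is available
  for macro-style counting.
* **Why a union mask with median background rather than per-channel
  above-threshold sums?** In mixed colonies the minority strain is dim
  *inside* the colony; restricting its signal to its own above-threshold
  pixels discards that signal and biased recovery by about −3 percentage
  points on rendered test images at 2% noise. Scoring both channels over
  the shared colony mask removes the bias (recovery within ±1 point over 20
  noise seeds). A rolling-ball-style alternative (`background = "tophat"`,
  morphological opening with a disc, default radius 50 px) is retained for
  images with illumination gradients; its radius must exceed the colony
  radius, or the opening subtracts real signal.

`biofilm_footprint()` thresholds one channel and returns the area of the
largest connected component, ignoring satellite colonies.

`fit_doubling_time()` fits $\log_2 \mathrm{OD}_{600}$ against time over the
exponential window; the doubling time is the reciprocal slope. The
automatic window is the longest contiguous run with positive slope,
$R^2 \ge 0.99$, and no point deviating from the line by more than 0.15
log2 units. The residual bound matters: when the exponential spans many
doublings, a lag or plateau point can ride along with $R^2$ still above
0.99 and bias the slope by several percent; a per-point residual cap
rejects such windows while leaving noiseless exponentials exact.

## The comP disruption screen

`extract_comQXPA()` locates comQ, comX, comP and comA by annotated gene
symbol, with a protein-similarity fallback (≥ 40% identity, query/reference
length ratio ≥ 0.7) to survive annotation-name drift, and extracts the
operon from the start of *comQ* to the end of *comA* on the operon strand.
Fragmented or partly missing operons are flagged but *comP* is still
analysed whenever its CDS is intact.

`classify_comP()` performs a codon-aware comparison against the reference
comP via global nucleotide alignment with affine gaps (match 2, mismatch
−1, gap open 12, extend 1). The penalties deliberately favour mismatches
over gaps so that the highly polymorphic 5′ region aligns gaplessly, while
true indels — flanked by identical sequence — still open gaps. Four
disruption classes are called, and may co-occur:

1. **Nonsense**: a stop codon in the query's own reading frame upstream of
   any indel, before 95% of the reference protein length. The 95% cutoff
   tolerates natural C-terminal length variation while catching premature
   truncation; stops *caused by* a frameshift are attributed to the
   frameshift, not double-counted.
2. **Frameshift**: net intra-CDS indel length not divisible by 3.
   Insertions of insertion-element scale (below) are excluded from the net
   length: the engineered element arrives with a 4-nt target-site
   duplication, and calling the same event both an insertion element and a
   frameshift would misrepresent one biological event as two.
3. **In-frame 3′ deletion**: a deletion of ≥ 1 whole codon at or beyond the
   conserved-region boundary (default reference codon 300; the 5′ third of
   the gene is pherotype-polymorphic, so 5′ in-frame variation is not
   treated as disruption). The boundary is a configurable parameter.
4. **Insertion element**: an intra-CDS insertion ≥ 100 nt. Length is the
   only annotation-free signal available; the packaged IS-like cassette is
   1200 nt with terminal inverted repeats and comfortably clears the
   threshold.

Point substitutions are deliberately **not** called disruptive, even when
they are known to inactivate ComP; a substitution-based screen would need
functional evidence the sequence alone cannot supply, so the disruption
census is a lower bound by design.

`predicted_variant_length()` translates the variant CDS from its annotated
start, through frameshifts, to the first stop — the "calculated length of
the variant protein". `detect_polyT_hotspot()` anchors the reference 8-T
tract (a slipped-strand mispairing hotspot in the NCIB 3610-like allele) by
local alignment of a 58-nt flanked window and reports the observed run
length and whether it differs from 8; in pherotypes whose divergent 5′
region has no equivalent tract the window fails to align and the hotspot is
reported absent.

`assign_pherotype()` assigns the ComQ pherotype by global protein alignment
against the reference ComQ panel: best label at ≥ 90% identity with a ≥ 5
point margin over the runner-up, otherwise "unassigned". Identity is
defined throughout the package as matches over alignment length including
gap columns, stated explicitly because identity conventions differ.

## The rapP–phrP screen

`detect_rapP_module()` scans every CDS for local-alignment similarity to
the reference RapP and accepts candidates at ≥ 80% identity over ≥ 60% of
the reference length. These thresholds were chosen so that Rap-family
paralogs — which the synthetic genomes always include at ~45% identity —
fall well below the cutoff while a 5′-truncated rapP (missing up to ~40% of
the protein) is still detected. Completeness: coverage ≥ 95% with an intact
start codon is `complete`; an N-terminal gap of ≥ 5% of the reference is
`five_prime_truncated`. phrP is sought within 500 nt downstream on the same
strand (typical rap–phr spacing) at ≥ 60% identity. Residue 236 — the
threonine/asparagine switch that controls PhrP responsiveness — is read at
the *aligned* reference column, not the raw index, so indels elsewhere in
the protein cannot shift the call; a gap at the column yields
"undetermined". `replicon_context()` calls a contig plasmid-like from its
annotation, or from assembly structure (< 20% of the largest contig in a
≤ 5-contig assembly), chromosomal when the gene sits on the largest contig,
and unknown otherwise.

## Toxin repertoire and expression summaries

`top_match_identity()` consumes an externally produced LXG/PF04740 domain
hit table (profile-HMM searching is out of scope) and reports, for each
reference toxin and isolate, the best global-alignment identity among the
isolate's flagged proteins. `toxin_panel_filter()` applies the strict
differential-expression cutoffs FDR < 0.01 and |log2FC| > 1 and restricts
the report to a configured toxin list; `operon_regulation_summary()` flags
an operon uniformly down- (or up-) regulated more than 2-fold only when
*every* member passes, listing the members that block the flag.

## What the synthetic data emulate — and what they do not

The generators exist so every screen can be validated against known truth
with no downloads: `make_reference_operon()` builds annotated genomes with
a syntenic comQXPA operon (either strand) in ~43% GC filler;
`mutate_comP()` applies one engineered disruption per call and records it;
`make_rapP_module()` builds two-contig assemblies crossing presence ×
residue-236 × replicon, always including the decoy paralog;
`render_fluorescence_image()` maps density fields to two noisy,
bleed-contaminated channels; `make_de_table()` fabricates expression tables
with a recorded pass-set. All generators are deterministic per seed.

The template coding sequences are synthetic stand-ins generated from a
fixed internal seed — not real isolate sequence — and pherotype templates
differ only where the screens require (divergent ComQ; divergent comP 5′
third; presence/absence of the poly-T tract). Consequently, passing the
round-trip panels demonstrates that the screening logic inverts the
generator's mutation model exactly; it does not demonstrate robustness to
real-world annotation errors, assembly gaps, sequencing error, or
phylogenetic divergence beyond the modelled polymorphism. Real genome
surveys should supply real reference operons via the `refs` argument, and
the thresholds (conserved-region boundary, truncation fraction, insertion
size, identity/coverage cutoffs) are all exposed precisely because their
defaults here are calibrated stand-ins for unpublished screening criteria.

The same caveat applies to the simulator: it is a minimal mechanistic model
for *why small growth-rate differences amplify into exclusion*, not a
fitted description of any particular biofilm; and to the rendered images,
which emulate well-registered, background-flat fluorescence data rather
than real stereoscope optics.

## Numerical choices and degenerate inputs

* Alignment engine: `Biostrings::pairwiseAlignment` throughout; BLOSUM62
  with gap open 10 / extend 0.5 for proteins.
* Ties in gap placement follow the aligner's left-most convention; the
  classifier depends only on indel widths and approximate positions, with
  ≥ 30 nt of margin built into the conserved-boundary default.
* Empty biofilms (both fields or both channels zero) raise a defined
  "empty biofilm" error rather than returning 0/0.
* A uniformly saturated image is treated as one full-frame component; a
  blank image returns area 0 with a warning.
* Overlapping founder spots are resolved by proportional rescaling wherever
  the summed inoculum would exceed capacity.
* `run_screen()` isolates per-genome failures: a corrupt annotation skips
  that genome with a warning and never poisons the rest of the directory.

## Limitations

* The capacity-preservation argument requires equal strain motilities;
  exploring unequal $d_i$ is possible but outside the tested envelope.
* The screen's disruption census is a deliberate lower bound (no point
  substitutions, no promoter or regulatory lesions).
* Insertion elements are recognised by size alone, not by homology to IS
  families.
* The image quantifier assumes two channels of comparable gain; it is
  scale-invariant jointly but not robust to strongly nonlinear detectors.
* Pherotype assignment depends on the supplied ComQ reference panel;
  unassigned simply means "not within 90% of any packaged reference".
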