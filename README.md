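# g4tune

Design and evaluation tools for **synthetic G-quadruplex (G4) expression
controllers** — guanine-rich motifs that fold into four-stranded structures
and, when placed in a core promoter (DNA level) or 5'UTR (RNA level),
sterically dampen transcription or translation of a downstream gene. A
library of such motifs with graded strengths gives cassette designers a
dial for mammalian recombinant protein expression, usable at both levels at
once. The intended users are synthetic biologists and bioprocess engineers
building expression vectors (reporter constructs, mRNA payloads, multichain
biologics) who need predictable, tunable output levels.

## What the package computes

Component activity is measured in **relative expression units (REU)**:
protein output as a percentage of the unengineered control chassis.

* **Motif libraries.** Full-factorial enumeration over the four design
  parameters (G-tract length *L*, G-tract number *N*, loop length, loop
  composition) under two strategies — (i) *N* = 4 with *L* = 2–6 and loop
  1–5 nt; (ii) 2 nt loops with *L* = 2–6 and *N* = 4–7 — deduplicated and
  instantiated at the DNA and RNA levels: 80 components. Loops are G-free
  with balanced A:T:C composition (deterministic cyclic fill), or fixed
  (all 27 three-letter permutations for loop scans).
* **PQS gate and disabled mutants.** A putative quadruplex-forming
  sequence scanner (≥ 4 all-G tracts of a common length ≥ *min_tract*,
  loops 1–7 nt, longest-chain dynamic program) plus the minimal set of
  G→A substitutions that abolishes detection — length-preserving disabled
  controls.
* **Chassis assembly.** A standardized 98 bp control unit (41 bp hCMV-IE1
  core promoter + 57 nt 5'UTR) with TSS-relative coordinates (no 0).
  DNA-level motifs insert reverse-complemented (template strand) at
  negative positions, RNA-level motifs verbatim at positive positions;
  defaults −1 and +6. Transcript derivation and upstream-AUG screening
  catch loop variants (AAU/UAU/CAU) that create alternative start codons.
* **Activity model.** OLS from the normal equations:
  `REU = β0 + β1·L + β2·N + β3·loop + ε`, with R², F-test, clipped
  prediction, Pearson correlation (t-transform p), standardized-residual
  outlier screening, >20 REU-reduction classification, and cross-context
  mean-shift estimation.
* **Two-level synergy.** `REU_combined = REU_DNA × REU_RNA / 100`, with
  deviation reports against a ±12 REU agreement band.
* **HC:LC ratio design.** A 5 × 5 encoded-ratio space (component REUs 10,
  30, 50, 70, 100 for each antibody chain), argmax-titer optimum and
  design-rule extraction.
* **Synthetic data.** A seeded generator emulating replicate REU
  measurements (truth model + Gaussian noise), context shifts (HEK +7,
  HepG2 +17 REU), bounded dual-controller deviations, and a titer surface
  peaking at encoded ratio 0.5 — so every stage above is testable offline.

## Worked example

```r
library(g4tune)

lib <- enumerate_library()            # 80 component specs, DNA + RNA
motif <- assign_loops(spec_from_row(lib[31, ]), "balanced")
motif
#> <g4_motif> DNA DNA:G3x7:L2.2.2.2.2.2 (33 nt)
#>   GGGATGGGCAGGGTCGGGATGGGCAGGGTCGGG

cfg  <- generator_config(seed = 7)    # simulated assay in lieu of wet-lab REUs
acts <- simulate_activities(lib, cfg)
head(acts[, c("component_label", "tract_length", "tract_count",
              "loop_length", "reu_mean", "reu_sd")], 4)
#>   component_label tract_length tract_count loop_length  reu_mean   reu_sd
#> 1       DNA.90REU            2           4           1  87.66030 9.416398
#> 2       DNA.85REU            2           4           2  87.11626 1.579223
#> 3       DNA.95REU            2           4           3  96.30640 2.213291
#> 4      DNA.105REU            2           4           4 106.91161 5.305916

fit <- fit_activity_model(acts, "DNA")
fit
#> <g4_activity_model> DNA level, n = 40
#>    intercept tract_length  tract_count  loop_length
#>     145.3872     -12.9477      -8.9851       4.0092
#> R-squared 0.9841, F = 741.59 (p = 2.1e-32)

predict_reu(fit, c(4, 5, 2))          # a G4x5 motif with 2 nt loops
#> [1] 56.7                            # ~57% of control expression

predict_combined(45, 50)              # DNA.45REU + RNA.50REU dual controller
#> [1] 22.5

opt <- find_optimum(simulate_titer_surface(build_design_space(), cfg))
opt$best
#>   hc_component lc_component reu_hc reu_lc encoded_ratio    titer
#> 1    DNA.50REU         BPCU     50    100           0.5 1287.546
```

Reading the output: each component is named for the level it acts at and
the REU it encodes (`DNA.90REU` ≈ 90% of control). The fitted coefficients
say every extra guanine per tract costs ~13 REU and every extra tract ~9
REU, while longer loops weaken inhibition (+4 REU/nt); R² ≈ 0.98 on this
synthetic panel. The dual controller combining a 45-REU DNA element with a
50-REU RNA element is predicted at 22.5 REU, and the best antibody titer on
the simulated surface sits at an encoded HC:LC ratio of 0.5 (1:2).

A thin command-line wrapper over the same functions ships in
`inst/cli/g4tune.R` (`design`, `scan`, `combine`, `ratio`, `simulate`
subcommands).

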