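---
title: "Designing synthetic G-quadruplex expression controllers with g4tune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing synthetic G-quadruplex expression controllers with g4tune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4tune)
```

## The design problem

G-quadruplexes (G4s) are four-stranded secondary structures that fold from
guanine-rich nucleic acid sequence: four G-tracts, each contributing a strand
segment to stacked G-tetrads, separated by short loops. Placed at the right
position in a core promoter (acting in DNA, on the template strand) or a
5'UTR (acting in the mRNA), a G4 sterically hinders the transcriptional or
translational machinery and thereby *reduces* protein output by an amount
that tracks the stability of the structure. That makes G4s attractive as
tunable expression controllers for bioindustrial cassette design: a library
of motifs with graded inhibitory strengths gives a dial for protein
expression, usable at two levels (transcription and translation) at once.

`g4tune` implements the computational side of building and evaluating such a
library:

1. **motif design** — full-factorial enumeration of motif specifications,
   loop-sequence realization, minimal disabled-mutant design, activity-based
   naming;
2. **PQS detection** — a putative quadruplex-forming sequence scanner used as
   a binary design gate plus a monotone propensity score;
3. **cassette assembly** — a standardized 98 bp core-promoter/5'UTR chassis
   (BPCU) with strand-aware insertion semantics, transcript derivation, and
   an upstream start-codon screen;
4. **activity modeling** — a three-feature linear model of component
   activity, correlation statistics, classification, outlier screening, and
   cross-context shift estimation;
5. **synergy** — the multiplicative two-level dual-controller predictor;
6. **ratio design** — a heavy-chain:light-chain (HC:LC) design space for
   multichain products;
7. **synthetic data** — a generator that emulates the measurement structure
   of relative expression unit (REU) assays so the whole pipeline is
   testable without wet-lab data.

Activity is expressed throughout in REU: protein output as a percentage of
the unengineered chassis control, so 100 means "no effect" and smaller
numbers mean stronger inhibition.

## Motif enumeration and loop realization

A motif spec has four design parameters: level (DNA/RNA), G-tract length,
G-tract number, and per-loop lengths. Two complementary full-factorial
strategies span the design space while keeping it assayable:

* strategy (i): 4 tracts, tract length 2–6 nt, uniform loop length 1–5 nt
  (25 specs);
* strategy (ii): 2 nt loops, tract length 2–6 nt, 4–7 tracts (20 specs).

The strategies overlap where loop length is 2 and tract number is 4 (5
specs); removing exact duplicates leaves 40 specs per level, 80 components
over both levels:

```{r}
lib <- enumerate_library()
nrow(lib)
table(lib$level)
```

Within strategy (i) every loop in a motif shares one length: the strategy
exposes a single loop-length parameter, and heterogeneous loops — although
representable by `g4_spec()` — are deliberately not enumerated by default.

Loops never contain G (a G in a loop could recruit into a tract and change
the structure), so they are drawn from {A, T, C} (or {A, U, C} in RNA). The
default `balanced` policy fills the concatenation of all loop positions with
a cyclic A, T/U, C pattern 5'→3'. This is deterministic and keeps the three
nucleotides within one count of each other in every construct; when the
total loop length is not divisible by 3, the earlier letters in the cycle
receive the extra copies. Published libraries of this kind use equal A:T:C
loop composition but do not prescribe the exact strings, so the cyclic rule
is this package's own deterministic choice; measured libraries with known
loop sequences can be realized with the `fixed` policy instead.

One widely used reference architecture is "motif 13", (G4N3)3G4 — four G4
tracts with three 3 nt loops. Note that the same architecture is sometimes
quoted with G3 tracts (`GGGATCGGGATCGGGATCGGG`); both render fine:

```{r}
assign_loops(g4_spec("DNA", 4, 4, 3), "fixed", "ATC")$sequence
assign_loops(g4_spec("DNA", 3, 4, 3), "fixed", "ATC")$sequence
```

`enumerate_loop_variants()` produces all 27 three-letter loop permutations of
such a spec, the panel used to probe loop-composition effects.

## PQS detection and disabled mutants

The scanner answers one question: does a sequence still contain a plausible
quadruplex-forming arrangement? A hit is ≥ `min_tracts` all-G windows of a
common length ≥ `min_tract`, consecutive windows separated by 1–`max_loop`
nt. For each tract length a longest-chain dynamic program over candidate
tract starts reports maximal chains, so a hit is found whenever *any* valid
decomposition exists (the test suite checks this equivalence against an
exhaustive brute-force oracle). Defaults are `min_tract = 2` (the smallest
designed tract), `max_loop = 7`, `min_tracts = 4`. Loops may themselves
contain G (a long G-run is legitimately PQS-positive).

The propensity score is a documented closed form,
`3·tract_length + 2·n_tracts − mean(loop_length)`: strictly increasing in
tract length and number, strictly decreasing in mean loop length, matching
the direction in which those features drive inhibitory strength. It is a
ranking device only. A G-score in the style of dedicated quadruplex mappers
is intentionally not reimplemented here — for mutant design the detector is
used purely as a binary gate.

Disabled mutants preserve length and maximize sequence similarity: the
smallest set of G→A substitutions after which the detector reports nothing,
found by exhaustive search over substitution counts k = 1, 2, …
(5'-most substitution set preferred among ties, explicit failure beyond
`max_substitutions = 6`). For mutant design the detector's `min_tract` is
set to the parent's designed tract length, so a single G→A inside a tract
removes that tract from consideration. Note the minimal count is not always
"tracts − min_tracts + 1": breaking two *interior* tracts can push the
surviving tracts farther apart than `max_loop`, disconnecting the chain, so
the exhaustive search sometimes finds a smaller solution than tract
arithmetic suggests.

## The BPCU chassis and insertion semantics

The chassis is a 41 bp hCMV-IE1 core promoter fused to a 57 nt 5'UTR
(98 bp total). Two flags matter:

* the packaged UTR is a **synthetic placeholder** — the authentic
  bioproduction UTR is proprietary. The placeholder is guanine-free and
  ATG-free, so it cannot form quadruplexes, introduce start codons at motif
  junctions, or otherwise interact with inserted motifs. Licensed users
  supply the real sequence via `assemble_bpcu(utr = ...)`.
* the packaged 41 bp core is the TATA-box region of the widely distributed
  hCMV-IE1 promoter; it too is user-replaceable.

Coordinates are TSS-relative with no position 0: +1 is the first UTR base,
−1 the last promoter base. An insertion at coordinate *p* places the motif
immediately 3' of the nucleotide at *p*, so −1 sits between promoter and
TSS and +6 sits six bases into the UTR — the two positions at which G4s are
most inhibitory in this chassis, and the defaults throughout. Whether "+6"
should count from the transcript 5' end or a UTR landmark is not externally
fixed; the TSS-anchored reading is adopted and documented here. The full
candidate panel (`candidate_sites()`: 7 DNA + 6 RNA sites) beyond the two
optima is an editable configuration, not an assertion.

Strand semantics follow the level: DNA-level motifs act on the **template**
strand, so the coding strand receives the reverse complement (a C-rich
insert); RNA-level motifs must appear in the mRNA, so they are inserted
verbatim into the UTR. `transcript_of()` returns everything downstream of
the TSS in the RNA alphabet, and `scan_upstream_starts()` reports AUGs
upstream of the intended start codon. Only AUG is screened: loop variants
that flank a G-tract with `..AU` (AAU, UAU, CAU) create upstream AUGs, and
near-cognate starts are out of scope.

## The activity model

Component activity is modeled as
`REU = β0 + β1·tract_length + β2·tract_count + β3·loop_length + ε`,
with mean loop length as the loop summary — for the factorial strategies
every loop in a motif shares the designed value, so the mean equals that
parameter. The fit is ordinary least squares solved from the normal
equations (rank-deficiency is reported naming the collinear feature), with
R² and the overall F-test; `lm()` is used in the tests only as an
independent cross-check. Predictions are clipped to [0, 120] REU — mild
activation above the control has been observed (up to ~107%), hence
headroom above 100.

Supporting statistics follow the same implemented-not-delegated rule:
`pearson_r()` is the product-moment closed form with the t-transform
p-value, and `outlier_screen()` flags internally studentized residuals with
|z| > 2.5 (the method is standard; the cutoff is this package's
documented choice). `classify_components()` separates structure-acting
components from insertional-only effects at a strict >20 REU reduction,
the upper edge of the generic insertional band observed for disabled
mutants. `context_shift()` estimates the mean REU offset between paired
panels measured in two cell hosts. p-values are reported but never drive
automated decisions.

## Two-level synergy

Transcriptional and translational controllers act on sequential stages, so
their fractional effects multiply:
`REU_combined = REU_DNA × REU_RNA / 100`. The formula is exact by
definition here — no interaction term is ever refit — and
`evaluate_matrix()` reports each observation's deviation plus a flag at the
±12 REU agreement band (configurable), the band within which measured
dual controllers have been found to sit.

## HC:LC ratio design

For two-chain products, `build_design_space()` crosses component strength
levels for heavy and light chains (defaults 10, 30, 50, 70, 100 REU — four
G4 strengths plus the unengineered chassis — giving 25 points). The encoded
ratio is the REU quotient at equal gene copy numbers; copy-number
rebalancing is out of scope. `find_optimum()` returns the argmax-titer
point (ties: lowest HC REU, then lowest ratio) and two design rules read
off the surface: the titer-vs-LC correlation in every HC row, and the
HC-level peak in every LC column. "Optimal ratio ~1:2" is interpreted as
encoded ratio 0.5 on this grid.

## What the generator emulates — and what it does not

`generator_config()` fixes the simulator's ground truth:

| parameter | default | units / meaning |
|---|---|---|
| `truth_intercept` | 145 | REU of a hypothetical feature-free motif |
| `truth_betas` | (−13, −9, +4) | REU per nt tract length, per tract, per nt loop |
| `noise_sd` | 5 | replicate SD, REU |
| `n_replicates` | 3 | draws per measurement |
| `reu_bounds` | (0, 110) | truncation, covering the observed 4–107% range |
| `context_shifts` | HEK +7, HepG2 +17 | mean REU offsets vs CHO |
| `dual_noise_halfwidth` | 10 | uniform dual-controller noise, inside the ±12 band |
| `titer_params` | peak 0.5, exponent 1.5, penalty 10, noise 3% | titer surface shape |

The truth coefficients were calibrated once against the printed dynamic
range of measured libraries (DNA components spanning ~11–107 REU, RNA
~4–90): with these defaults the 40-spec library spans 12–103 REU
noiselessly. They are frozen; moving them per-analysis would defeat their
role as ground truth. Replicate noise is Gaussian with SD 5 REU — published
figures show error bars but no numeric SDs, so this is a configurable
assumption, not an asserted fact. Dual-controller noise is *uniform* and
bounded (half-width 10 < 12) precisely so the ±12 band is provable rather
than probabilistic; a Gaussian alternative would be realistic but makes the
band a tail event.

The titer surface is
`titer ∝ (REU_LC/100)^1.5 · exp(−10·(ratio − 0.5)²)`, normalized so the
both-chains-unengineered point defines 100%. It encodes the three
qualitative rules a two-chain optimization is expected to show — titer
rises with LC strength at every HC level, the surface peaks at encoded
ratio 0.5, and HC must be controlled precisely (the LC = 100 column peaks
at an interior HC level). The sharpness (penalty 10) is chosen so the
optimum is recoverable by a single-point argmax at titer noise up to 5% of
the peak across 100 seeds — a robustness property the package's tests
enforce. Two consequences are deliberately stylized: the peak sits roughly
an order of magnitude above the mis-ratioed control (measured mAb surfaces
are flatter), and cells at extreme ratios (e.g. HC 100 / LC 10) underflow
to numerically zero titer.

More generally, the generator emulates *measurement structure* — feature
monotonicity, replicate noise, context offsets, bounded multiplicative
deviations, a peaked titer surface — and none of the biology the features
stand for: no folding topology, no thermodynamics, no flanking-sequence
kinetics, no single-cell heterogeneity (population means only). Pipeline
tests passing on generated data therefore demonstrate the *software*
recovers planted structure under the assumed noise; they say nothing new
about real cells.

## Numerical choices and degenerate inputs

* REU labels round to the nearest 5 with halves rounding up
  (`floor(x/5 + 0.5)·5`), since measured component names are multiples
  of 5; label collisions get `.2`, `.3`, … suffixes in registration order.
* The mutant search cap (6 substitutions) is an explicit failure, never a
  silent partial mutant; PQS-negative input to `design_mutant()` is a
  precondition error.
* `find_pqs()` on an empty or G-free sequence returns an empty hit table;
  invalid characters are rejected naming the offending position; mixed
  T/U alphabets are rejected.
* OLS needs ≥ 5 records and a full-rank design; strategy-(i)-only records
  (constant tract count) are intentionally rank-deficient and error.
* `pearson_r()` on constant input errors rather than returning NaN;
  |r| = 1 reports p = 0.
* All simulators call `set.seed(config$seed)` on entry: identical
  (seed, config) gives byte-identical output tables.

## Problem sizes

The shipped tests fit models on the 40-spec per-level library (200
replicates for recovery checks), compare the scanner with the exhaustive
oracle on 1,000 random sequences of up to 60 nt, verify mutant minimality
by exhaustive substitution search on motifs up to 30 nt, and re-run the
ratio-optimum recovery over 100 seeds; the full suite completes in well
under a minute on one CPU. These sizes were chosen as the smallest at which
the properties are meaningfully exercised.

## Known limitations

* The PQS gate is structural, not thermodynamic: no G-score, G4Hunter
  score, topology, or melting prediction.
* The packaged chassis sequences are stand-ins; conclusions about a real
  construct require the licensed sequences.
* The activity model is linear in three features; interactions and
  loop-composition effects are out of model by design (composition has
  little effect except through start-codon creation).
* Cross-context behavior is modeled as a mean shift plus noise; real
  context effects can be component-specific.
* The exact coordinates of historical insertion-site panels are not
  asserted; only −1/+6 are fixed by the positioning analysis.
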