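---
title: "guidekit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{guidekit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidekit)
```

guidekit is a computational companion to a GoldenGate (MoClo-compatible)
CRISPR mutagenesis toolkit for barley and wheat that combines Cas9 and Cas12a
nucleases with multiplexed guide arrays. The package covers the four
computational tasks around such a toolkit: choosing targets and writing
cloning oligos, planning and verifying the hierarchical cloning itself,
quantifying editing outcomes from amplicon sequencing, and summarising
efficiency statistics across constructs. This vignette records the models,
parameter choices and their rationale, and what the synthetic test data do
and do not establish.

## Target scanning and oligo design

Cas9 targets are 20-nt protospacers followed 3' by an NGG PAM; Cas12a targets
lie 3' of a TTTV PAM (V = A/C/G). `scan_targets()` reports every position on
both strands where a full-length protospacer window abuts a matching PAM.
IUPAC codes in the PAM pattern are honoured; an `N` in the *sequence* never
matches, either in the PAM or the protospacer, so ambiguous reference bases
cannot produce spurious guides. Minus-strand sites are reported in their own
reading orientation with `start` giving the leftmost forward-strand offset of
the protospacer footprint (0-based), so reverse-complementing
`[start, start + length)` reproduces the protospacer.

Two scanning choices were genuinely open:

* **Cas12a protospacer length.** Published Cas12a arrays use spacers of
  roughly 20-24 nt; the toolkit's own worked example is 23 nt. The default is
  23 and the length is configurable via `nuclease_spec()`.
* **5' base requirements.** Pol III promoters are often used with a 5' G
  (U6) or A (U3) appended to the spacer. The toolkit's own printed example
  protospacer begins with T, so no 5'-base constraint is imposed or
  auto-corrected; users who want a transcription-initiating base can include
  it in the protospacer.

Cut offsets are used only to centre the default amplicon cut window: Cas9 is
modelled as a blunt cut 3 bp 5' of the PAM; Cas12a as a staggered PAM-distal
cut after protospacer positions 18/23 (top/bottom). Both are configurable;
nothing else in the package depends on them.

`design_oligo_pair()` writes level-1 cloning oligos as
`forward = fwd_overhang + protospacer` and
`reverse = rev_overhang + revcomp(protospacer)`. The overhangs are fixed by
the accepter architecture: `CTTG/AAAC` for the TaU6 Cas9 accepter,
`AGCA/AAAC` for the TaU3 and HvU3 accepters, `AGAT/GGCC` for Cas12a V2
(ribozyme-separated) and `AGAT/ATTA` for Cas12a V3 (tRNA-separated) arrays.
A protospacer that itself contains a BsaI/BpiI recognition motif triggers a
warning, because it would leave a re-cuttable site in every downstream
product. Architecture B (ribozyme) and C (CSY4) Cas9 oligo templates are out
of scope: their oligo chemistry is not part of the toolkit's level-1
accepters.

## Assembly planning

The planner encodes the toolkit's routing rules:

* Oligo pairs go into level-1 guide accepters with **BsaI**.
* With 1-4 guides, loaded level-1 cassettes go directly into the level-2
  binary vector with **BsaI + BpiI**.
* With more than 4 guides, cassettes are packed into intermediate level-M
  vectors with **BpiI** (up to 4 per vector), and level-M modules are then
  combined in the level-2 step with **BsaI + BpiI**.

Packing is greedy (fill each level-M vector to 4 before opening the next):
the toolkit bounds per-step inserts at 4 but does not prescribe a packing, so
the deterministic strategy that minimises the number of level-M vectors was
chosen over balanced packing. Capacity is 26 guides per final vector, taken
from the toolkit's vector-choices documentation as a named constant rather
than derived. Position bookkeeping uses integer GoldenGate positions 1-7 per
level.

Promoters along a tandem array alternate between the U6 class (TaU6) and the
U3 class (TaU3/HvU3), because repetitive tandem pol III cassettes recombine
in *E. coli*; explicit preferences are honoured and a warning is emitted when
they force adjacent same-class promoters. With both nucleases on one T-DNA
(the dual barley vector), Cas9 and Cas12a guides form two consecutive
sub-arrays, each packed independently, mirroring how co-mutagenesis
constructs are organised.

The nine binary vectors form a complete matrix over species (barley/wheat),
nuclease cassettes (Cas9, Cas12a, or both — the dual option exists only in
barley) and, in wheat, GRF-GIF or dexamethasone-inducible GR-GRF-GIF
transformation boosters. `choose_binary_vector()` is an exact lookup; an
unsupported combination errors with the nearest supported configurations.

## In silico digestion-ligation

`simulate_reaction()` answers "is this design correct", not "what is the
yield": methylation sensitivity, partial digestion and ligation kinetics are
deliberately not modelled. Double-stranded DNA is represented by its top
strand; 4-nt 5' overhangs are stored as top-strand text so that two
fragments ligate exactly when one's right overhang text equals the other's
left overhang text. BsaI (GGTCTC, 1-nt spacer) and BpiI (GAAGAC, 2-nt
spacer) geometries are the standard enzyme definitions. Digestion of
circular parts rotates the molecule to the first cut; ligation requires a
unique closed chain over all selected fragments — any overhang occurring
twice among the available 5' ends is reported as ambiguous and no product is
formed. Failures are always diagnostics, never errors, except for geometric
impossibilities (cut sites so close their overhangs overlap).

Backbone selection follows the toolkit's colour selection logic rather than
fragment size: the accepter fragment *lacking* the `dropout` annotation
(lacZ in levels 1/M, RFP in level 2) is the backbone, and insert fragments
*lacking* a `backbone` annotation are the cargo. After ligation the product
is checked for residual recognition sites — the defining invariant of
one-pot GoldenGate is that correct products can no longer be cut.

Because the physical AddGene plasmids are not distributed with the package,
`plan_parts()` fabricates minimal synthetic accepters, end linkers and oligo
duplexes for any plan. The inter-position fusion overhangs are invented,
fixed 4-mers (the toolkit's physical fusion sites are not published) and the
filler sequences are seeded random DNA screened against recognition motifs.
A random junction can still recreate a motif across segment boundaries, so
`simulate_plan()` regenerates fillers from a derived seed until the full
plan simulates cleanly; the result is deterministic given the seed. These
parts are explicitly synthetic stand-ins: simulations verify the *logic* of
a plan (routing, overhang closure, irreversibility), not the sequence of any
physical plasmid.

## Amplicon mutation calling

The caller re-implements the deposited amplicon pipeline's logic on aligned
read pairs (any SAM-producing mapper upstream; bwa mem with defaults was
used for the original data):

1. **Boundary inference** — amplicon boundaries are the modal lower/upper
   mate start positions per locus (`modal_starts()`), ties broken toward the
   smaller coordinate; fixed boundaries can be supplied instead.
2. **Boundary filtering** — only pairs with *both* mates starting exactly on
   the boundaries are usable. A deletion extending past a mate's start
   shifts the mapped start and excludes the pair; this is a documented
   consequence of the filter, inherited from the original design.
3. **Pattern extraction** — each mate's CIGAR is walked in reference
   coordinates; insertion and deletion operations intersecting the cut
   window are collected into a canonical pattern key. The pattern comes from
   the mate overlapping the window; when both mates overlap and disagree the
   pair is flagged discordant and the union pattern counts as mutant (the
   original pipeline is silent on this case).
4. **Reporting** — `pct_wt = 100 * wt / usable` and its complement, plus the
   per-pattern spectrum. With zero usable pairs the percentages are `NA` and
   flagged, not an error.

Parameter choices: the cut window defaults to the cut site ± 15 nt —
real NHEJ indels cluster at the cut while indels at read ends are usually
alignment artefacts; the window is configurable and nothing is subtracted
from the reported percentages (wild-type controls show a few percent
artefact floor; interpreting that floor is left to the analyst). Insertions
count as mutations by default because NHEJ frequently yields +1 insertions;
`deletions_only = TRUE` restores the strictly deletion-based behaviour of
the original script. Internally all coordinates are 0-based half-open;
SAM's 1-based starts are converted on input and report positions are printed
1-based.

`sanger_classify()` covers capillary screening: a global affine-gap
alignment (match +2, mismatch −1, gap open 6, gap extend 1, via Biostrings)
of the base-called read against the wild-type reference; a read is mutated
iff an alignment gap intersects the cut window. Substitutions never flag
mutation — capillary base-calling errors are overwhelmingly substitutions.

## Efficiency statistics

Editing proportions are analysed with a logit-link binomial GLM
(`stats::glm`, i.e. IRLS) on (construct, gene) count tables; factor effects
are tested by likelihood-ratio chi-squared between nested fits
(`chi2 = deviance(null) − deviance(full)`). Separation (cells at 0% or
100%) is tolerated with a warning because the deviance-based tests remain
usable. Per-plant mutant-allele percentages are analysed by sequential
(type-I) crossed ANOVA, `Gene * Variant` against the residual, with
treatment contrasts and terms in the supplied order. No multiple-testing
correction is applied; raw p-values are reported.

Summaries follow the reporting conventions of T0 screens: per-gene
efficiency `100·k/n`; construct mean = unweighted mean over genes; its
standard error = SD of gene-level percentages / √(#genes) (the natural
reading of "standard errors of mean efficiency averaged over genes"); the
all-targets rate = percentage of plants mutated in *every* targeted gene.
The all-targets rate can never exceed the weakest per-gene rate, and under
perfectly nested outcomes it equals it. Display rounding is to whole
percent; machine-readable outputs keep raw values. When only mutant-allele
percentages are available, plants are scored mutated above a configurable
threshold (default 10%, chosen above the few-percent artefact floor of
wild-type controls; the threshold is a package choice, not a measured
constant).

`synergy_decomposition()` formalises the two-feature enhancement argument
(e.g. the D156R point mutation and intron insertion in Cas12a): with
efficiencies for the baseline, each single feature and the combination, the
synergy is `combined − (base + Δa + Δb)`. When the additive expectation
exceeds 100% the decomposition is flagged saturated — the combined gain
cannot be separated from ceiling effects, which is exactly what happens at
permissively edited loci.

## Synthetic data: what it shows and what it does not

`make_reference()` places G/C bases by exact quota, so GC content is exact,
and all generators are seed-deterministic (identical seeds give
byte-identical output). `simulate_edited_reads()` emits proper SAM pairs
whose mate-1 carries the requested indel (consistent CIGAR and SEQ) and
whose mate-2 matches at the right boundary; pattern frequencies are realised
by largest-remainder quotas so truth fractions are *exact*, which makes
caller recovery tests sharp rather than stochastic. Substitution errors
modify SEQ only — by construction they can never register as indels, which
is what the substitution-robustness tests verify. Off-boundary pairs
(shifted mate-1 starts) model library artefacts rejected by the boundary
filter.

`simulate_t0_cohort()` offers two outcome models. The `nested_activity`
model draws one latent per-plant activity `a ~ U(0,1)` and mutates gene `g`
iff `a < e_g`; it is our single-latent-variable encoding of the empirically
observed nesting (plants edited at hard targets are edited at easy ones), so
the all-targets rate equals the minimum per-gene efficiency. The
`independent` model drops that coupling, driving the all-targets rate toward
the product of efficiencies — useful as a contrast, not as a claim about
real plants.

None of the simulators model realistic sequencing-error spectra, quality
scores, chimeric reads, mapping ambiguity or primer artefacts. Passing tests
therefore demonstrate correctness of the pipeline's logic and arithmetic on
well-formed alignments, not robustness to every pathology of real amplicon
data.

## Problem sizes and numerical choices

The test-suite and acceptance problem sizes were chosen to make binomial
noise negligible relative to the effects checked: 200 read pairs per
simulated locus (3 binomial SE at f = 0.5 is ≈ 10.6 points, but quota
sampling makes recovery exact); mutant-fraction grid {0, 0.1, 0.5, 0.7,
0.9, 1}; 1,000 replicates for the type-I-error calibration of the LRT
(binomial SE ≈ 0.7 points around the nominal 5%); 500 replicates for the
power check; worked-example cohorts sized so the reported per-gene
percentages are realised by integer counts (e.g. n = 50 for 98/94/92%,
n = 100 for a 68% all-targets construct). ANOVA agreement with a
projection-matrix computation is required to 1e-8; GLM deviances against a
direct likelihood maximisation to 1e-6. Ties in modal-start inference break
toward the smaller coordinate; degenerate inputs (zero usable pairs, empty
design cells, unsupported vector combinations) return flagged results or
named errors as documented on each function.

## Known limitations

* The planner's position bookkeeping assumes up to 7 positions per level; it
  does not model end-linker part numbers of the physical kit, only their
  function.
* The assembly simulator ignores enzyme fidelity: overhangs either match
  exactly or not at all, so near-cognate ligation (a real failure mode of
  large one-pot reactions) is invisible.
* The caller trusts the upstream aligner; soft-clipped or split alignments
  are excluded rather than re-aligned.
* The GLM treats plants as independent Bernoulli trials within cells;
  construct-level random effects (e.g. transformation batch) are out of
  scope.
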