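---
title: "Methods: calling, pairing and comparing sense-antisense transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling, pairing and comparing sense-antisense transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascons)
```

# The analysis in one paragraph

Antisense RNAs — non-coding transcripts running opposite a protein-coding
gene and overlapping it — are widespread in budding yeasts, and one proposed
mode of action is *inverse expression*: when the cell moves from mid-log
growth (ML) into early stationary phase (ES) or heat shock (HS), the sense
transcript goes down while its antisense partner goes up, or vice versa.
`ascons` implements the full computational chain needed to ask whether this
behaviour is conserved between two related species: discover transcript
units from strand-specific read depth, quantify them (BPKM), couple sense
ORF transcripts with opposite-strand non-coding RNAs, score how similar the
overlap geometry of a homologous pair is in the two species, classify
inverse expression changes per condition, and test whether geometrically
conserved pairs are enriched for inverse expression.

# Transcript-unit calling

Depth tracks are per-base, per-strand counts of *fragments* (each properly
paired template is one molecule, spanning mate to mate; counting reads
would count every molecule twice). The caller iterates four steps on each
strand of each chromosome:

1. **Seed** at the unmasked position of maximal depth; seeds need depth
   ≥ `min_seed_depth` (default 5). Ties go to the leftmost position, with
   chromosomes processed lexicographically and `+` before `-` — the
   procedure needs an explicit tie-break to be deterministic.
2. **Grow** one base at a time, alternating directions (upstream first,
   recomputing the running mean after every accepted step; a stopped
   direction stays stopped). A direction stops when the unit's mean depth
   is at least `edge_ratio` (default 4) times the depth of the next
   position past the boundary. Positions beyond the chromosome end or
   inside an already-called unit count as depth 0, so the rule always
   stops there.
3. **Reassign** each stopped boundary once to cover the full span of every
   same-strand fragment containing the boundary base. The extension is
   clamped at previously masked bases: without the clamp a long fragment
   could drag a unit into its neighbour and break the caller's core
   invariant that units on one strand never overlap.
4. **Mask** the unit and repeat until no eligible seed remains.

Masking is strand-specific on purpose: a sense unit must not prevent an
antisense unit from being called over the same bases, because that overlap
is the object of study.

Two readings of the procedure were genuinely open. Growth could alternate
or run one side to exhaustion first; alternation is the symmetric reading
and is what the naive reference implementation in the test suite encodes
too. Boundary reassignment could cascade (re-extend through fragments
touching the *new* boundary); a single pass per end is the minimal reading
and makes termination trivial. `min_length` defaults to 1 — no minimum —
and is configurable.

# Quantification and classification

`BPKM = B / ((L/1000) · (T/10^6))`, with `B` the summed same-strand depth
over the unit, `L` its length and `T` the library's total mapped bases.
BPKM is length-additive (splitting a unit gives halves whose
length-weighted mean is the whole), which the tests assert.

Classification against the ORF annotation: same-orientation overlap (≥ 1
base) with a verified or uncharacterized ORF makes a unit an ORF-T; a unit
whose only same-orientation overlaps are with ORFs of any other status
(dubious ORFs, miscellaneous features) is classed `other`; everything else
is an ncRNA. The `other` class is a documented interpretation — annotation
conventions vary — and units in it take no part in pairing.

Pairing couples every ORF-T with every opposite-strand ncRNA overlapping it
by at least one base; an ncRNA spanning two ORF-Ts yields two pairs with
the larger overlap flagged primary. The working set for all cross-species
statistics keeps pairs whose four members (sense and antisense, both
species) have BPKM above `min_bpkm` (default 0, i.e. any expression) in all
three conditions. The floor is configurable because "expressed" could
defensibly mean more than "non-zero"; 0 is the least arbitrary default.

Units are called once per species on coverage pooled over the three
conditions, then quantified per condition. Calling per condition would give
three incompatible unit sets and make fold changes ill-defined; pooling is
the standard resolution and only strengthens seeds.

# Conservation score and enrichment

For a homologous pair, `C_i = O_i / L_i` is the fraction of species *i*'s
sense transcript covered by its antisense partner, and

`S = min(C_Sc, C_Sp) / mean(C_Sc, C_Sp)`,

defined as 0 when both fractions are 0. `S` is symmetric in the species,
lies in [0, 1], equals 1 exactly when the fractions agree, and ignores
sequence identity — it measures geometry only. Pairs with `S > 0.8`
(stringent) are contrasted with `S < 0.5` (background).

Inverse expression is classified per species and condition from fold
changes relative to ML. The direction categories use the loose rule
(sense < 1 and antisense > 1, or the mirror); significance applies the
1.5-fold threshold to **both** members (`sense_fc ≤ 2/3` and
`antisense_fc ≥ 1.5`). Requiring both members is the stricter, symmetric
reading of "at least a 1.5-fold change"; a flag (`mode = "either"`)
relaxes it. A pair's inversion is *conserved* in a condition when both
species show a significant inversion of the same direction in that
condition.

The enrichment contrast builds, among pairs inverse in at least one
species, the 2×2 table (stringent vs background geometry) × (conserved vs
species-specific inversion) and applies Fisher's exact test, two-sided by
default: enrichment can point either way in a given condition, and a fixed
one-sided test would encode the answer into the method. The companion
one-sided two-sample proportion test (normal approximation with continuity
correction) contrasts the conserved proportions between HS and ES; its
counts are explicit arguments because the appropriate denominators depend
on the question asked of a given data set.

Expression variation between species is `|log2 e_Sc − log2 e_Sp|` (base 2
documented; the magnitude depends on it). Correlation matrices use
`log10(BPKM + pseudocount)` with pseudocount 0 — correlations are
base-invariant, and the working set is pre-filtered positive. The
distribution-shift test is a one-sided Wilcoxon rank-sum on log BPKM
(condition vs ML), exact for small samples without ties.

# Metagene profiles

Each gene's body (called unit boundaries by default; the annotation-based
alternative is available by passing ORF intervals instead) is split into
200 equal intervals, each contributing the mean per-base depth; 100 nt
flanks contribute per-base values. Mean-per-interval is the only statistic
consistent with interpreting the profile as a density. Minus-strand genes
are flipped so index 1 is always 5′. Per-base values are put on the BPKM
scale and divided by the gene's mean sense/antisense BPKM, so strongly and
weakly expressed genes contribute comparably; genes shorter than 200 bases
or with no expression are excluded and counted. Flanks running off a
chromosome end are zero-padded. Overlapping neighbours are *not* masked
from flanks — with the generator's spacing this is moot, and on real data
masking is a policy choice left to the caller of the function.

# The synthetic-data generator

`simulate_experiment()` exists so every downstream stage has ground truth.
Its defaults define the simulated study: 200 genes of 500–2,000 bases
alternating strands along one chromosome with 500-base silent gaps (more
than twice the mean fragment length, so units are separable); 60% of genes
carry an antisense unit anchored over the sense 3′ terminus — the
characteristic position of yeast antisense initiation — extending a
50–150 base tail beyond it; half the pairs get near-identical overlap
fractions in the two species (conservation target S > 0.8, fractions
0.35–0.70 jittered ±5%) and half get disparate fractions (one species
0.08–0.18, the other 0.55–0.90, giving S < 0.5). Log2 expression is
Gaussian with mean 1 (sense) or 0 (antisense) and SD 0.8 / 1.1, composed
of a gene effect shared everywhere, a condition effect shared between
species, a species effect and a residual, with shares set so the
within-condition cross-species correlation hits 0.85 (sense) and 0.5
(antisense) — antisense transcription is the more divergent, the ordering
the analysis must detect. 15% (ES) and 25% (HS) of pairs are planted with
an exact inverse change in both species: sense divided by `fold = 2`,
antisense multiplied by it; 2 comfortably exceeds the 1.5-fold detection
threshold while staying within a biologically ordinary range. Fragment
counts are Poisson with mean `depth_scale · expression · L/1000`
(`depth_scale = 50`), lengths truncated-normal (200 ± 50, floor 50),
starts uniform within the transcript.

What the generator does **not** emulate: sequencing error, base
composition, GC or positional bias, intron splicing, overlapping gene
arrangements beyond the planted antisense, or multi-mapping ambiguity.
Passing recovery tests therefore demonstrates that the pipeline's logic is
correct under its own assumptions — clean strand separation and separable
units — not that it is robust to every artefact of real libraries.

Recovery under the defaults (asserted in the test suite at problem size
200 genes, depth scale 50, fixed seed): transcript boundaries within one
fragment-length scale (300 bases, typically a few bases in the median),
Spearman correlation of BPKM with true expression above 0.9, planted
inverse fractions recovered within three binomial standard errors
(detection noise biases recovery downward slightly: both members in both
species must clear the threshold), sense cross-species correlation above
antisense, and antisense metagene density concentrated in the 3′ half.
The caller is additionally checked against a deliberately naive, literal
reimplementation of the four-step procedure on 1,000 random depth tracks.

# Interfaces and formats

Alignments are read from SAM/BAM via Rsamtools. The transcribed strand is
resolved per library dialect: `dutp` (default — the dUTP second-strand
protocol destroys the uridine-marked strand, so mate 2 carries the
transcript's strand), `reverse` (identical for proper FR pairs) and
`forward` (mate 1). The uniqueness filter keeps templates whose `NH` tag is
1 when the tag is present and otherwise requires mapping quality ≥ 10 —
aligners disagree on how multi-mapping is recorded, so both mechanisms are
supported. Coverage round-trips exactly through per-strand bedGraph pairs;
annotations load from GFF3 (1-based inclusive) into the package-internal
0-based half-open convention; units round-trip through GFF3 with all
fields. Homology maps are two-column TSVs and must be one-to-one.

The package is function-first: `run_pipeline()` orchestrates the stages on
an in-memory experiment and `validate_config()` normalizes parameter lists
or YAML files (defaults: seed depth 5, edge ratio 4, fold threshold 1.5,
stringent cut 0.8, background cut 0.5). A shell wrapper would add nothing
over `Rscript -e` around these two calls, so none is shipped;
`scripts/acceptance.R` is the worked example of scripting the package.

# Known limitations

- The caller is not splice-aware; introns in highly expressed genes can
  split units if coverage dips below the edge ratio.
- Cross-species matching of ncRNAs has no coordinate liftover: an
  antisense unit counts as shared when both species' homologous sense
  genes carry an overlapping antisense unit. This proxy can over-merge
  distinct antisense units at the same locus.
- The proportion test's counts are caller-supplied; the package does not
  decide which denominators are appropriate for a given contrast.
- With `mode = "both"`, measurement noise near the fold threshold biases
  conserved-inversion counts downward (each of four fold changes must
  clear it); the `either` mode trades specificity for sensitivity.
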