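---
title: "Degradome-guided sRNA target prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degradome-guided sRNA target prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretarget)
```

## The biological model

Plant sRNAs direct endonucleolytic cleavage of near-complementary mRNA sites;
the cut falls between the target nucleotides opposite sRNA positions 10 and
11. Degradome (PARE/GMUCT) sequencing ligates an adapter to the uncapped 5′
ends of the 3′ cleavage fragments, so the 5′ end of a degradome tag aligned to
a transcript is direct evidence for a cleavage position. The package predicts
interactions by requiring two independent pieces of evidence to coincide:
a degradome peak at a position, and a rule-compliant sRNA–mRNA duplex
anchored there.

## Coordinate conventions

All transcript coordinates are 1-based. A tag whose 5′ end aligns at position
`p` supports cleavage at `p`; the sRNA is anchored with position 10 opposite
`p`. The candidate window covers `p − 16 .. p + 15` (32 nt), placing `p` at
window index 17. Under gap-free anchoring, sRNA position `i` pairs window
index `27 − i`; TR2 (opposite sRNA 8–14) is transcript `p + 2` down to
`p − 4`, TR1 (opposite 1–7) is `p + 9` down to `p + 3`, both read 3′→5′ and
encoded in mRNA mode. These placements are an internal convention — the
pairing geometry fixes only that `p` faces position 10 — and are used
consistently by the degradome, region and duplex modules, so any compliant
choice yields the same final predictions.

## The 2-bit encoding

Each base is two bits (sRNA: A=00, C=01, G=10, T/U=11) and a k-mer is the
integer formed by concatenating codes 5′→3′, most-significant first. The mRNA
code is the bitwise inverse, so a sRNA k-mer and the mRNA k-mer it pairs with
positionwise share one integer; all 7-mers lie in `[0, 16383]`. U is
normalised to T on input everywhere; duplexes are rendered with U on the sRNA
strand on output. Encoded values are stored as doubles (exact to 26 nt;
the accepted read lengths are far below that).

## Degradome alignment and weighted abundance

Tags are collapsed to (sequence, abundance) records, encoded, and sorted into
one ascending list per tag length (default accepted range 19–21 nt, the
typical PARE tag size). Each transcript is scanned with a rolling-window
encoding and every window value is binary-searched in the list of its length;
matching is exact and sense-strand only, since tags derive from cleaved mRNA.
A tag matching `w` transcriptome windows contributes its full abundance to
each position's raw abundance and `abundance / w` to the weighted abundance,
so one read's weighted evidence sums to its abundance across the
transcriptome. All matches are reported; there is no random assignment of
multi-mapping tags.

## Peak categories

Per transcript, with `M` the maximum positional abundance and `avg` the mean
abundance over positions with more than one read (0 if none):

| category | definition |
|---|---|
| 0 | > 1 read, unique maximum |
| 1 | > 1 read, tied maximum |
| 2 | > 1 read, above `avg` |
| 3 | > 1 read, at or below `avg` |
| 4 | exactly 1 read |

Excluding abundance-1 positions from the average stops ubiquitous background
degradation from dragging the average down and inflating category 2. The
partition is exhaustive and exclusive. The stringent pipeline default keeps
categories 0–3 and requires sRNA abundance ≥ 5.

## Targeting rules and scoring

A rule set bundles the penalties (mismatch, G:U wobble, gap), the core region
and its multiplier, the count maxima (mismatches, adjacent mismatches,
wobbles, gaps, core variants), position-10/11 permissions, optional
permissible/non-permissible mismatch position sets, and whether wobbles count
as mismatches. The `allen` preset uses mismatch 1, wobble 0.5, gap 1, core
2–13 doubled, total cutoff 4, at most 4 mismatches, 2 adjacent, 1 gap, and
requires Watson–Crick pairs at positions 10 and 11; `fahlgren_carrington`
differs only in permitting a mismatch or wobble there. Preset fields the
presets' sources leave open were fixed once as: wobble maximum 24
(effectively bounded only through the score), core count maxima equal to the
global maxima, empty position sets, wobbles not counted as mismatches, and
position-10/11 mismatch scores equal to the ordinary mismatch score. Rule
files are flat JSON with exactly these field names.

Scoring semantics chosen where the convention is genuinely open, applied
identically in the aligner, the region prefilter and the generator:

* the core multiplier applies to any penalty incurred at a core sRNA
  position, gaps included (a gap is attributed to the next sRNA position
  paired in traversal order);
* "adjacent mismatch" runs count mismatches and gaps, plus wobbles only when
  wobbles count as mismatches; a Watson–Crick match (or non-counted wobble)
  resets the run;
* when position 10 or 11 is not open, any non-Watson–Crick state there
  (mismatch, wobble, or gap involvement) rejects the alignment;
* the score cutoff is inclusive (`score ≤ max_score` passes, with a 1e-9
  floating-point guard).

## The duplex search

The search enumerates alignments depth-first from the anchor (never gapped)
toward the sRNA 5′ end, then on success toward the 3′ end, branching at each
step on pairing, skipping a window base (gap shown on the sRNA line), or
bulging the sRNA base (gap on the target line). Gaps in both strands are
allowed, jointly bounded by `max_gaps`. Every budget is checked incrementally
and violating branches are pruned, so the enumeration is exhaustive over
rule-compliant alignments. The reported alignment is the lexicographic
minimum by (score, gap count, mismatches + wobbles), with remaining ties
broken by the 5′-most difference in pair states — a deterministic,
documented choice. An sRNA whose 3′ end would overhang the 32-nt window is a
hard error rather than a silent truncation (impossible for ≤ 24-nt sRNAs
under this anchoring).

## Region rows and the three-stage filter

For a sRNA region 7-mer, `region_row()` marks every mRNA 7-mer that can pair
with it without exceeding any global budget *within the region alone* —
deliberately the full budget, not a partition of it, trading pruning power
for a guarantee: the filter never discards a candidate the aligner would
accept. With gaps enabled, the feasibility search also admits register
shifts of up to `max_gaps` positions for R1/R3 (gaps between the anchor and
the region shift its frame; each shift is charged a gap and its minimum
penalty) and treats target positions outside the 7-mer as free. R2 contains
the anchor, so its frame cannot shift. Rows of the three conceptual
16384×16384 matrices are computed lazily and memoized per (region, code,
sRNA length, rules) instead of materialising ~0.8 GB of tables; group
filtering tests only the codes actually present. The equality of on/bypassed
prediction sets is enforced by tests over randomized planted fixtures under
both presets and `max_gaps ∈ {0, 1}`. One caveat: the per-transcript
binomial p-value depends on how many candidates were *evaluated*, so that
one reported column may differ when the prefilter is bypassed; the
interaction set, scores and duplexes do not.

## Confidence filters

The MFE ratio divides the predicted duplex's hybridisation energy by that of
the perfect-complement duplex for the same sRNA; predictions below the
cutoff (default 0.7, boundary kept) are discarded. The default energy
backend is an internal nearest-neighbor model (versioned "internal-1"):
Turner/Xia Watson–Crick stack free energies at 37 °C, a flat −1.2 / −0.5
kcal/mol for stacks with one/two G:U pairs, +4.09 helix initiation, +0.5 per
mismatch and +3.0 per bulge. It is intentionally simple, fully deterministic
and bit-reproducible; it preserves the sign and ordering properties the
ratio filter relies on but does not reproduce RNAplex energies to the
decimal. When ViennaRNA's `RNAplex` binary is on the PATH it can be selected
with `energy_backend = "rnaplex"`.

The p-value filter treats a site of category `c` on a transcript whose
profile has fraction `q_c` of signal positions at category ≤ `c`:
`p = 1 − (1 − q_c)^n`, with `n` the number of candidate positions evaluated
on that transcript for that sRNA after region filtering. It is the
probability that at least one of the evaluated positions would show an
equal-or-better signal by chance. The exact parameterisation of the original
CleaveLand formulation is not published alongside its description, so this
per-transcript form is documented as this package's definition, and the
filter ships disabled by default (`pvalue_cutoff = NULL`; 0.05 is the
conventional cutoff when enabled). The MFE filter defaults to on, mirroring
standard practice.

Reads-per-million normalisation uses the post-filter retained library total
as its base; the analysis log records that total explicitly.

## The synthetic-data generator

`make_transcriptome()` draws uniform-random A/C/G/T sequences (defaults: 500–
1500 nt, GC 0.5). `plant_interactions()` selects transcripts, cleavage
positions and sRNA lengths (19–24 nt) at random, writes each sRNA as the
reverse complement of its site with a requested number of mismatch/wobble
edits (never at positions 10/11; edit placements are resampled until the
preset's budgets are satisfiable, and specs that cannot satisfy them error
out), emits degradome tags whose 5′ ends sit exactly at the cleavage
positions, and can add Poisson abundance-1 background tags, which are
category 4 by construction and separable under stringent settings. Planting
avoids sites whose tag or sRNA would trip the low-complexity input filter,
so every planted site is recoverable under default settings. A single
integer seed drives all randomness; the truth table's expected scores come
from the generator's own penalty arithmetic and its expected categories from
direct application of the category definitions — the generator never calls
the prediction code.

What the generator does *not* emulate: sequencing errors, ligation and size-
selection biases, expression-correlated degradation, isoform structure, and
real transcriptome composition (repeats, GC skew, low-complexity tracts).
Passing planted-truth tests therefore demonstrates algorithmic correctness —
recovery of every signal the rules admit, and nothing else — not predictive
accuracy on real libraries.

## Numerical and design notes

* Degenerate inputs: empty post-filter libraries and empty profiles are
  errors; transcript windows containing ambiguous bases are skipped by the
  scanner, and candidate windows touching them are dropped.
* At length 100, a sequence exceeding 75% mono-nucleotide composition always
  also exceeds the 37.5% di-nucleotide bound (a majority base forces adjacent
  pairs), so the mono rule acts as a backstop; the di- and tri-nucleotide
  boundaries are the empirically observable ones and the tests pin them at
  exactly 37.5% and 25% with strict (keep-at-boundary) semantics.
* The prediction path contains no randomness and iterates sRNAs and
  candidates in sorted order, so results are independent of input record
  order and byte-identical across runs; any parallel partitioning by sRNA
  would merge to the same canonical order.
* Replicate conservation intersects predictions by the full
  (sRNA sequence, transcript, position) triple — the strictest key, chosen
  over looser gene-level keys.
* In GFF3 mode every mRNA feature is emitted (all isoforms); UTR inclusion
  toggles exon vs CDS concatenation.
* Test and validation problem sizes were chosen to exercise each property at
  desk scale: exhaustive 16,384-column checks for one region row per region,
  ~1000 oracle-versus-aligner duplex pairs per preset family, 1000 random
  fixtures for prefilter conservativeness, and 100-site planted-truth
  recovery runs.

## Known limitations

Antisense degradome matching, mismatch-tolerant genome filtering, affine gap
penalties, alignment outside the 32-nt window, and probabilistic resolution
of multi-mapping tags are out of scope. The internal energy model is a
simplified stand-alone parameterisation, suitable for ratio-based filtering
rather than absolute thermodynamic prediction. The binomial filter's
fidelity to its inspiration is undetermined; treat its p-values as a
configurable ranking heuristic.
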