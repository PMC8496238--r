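---
title: "Two-step knock-in design with engineered landing pads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step knock-in design with engineered landing pads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landingpad)
```

## The problem and the editing model

Precision editing of a small genomic feature with an RNA-guided nuclease
(RGN) such as SpCas9 requires a cut site close to the feature. Small,
A/T-rich features (transcription-factor binding sites are the canonical
case) often have no usable PAM nearby, so a one-step knock-in either
fails outright or forces extra substitutions outside the feature to
destroy the guide's target after repair.

`landingpad` implements the two-step alternative. Step one deletes the
feature together with whatever flanking sequence is needed to reach a
high-quality cut site, and knocks in a short, engineered, genome-unique
RGN target — the *landing pad*. Step two cuts the landing pad and
restores the deleted interval from a second donor carrying the edited
(or wild-type) feature. Because the landing pad is unique and is itself
destroyed by the second integration, no sequence outside the intended
edit is altered: a wild-type add-back restores the genome byte for byte,
which is the central invariant the test suite asserts.

Three genome states are tracked: `plus` (wild type), `delta`
(knock-out with landing pad), and `addback`. Homology-directed repair is
modeled as exact, seamless arm-anchored replacement: the interval
between the donor's upstream-arm end and downstream-arm start is
replaced by the donor payload. Repair failure modes (NHEJ indels,
partial integration) are out of scope — this is a design tool that
predicts intended outcomes.

## Motif grammar

RGN targets are described in an IUPAC grammar: `N{17}|N{3}>NGG` is the
SpCas9 default (20 nt spacer, 3' NGG PAM, blunt cut 3 nt from the
PAM-proximal spacer end); `TTTV<N{20}` describes a Cas12a-style 5' PAM.
Ranged quantifiers (`{a,b}`) are matched as the union of their
fixed-length expansions, which is also how the property tests state
their oracle. Two deliberate conventions:

* genome `N` (assembly gap) matches only motif code `N`, never the
  concrete codes — gaps cannot produce phantom targets;
* multiple `|` cut marks are parsed and stored, but only the
  PAM-proximal one is used downstream (blunt-cut model).

## Guide quality control

A candidate target passes QC when all five filters hold (defaults in
parentheses): longest T run at most 4.5 — i.e. runs of five or more
fail (polyT ≤ 4.5); GC between 25 and 75 percent; no non-identical
genomic site within 1 mismatch, searched with an error budget of 5
(Errors ≤ 5); on-target score at least 45; aggregate off-target score at
least 90.

The off-target search is an exhaustive Hamming scan over every
PAM-compatible window on both strands, built once per genome as an
integer-coded window index. Each hit is scored with the position-weighted
single-hit scheme of Hsu et al. (2013),

$$ S_\text{hit} = 100 \prod_{p \in M}(1 - W_p) \times
   \frac{1}{\frac{19-d}{19}\,4 + 1} \times \frac{1}{n^2}, $$

where $M$ are the mismatch positions (1 = PAM-distal), $W$ the published
20-entry weight vector, $d$ the mean pairwise mismatch distance and $n$
the mismatch count ($n=0 \Rightarrow 100$; $n=1$ drops the distance and
multiplicity terms). Hits aggregate to the familiar 0–100 guide score
$100 \cdot 100 / (100 + \sum S_\text{hit})$. Spacers shorter than 20 nt
use the PAM-proximal tail of the weight vector; longer spacers pad the
distal end with zeros. A CFD-style table scorer is available behind
`read_cfd_table()`; the published table is not bundled.

The on-target model is a pluggable seam. The default `rule_surrogate`
scorer is a deterministic rule (100 minus the GC deviation from 50%
minus 10 per extra T in the longest T run), clearly *not* a trained
efficacy model; outputs say so, and trained models can be registered via
`register_ontarget_scorer()`. The 45-point threshold applies to
whichever scorer is active.

### Haplotypes

Diploid loci are represented as two contigs in one *ploidy group*. Two
consequences are worth spelling out. First, the off-target exclusion of
a candidate's own site extends to every contig of its ploidy group:
the sister-haplotype copy of a cut site is the same locus, not an
off-target (without this, every guide at a locus conserved between
haplotypes would fail the uniqueness floor). Haplotypes are assumed
colinear; indels between them in the arm regions are surfaced by the
arm-polymorphism check (ungapped, length-strict, mismatch fraction
≤ 0.05 by default) rather than by alignment. Second, HDR is homozygous:
one donor edits all contigs of the group, so heterozygosity inside the
replaced interval is overwritten by the donor payload — loss of
heterozygosity is an emergent, tested model behavior, not an error.

## Feature expansion and the editability sweep

When no QC-passing target lies inside the feature, the deletion bounds
grow by alternating one step left, one step right (50 bp steps) until a
passing target is wholly contained, capped at a total width of 4096 bp;
beyond the cap the feature is reported not editable. The smallest
containing expansion is chosen, which makes the result deterministic.

`editability_sweep()` reproduces the method's motivating experiment at
arbitrary scale: sample loci, grow nested features of 11 sizes
(1–1024 bp) around each, and report the proportion editable *directly*
(≥ 1 bp overlap between the feature and a passing spacer+PAM window) and
*indirectly* (feature and a passing target jointly fit in a 4096 bp
window — the geometric equivalent of the stepwise expansion, used here
so the sweep can cache QC per candidate). Nesting makes the direct
proportion non-decreasing in feature size, and direct implies indirect;
both properties are asserted rather than assumed.

## Donors

The landing-pad insert is rejection-sampled from the motif (uniform base
per ambiguous position), must pass the polyT/GC filters, and must have
at least 6 mismatches to *every* motif-compatible window of the +
genome — one more than the off-target error budget, so the insert
survives its own QC with margin. Sampling is deterministic given the
seed, with a bounded retry count. A user-supplied insert (e.g. a longer
cassette that embeds a landing pad) is accepted instead; it must contain
a motif match.

Step-1 donors take `arm_length` (default 50 nt, hard floor 20 — two
annealed 100-mers around a 23 nt insert is the practical reference
construction) homology arms immediately outside the expanded bounds;
arms must be unique in the genome (once per haplotype of the edited
group, absent elsewhere). Step-2 donors restore the expanded interval
with the feature either wild type or replaced;
`combinatorial_donors()` emits all $2^k$ bitmask combinations over
disjoint site edits, which is how multi-site promoter dissections are
built.

## Validation primers and in-silico PCR

Candidate primers are every 18–28 nt window on both strands of each
role region passing hard constraints (GC 30–70%, homopolymers ≤ 4, 3'
G/C clamp, no self-complementary 3' tail of 4 nt). Melting temperatures
come from the SantaLucia (1998) unified nearest-neighbor parameters with
initiation terms, the entropic salt correction
$\Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+]$ (50 mM, 500 nM primer), and
a symmetry correction for self-complementary sequences. This is a duplex
model — a deliberate, documented design choice over folding
partition-function thermodynamics, which is out of scope.

Primer weights are products of Gaussian penalties around the optima
(Tm 60 °C, σ 2.5; GC 50%, σ 10; length 20, σ 2); pair weights multiply
the two primer weights by a Tm-difference Gaussian (σ 2 °C) and a 0.1
dimer factor when the primers share a cross-complementary run of 8 nt.
These functional forms and constants are this package's own choices —
exposed as configuration, asserted by closed-form tests — because only
the weighting *idea* is fixed by the method. The set objective is the
product of pair weights over the scored role pairs (sF/sR, sF/oR,
oF/sR, iF/iR per state, AmpF/AmpR), zero if a primer sequence is reused
across roles or if a scored pair cannot form an amplicon (forward must
precede the reverse site). Set selection is Metropolis simulated
annealing with geometric cooling (T₀ = 10, rate 0.995, 20 000
iterations), seeded and deterministic; on instances small enough to
enumerate it provably returns the exhaustive optimum, which the tests
check. `sF`/`sR` are mandatory; internal roles are dropped with a
warning when their region is too short to host a primer — in
particular, a generated 23 nt landing pad cannot host an iF/iR pair,
only longer user inserts can.

In-silico PCR uses exact, full-length, 3'-anchored primer matching
(tolerance 0 by default) with a 5000 bp product cap; amplicon length is
the outer-coordinate difference, so it includes both primers. The cPCR
decision table runs every scored pair against the +, delta and add-back
states. The sF/sR genotyping verdict has two passing modes: a replaced
interval wider than the cap amplifies *only* the delta state; a small
interval amplifies all three states and discriminates when the three
product lengths are pairwise distinct. With a wild-type add-back the AB
state is byte-identical to +, so the three-length mode requires a
length-shifting replacement; the fixtures use one.

## The synthetic-genome generator

All tests and the acceptance script run on generated genomes: i.i.d.
background at a requested GC fraction, planted features and decoy
off-target sites (a spacer mutated at a requested number of positions,
next to a concrete PAM), and an optional second haplotype carrying
heterozygous SNVs at a per-base rate outside protected windows. The
generator is seeded and byte-reproducible, and emits FASTA + GFF3 + a
truth manifest.

What it emulates — and what it does not: local base composition,
target/PAM density as a function of GC, haplotype SNV polymorphism, and
planted near-off-targets. It does not model repeats, segmental
duplications, indel polymorphism between haplotypes, or chromatin
context. Passing tests therefore demonstrate the correctness of the
algorithms and the internal consistency of the two-step model, not
guide-efficacy predictions on any real genome.

Study-condition choices baked into the acceptance fixtures: 25 genomes
of 10–100 kb at GC 0.45 alternating haploid/diploid, heterozygous SNV
rate 0.005 for diploids with a 2500 bp protected window around the
edited locus (arms and the replaced interval must be het-free for
byte-identity to be a well-posed claim — the homozygous-edit model
erases heterozygosity inside the replaced interval by design); a 100 kb
GC 0.4 genome with 200 loci and 11 sizes for the sweep. These sizes
keep the whole suite within a few minutes on one CPU while exercising
every code path at realistic locus scale.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere internally; GFF3 (1-based
  closed) is converted at the boundary; distances are half-open interval
  arithmetic.
* Off-target enumeration is substitution-only (Hamming); windows, not
  alignments, so results are exactly oracle-checkable.
* Ranking ties break deterministically by (contig, start, strand);
  permuting the input never changes a ranked order.
* A feature wider than the expansion cap, an all-`N` or motif-free
  region, empty candidate pools for optional primer roles, and an empty
  off-target hit list (score exactly 100) are all defined, tested cases.
* One master seed fans out to per-stage child seeds by stable string
  hashing (`child_seed()`), so any stage can be reproduced in isolation.

## Known limitations

Haplotypes must be colinear (SNVs, not indels) for coordinate sharing
to be valid; arm search tolerates up to 5% mismatches when annealing a
donor to a polymorphic haplotype but will refuse ambiguous (multi-site)
arm matches. The on-target surrogate is a stand-in and should be
replaced by a trained scorer for real designs. In-silico PCR does not
model mispriming from partial 3' matches at the default tolerance. The
annealing objective treats role regions independently; it does not
re-optimize donor arms and primers jointly.
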