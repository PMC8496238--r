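# landingpad

Design engine for **two-step CRISPR/Cas genome editing** with engineered
landing-pad targets.

Small genomic features — transcription-factor binding sites are the
archetype — often sit in A/T-rich sequence with no usable PAM nearby, so
a conventional one-step knock-in either cannot cut close enough or has
to scar the flanks to destroy the guide's target after repair.
`landingpad` designs the two-step alternative:

1. **Step one (knock-out):** delete the feature plus whatever flanking
   sequence is needed to reach a high-quality RGN cut site, and knock in
   a short engineered, genome-unique target — the *landing pad*.
2. **Step two (add-back):** cut the landing pad and restore the deleted
   interval from a second donor carrying the edited (or wild-type)
   feature. The landing pad is destroyed by the restoration, so a
   wild-type add-back reproduces the original genome exactly.

Given a genome (FASTA), a feature (GFF3 or `contig:start-end` literal)
and a target motif in an IUPAC grammar (SpCas9 default
`N{17}|N{3}>NGG`), the package produces the four design artifacts:

* ranked candidate cut sites with quality control (polyT ≤ 4.5,
  25 ≤ GC ≤ 75, off-target search with a 5-error budget, on-target
  score ≥ 45, Hsu–Zhang aggregate off-target score ≥ 90), expanding the
  feature bounds (cap 4096 bp) when no passing target lies inside;
* the step-1 donor: homology arms around a landing-pad insert with ≥ 6
  mismatches to every motif-compatible genomic window;
* the step-2 donor(s): wild-type, single replacement, or all 2^k
  combinatorial edits over multiple sites;
* an annealing-optimized validation primer set (sF/sR, oF/oR, iF/iR,
  AmpF/AmpR) with in-silico PCR predictions for the wild-type (+),
  intermediate (Δ) and add-back (AB) genome states.

The aggregate guide-specificity score follows the position-weighted
scheme of Hsu et al. (2013):

S_hit = 100 · Π_{p∈M} (1 − W_p) · 1/(((19 − d)/19)·4 + 1) · 1/n²,
S_guide = 100·100 / (100 + Σ S_hit)

with mismatch positions M (1 = PAM-distal), the published 20-entry
weight vector W, mean pairwise mismatch distance d and mismatch count n.
Melting temperatures use the SantaLucia (1998) nearest-neighbor duplex
model with salt correction. The on-target scorer is a pluggable seam
(the bundled `rule_surrogate` is a deterministic rule, not a trained
model).

A seeded synthetic-genome generator (`generate_synthetic_genome()`)
produces every test input — haploid or diploid with heterozygous SNVs,
planted features and decoy off-targets — so the whole pipeline runs
without external data.

## Worked example

```r
library(landingpad)

# a 20 kb synthetic genome with a 9 bp binding-site feature at 10 kb
synth <- generate_synthetic_genome(synthetic_spec(
  20000, seed = 42,
  planted_features = list(list(pos = 10000, seq = "TTAAAGTTT",
                               name = "bs1"))))
design <- design_locus(synth$genome, synth$features[1, ],
                       design_config(seed = 7))
design
#> <locus_design> 'bs1' chr1:10000-10009
#>   expanded to 9950-10009 (59 bp)
#>   cut target: GTTTAACTGCGTTCGTTGCC TGG (-) off-target score 100
#>   landing pad: TGTTTATATAGCGCAGCTGTTGG
#>   donors: step1 123 nt, step2 159 nt
#>   primer set weight: ...
#>   cPCR: sF/sR mode ambiguous

write_design_bundle(design, "design_out")  # targets, donors, primers,
                                           # Δ/AB genomes, cPCR table
```

Reading the output: the 9 bp feature had no QC-passing Cas9 site of its
own, so the deletion bounds expanded to 59 bp to cover one
(`GTTTAACTGCGTTGC...TGG` on the minus strand, aggregate off-target
score 100 = no near-matches genome-wide). The 23 nt landing pad
(`TGTTTATATAGCGCAGCTGTTGG`) passes polyT/GC and has ≥ 6 mismatches to
every NGG-adjacent window of the genome. The step-1 donor is
50 + 23 + 50 nt, the step-2 donor restores the 59 bp interval. With a
59 bp replaced interval and a wild-type add-back, sF/sR amplifies all
three genotypes and + equals AB by construction, hence the `ambiguous`
sF/sR verdict — the oF/oR and AmpF/AmpR rows of
`design$cpcr$table` do the discriminating in that regime. Applying both
donors in silico (`design$states$addback`) reproduces the input genome
byte for byte.

A command-line front end with `design`, `sweep`, `synth` and `pcr`
subcommands is installed at `inst/cli/landingpad.R`.

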