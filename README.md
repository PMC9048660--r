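# intronless

Design intronless (or first-intron-only) mammalian transgenes by
stochastic synonymous recoding.

## Why

Most mammalian genes are predominantly intron, so practical transgenes are
built intronless — and classically express poorly. Well-expressed human
retrogenes show the fix: high GC content at synonymous sites (GC3),
especially toward the 5′ end. A second knob is the density of exonic splice
enhancers (ESEs) — hexamer motifs crowded near exon ends that direct
splicing and lose that role once the neighbouring intron is removed.
`intronless` recodes only synonymous positions, so the protein is untouched,
while:

* driving GC3 toward one of four targets — position-dependent
  third-nucleotide probability curves modelling 1–2 exon human genes
  (`one_two_exon`), maximal GC (`max_gc`), human codon usage
  (`human_usage`), or no GC component (`ese_only`);
* raising or lowering ESE hexamer density within 70 nt of each removed
  intron junction (or genome-wide with `ese_in_cores`), for any of the five
  recognized published motif collections (RESCUE-ESE, ESR, Ke-ESE400, PESE,
  INT3) or a user-supplied set;
* protecting chosen restriction sites (IUPAC patterns, both strands) and
  never introducing blacklisted motifs, flank- and junction-spanning cases
  included;
* optionally retaining the first intron (the default).

## The method in brief

At each mutable codon `c` with synonymous candidates, a GC score
`g ∈ [0,1]` (curve probability of the third nucleotide, G/C fraction of the
variable positions, or within-family usage) and, near removed junctions, an
ESE score `e ∈ [0,1]` (the fraction of hexamer windows over the variable
positions matching the motif set, complemented when decreasing) are blended
as `(1 − λ)·g + λ·e` and normalised into a selection likelihood. Codon
choice is a draw from that distribution: repeated passes over the CDS
populate a *variant cloud*, and the variant minimising

```
objective = mean over 10-codon bins |GC3_achieved − GC3_target|
          + |ESE density_achieved − ESE density_target|   (if ESE mode on)
```

is reported; ties break by fewest changes. The position-dependent curves
follow `p(i) = floor + (ceiling − floor)·exp(−i/τ)` per codon box (6-fold
boxes split into their 4-fold and 2-fold sub-boxes), and
`fit_position_curves()` refits them from any training CDS collection.

## Worked example

```r
library(intronless)
set  <- load_ese_set(motifs = c("GAAGAA", "AAGAAG", "TTCTTC"))
gene <- make_toy_gene(c(300, 300), 30, gc3_bias = 0.35,
                      motif_seeding = list(set = set, count = 4), seed = 9)
proc <- remove_introns(gene, keep_first = FALSE)
cfg  <- design_config("max_gc", ese_mode = "decrease", ese_set = set,
                      protect_enzymes = "GAATTC", avoid_motifs = "GCGCGC",
                      n_variants = 200, seed = 1)
plan  <- build_site_plan(proc, cfg)
cloud <- generate_cloud(proc, plan, gc_target_model("max_gc"), cfg)
best  <- cloud$variants[[cloud$best_index]]
```

printing, with this seed:

```
<processed_gene> toy: 600 nt CDS, 1 removed junction(s)
176 of 200 codons mutable; 48 ESE-eligible
<variant_cloud> 200 variants (200 distinct); best objective 0.0884
<variant> 133 codon change(s), GC3 0.920, objective 0.0884
input GC3: 0.33   input vicinity ESE density: 0.037
best GC3:  0.92   best vicinity ESE density: 0.0074
```

The 200-codon toy gene entered at GC3 0.33; the best of 200 stochastic
variants reaches GC3 0.92 at degenerate sites while cutting the seeded ESE
density around the removed junction five-fold, keeping every `GAATTC` site
intact and introducing no `GCGCGC`. The per-change table (`best$changes`)
lists each recoded codon with its 0-based index and the score component
that drove it; `write_outputs()` / `run_design()` emit the best-variant
FASTA (retained intron re-inserted in lowercase), a multi-FASTA of the
distinct cloud, a TSV change table and a JSON summary plus run manifest.

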