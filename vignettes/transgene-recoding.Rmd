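---
title: "Designing intronless transgenes by stochastic synonymous recoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing intronless transgenes by stochastic synonymous recoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronless)
```

## The design problem

Mammalian genes are mostly intron, so practical transgenes (for synthesis,
delivery or gene therapy) usually have their introns removed — classically at
a cost, because intronless constructs tend to express poorly. Two sequence
properties mitigate this. First, intronless human retrogenes that are well
expressed carry high GC content at synonymous (mostly third codon) positions,
especially toward the 5\' end; raising GC3 rescues expression of intronless
transgenes. Second, exonic splice enhancers (ESEs) — hexameric motifs
concentrated near exon ends that recruit SR proteins to direct splicing —
lose their splicing role once the flanking intron is gone, and modifying
their density near the former junctions can tune expression (at some risk of
missplicing). Since only synonymous sites are touched, the encoded protein
is invariant by construction.

`intronless` turns a native (or previously "optimised") gene into an
intronless or first-intron-only construct by stochastically recoding
synonymous sites toward a GC3 target model and, optionally, an ESE density
target, while keeping user-specified restriction sites intact and never
introducing blacklisted motifs.

## The procedure

1. **Input.** A gene body from GenBank (CDS feature with `join()` /
   `complement()` locations) or FASTA, where exon/intron structure is
   encoded by case: UPPERCASE exons, lowercase introns. The GenBank route
   is lossless; the case convention is this package's choice for FASTA,
   which carries no feature table. Optional fixed 5\'/3\' flanks are
   attached but never recoded.
2. **Intron removal.** All introns are discarded; by default the first is
   retained (`keep_first_intron = TRUE`), since a first intron often
   supports robust expression. Each *removed* junction offset is recorded:
   these anchor the ESE windows. A retained intron's boundary is not a
   junction — the intron is still there, so no ESE adjustment applies.
3. **Site plan.** A codon is *mutable* if it has two or more synonymous
   candidates under the 6-fold policy, is neither start nor stop, and does
   not overlap a protected restriction-site match (matched as IUPAC
   patterns on both strands of the full construct, flanks included). A
   codon is *ESE-eligible* if any of its nucleotides lies within
   `vicinity_nt` (default 70) of a removed junction, on either side, or
   everywhere with `ese_in_cores = TRUE`.
4. **Scoring.** At each mutable codon the candidates are scored in
   `[0, 1]`:
   * GC component, one of four strategies — position-dependent
     third-nucleotide probability curves emulating 1–2 exon human genes
     (`one_two_exon`), G/C maximisation at the variable positions
     (`max_gc`), position-independent human codon usage (`human_usage`),
     or none (`ese_only`);
   * ESE component at eligible sites — the fraction of hexamer windows
     overlapping the candidate's variable positions that match the motif
     set after substitution (complemented in `decrease` mode).
5. **Selection likelihood.** Scores become probabilities by the convex
   blend `(1 - lambda) * gc + lambda * ese` (default `lambda = 0.5`),
   normalised linearly. Codon choice is a draw from this distribution, so
   recoding is deliberately non-deterministic: repeated draws populate a
   *variant cloud*.
6. **Blacklist.** A draw that differs from the current codon is substituted
   into the working construct and the surrounding window (sized by the
   longest avoid motif, so junction- and flank-spanning introductions are
   caught) is rescanned; if a blacklisted motif would appear at offsets
   where none existed, the site is left as is.
7. **Best variant.** Each variant's objective is the mean over 10-codon
   bins of |achieved − target GC3| (computed over degenerate third
   positions), plus |achieved − target ESE density| over the vicinity
   regions when ESE adjustment is on. The lowest objective wins; ties break
   by fewest changes, then generation order.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `vicinity_nt` | 70 | half-width (nt) of the ESE window each side of a removed junction |
| `lambda` | 0.5 | ESE weight in the score blend; 0 = GC only, 1 = ESE only |
| `sixfold_policy` | `full_box` | all six synonyms at Leu/Ser/Arg sites, or only the 2-/4-codon sub-box |
| `keep_first_intron` | `TRUE` | retain intron 1 for expression support |
| `n_variants` | 1000 | cloud size; seconds-scale at typical CDS lengths |
| `seed` | 1 | the cloud is a pure function of (input, config, seed) |

The 6-fold families are always *curve-scored* within their 4-fold/2-fold
sub-boxes (`CTN|TTR`, `TCN|AGY`, `CGN|AGR`) because third-position
probabilities are defined per codon box; under the default full-box policy,
cross-sub-box candidates are scored in their own sub-box and jointly
renormalised. Under `max_gc`, all variable positions of the candidate set
count (6-fold families also vary at positions 1–2), because each is a
degenerate site whose G/C content the strategy maximises.

## The position-dependent curve model

The favourability of third-position nucleotides in 1–2 exon human genes is
position dependent: GC3 is highest at the 5\' end and decays downstream. The
fitted coefficients of that usage are not redistributable reference data, so
the package ships a parametric stand-in and a fitting routine that rebuilds
the construction from any training set of CDSs:

* the default model puts the total GC-class probability at
  `p_GC(i) = floor + (ceiling - floor) * exp(-i / tau)` over 0-based codon
  index `i`, with `ceiling = 0.80`, `floor = 0.55`, `tau = 50` codons —
  a 5\'-high GC3 decaying to a genomic-average level within the first one
  to two hundred codons, which is what well-expressed intronless genes look
  like; within a box, the GC mass is split equally over the G/C-ending
  options and the AT mass over the rest. Probabilities are renormalised
  over each box's nucleotides at every index, so any user-edited YAML
  config (see `load_curve_model()`) remains a valid distribution.
* `fit_position_curves()` tabulates empirical third-nucleotide frequencies
  per box in 10-codon bins and fits `(floor, ceiling, tau)` per nucleotide
  by bounded least squares (`minpack.lm::nlsLM`), falling back to the flat
  position-independent frequency for degenerate or data-poor boxes. The
  exponential family is a documented choice: any smooth monotone decay
  with a 5\' plateau and a 3\' asymptote would serve, and the exponential
  has the fewest parameters that capture both.

## What the synthetic generator emulates — and what it does not

`make_toy_gene()` draws amino acids uniformly, sets degenerate third
positions to G/C with probability `gc3_bias`, gives introns canonical
`GT..AG` ends, and can plant a requested number of ESE matches
(codon-aligned, never creating stops) inside the junction vicinities.
`make_training_corpus()` draws third nucleotides from the exponential curve
above, per box. These generators reproduce the *statistical structure the
method manipulates* — GC3 levels, positional GC3 decay, ESE densities near
junctions — but not real-gene features the method does not model: amino-acid
composition bias, codon-pair and dinucleotide (CpG) effects, realistic
intron length and composition, splice-site strength, or secondary structure.
Passing tests therefore demonstrate the correctness of the recoding
machinery under controlled conditions, not expression outcomes on real
genes.

In the test-suite and acceptance runs, problem sizes are chosen desk-scale:
toy genes of 45–600 nt CDS, clouds of 1–2400 variants, a training corpus of
500 CDSs of 300 codons, and 1,000-fold property sweeps; all are this
package's own sizing for fast, convincing checks.

## Numerical and design choices

* Coordinates are 0-based half-open internally, 1-based inclusive in every
  user-facing report.
* ESE resemblance of a candidate is a *window fraction*, the simplest
  statistic consistent with scanning hexamer sets; with no window available
  the score is the neutral 0.5. ESE windows are evaluated on the intronless
  CDS (the mature-mRNA view), not across a retained intron.
* Scores convert to probabilities by linear normalisation; an all-zero
  score vector falls back to uniform. Both are documented choices where the
  method's description only requires "scores become a selection
  likelihood".
* Restriction protection is computed on the *original* construct: retained
  sites are skipped, but the appearance of new sites is not forbidden
  unless the pattern is also blacklisted.
* The vicinity is symmetric around each removed junction, measured on the
  intronless CDS.
* Per-variant RNG sub-streams derive deterministically from
  `(seed, variant index)`, so clouds are reproducible and independent of
  generation order.
* Degenerate inputs behave conservatively: a gene with no mutable sites
  returns itself; regions shorter than a hexamer have ESE density 0;
  zero-intron genes simply have no vicinity.

## Known limitations

* No splice-site strength scoring of the retained intron, no silencer
  (ESS) sets, no position-weight-matrix ESE models.
* No CAI/tAI, CpG or mRNA secondary-structure objectives.
* Stochastic hill-free sampling, not global optimisation: the cloud's best
  variant is only guaranteed optimal in the exhaustively checkable small
  cases (and the test suite checks exactly that).
* The default curve parameters are a calibrated stand-in, not fitted human
  coefficients; users with genome-scale training data should fit their own
  via `fit_position_curves()`.

## A compact example

```{r example, eval = FALSE}
set.seed(1)
set <- load_ese_set(motifs = c("GAAGAA", "AAGAAG", "TTCTTC"))
gene <- make_toy_gene(c(300, 300), 30, gc3_bias = 0.35,
                      motif_seeding = list(set = set, count = 4), seed = 9)
proc <- remove_introns(gene, keep_first = FALSE)
cfg <- design_config("max_gc", ese_mode = "decrease", ese_set = set,
                     protect_enzymes = "GAATTC", avoid_motifs = "GCGCGC",
                     n_variants = 200, seed = 1)
plan <- build_site_plan(proc, cfg)
cloud <- generate_cloud(proc, plan, gc_target_model("max_gc"), cfg)
cloud$variants[[cloud$best_index]]
```
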