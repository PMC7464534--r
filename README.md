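# msatphylo

Microsatellites — perfect tandem repeats of 2–6 bp motifs — expand and
contract rapidly through replication slippage, yet little is known about
how their total genomic content evolves over tens or hundreds of millions
of years. **msatphylo** is an R package for comparative genomicists who
want to measure microsatellite content across many genome assemblies and
model its tempo and mode of evolution on a time-calibrated phylogeny: how
fast content changes (globally, per clade, and per extant lineage),
whether the rate differs between species with holocentric and monocentric
chromosomes, and whether content or its rate tracks chromosome number or
genome size.

## What it computes

* **Repeat scanning** — exact detection of maximal perfect 2–6-mer runs
  with per-period minimum copy thresholds (2-mers ≥ 6 copies, 3-mers ≥ 4,
  4–6-mers ≥ 3 by default), primitive-period classification, BED-style
  coordinates, and per-genome summaries (bp by period, total bp, bp/Mbp,
  genomic proportion). A second, independently written reference scanner
  backs every result.
* **Brownian-motion inference** — for a trait *x* on a tree with branch
  lengths in My, the rate σ² ((trait units)²/My) is estimated by
  closed-form REML from independent contrasts, σ̂² = Σuᵢ²/(n−1);
  ancestral states are joint GLS/ML estimates; the **tip rate** of a
  species is (x_tip − â_parent)/t_terminal, its signed recent rate of
  change since the last sampled speciation event.
* **Centromere-type dynamics** — a two-state Markov (Mk) model with
  asymmetric transition rates, and stochastic character maps sampled
  exactly (joint node states + endpoint-conditioned paths by
  uniformization).
* **Hypothesis tests** — simulation-null phylogenetic ANOVA
  (F compared to BM-simulated nulls, plus-one empirical p); a censored
  two-rate Brownian test over stochastic maps (per-state σ² via profiled
  restricted likelihood, χ²₁ LRT, per-map tallies); and phylogenetic
  linear models (GLS under σ²C) with parametric-bootstrap confidence
  intervals, tallied across a posterior tree set.
* **Synthetic data** — birth–death trees, (state-dependent) Brownian
  traits, Markov histories, and genomes with planted repeats whose truth
  tables come from the reference scanner, so the whole pipeline is
  testable end-to-end with known ground truth.

## Worked example

Scan a genome with planted repeats, then run a full synthetic
comparative study:

```r
library(msatphylo)
set.seed(7)

g <- synth_genome(50000,
                  data.frame(motif = c("AC", "ATG", "AAGT"),
                             copies = c(12, 8, 6)),
                  gc = 0.4, sequence_id = "chr1")
loci <- scan_sequence("chr1", g$seq)
head(loci)
#>   sequence_id start   end period motif canonical_motif copies
#> 1        chr1   471   484      4  ATTT            ATTT      3
#> 2        chr1   732   756      2    AC              AC     12
#> 3        chr1  4753  4777      3   ATG             ATG      8
#> 4        chr1 24243 24267      4  AAGT            AAGT      6
#> 5        chr1 37212 37225      4  TTAT            ATTT      3
```

The three planted loci are recovered at their exact coordinates (24 bp of
(AC)₁₂ at 732, (ATG)₈ at 4753, (AAGT)₆ at 24243); the two extra 4-mer
loci arose by chance in the background and are equally real — the truth
table in `g$truth` already contains all five.

```r
summarize_genome("demo_species", loci, nchar(g$seq))
#> Microsatellite profile for demo_species (assembly 50000 bp)
#>   2mer: 24 bp
#>   3mer: 24 bp
#>   4mer: 50 bp
#>   5mer: 0 bp
#>   6mer: 0 bp
#>   total: 98 bp  (1960.00 bp/Mbp, proportion 0.00196)

study <- simulate_study(study_sim_config(n_taxa = 60, n_trees = 5,
                                         genome_length = 0, seed = 7))
cfg <- study_config(trees = study$trees, trait_table = study$trait_table,
                    min_group_n = 8, n_sim = 50, n_maps = 20, n_boot = 50,
                    seed = 7)
run_study(cfg)
#> Comparative study report: 54 species, 6 discarded by filters
#>   global sigma^2 (content/Mbp): 47288.6
#>   per-order rates: 3 groups fit
#>   censored test: 14/20 maps favored two rates
#>   content_vs_chromosomes: 0/5 trees significant (0 positive slopes)
#>   tip_rate_vs_chromosomes: 2/5 trees significant (0 positive slopes)
#>   content_vs_genome_size: 5/5 trees significant (5 positive slopes)
#>   tip_rate_vs_genome_size: 1/5 trees significant (5 positive slopes)
```

Reading the report: six species fell below the BUSCO ≥ 0.90 quality
filter; the global Brownian rate of content is ~4.7 × 10⁴ (bp/Mbp)²/My;
a majority of stochastic maps favour separate holocentric/monocentric
rates (the generator really did use a tenfold monocentric excess); the
genome-size effect on content (truly +10 bp/Mbp per Mbp) is significant
with a positive slope on every tree, while chromosome number (truly no
effect) is not.

A thin command-line wrapper over these functions lives at
`inst/cli/msatphylo.R` (`scan`, `simulate`, `analyze` subcommands).

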