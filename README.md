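# mitopopcons

Detecting purifying selection and calling functional elements from
ultradense within-species polymorphism in a small circular genome.

## The problem

Purifying selection removes deleterious mutations, so functional DNA is
depleted of both between-species divergence and within-species diversity.
Conservation scores (phyloP, phastCons) exploit the first signal; when a
genome has been sequenced in tens of thousands of individuals — as the
human mitochondrial genome has, with more than one SNP per two base pairs —
the second signal becomes usable at single-base resolution, and it reflects
*current* selection rather than selection averaged over tens of millions of
years. This package implements that polymorphism-based route for
mitochondrial-like data, for population geneticists and genome annotators
who want to ask: which bases does selection care about *now*?

## What it computes

Let $o_i \in \{1,2,3,4\}$ be the number of distinct alleles observed at
site $i$ (1 = monomorphic). The package provides:

- **Polymorphism–divergence correlations** — Spearman's $\rho$ (midranks;
  $t$-approximation p-values floored at $2.2\times10^{-16}$ in reports)
  between $o_i$ and a negated conservation score, at site, window
  (10-bp adjacent or sliding), per-gene and codon-class resolution, and
  between minor allele frequencies and divergence.
- **Mutational-bias correction** — the replication-strand covariate
  $D_{\mathrm{ssH}}$ (time single-stranded during asymmetric replication;
  closed form $2(D-d)$ on the major arc, $\max(L-2y,0)$ on the minor arc)
  is regressed out of $o_i$ with a Poisson GLM, and correlations are
  recomputed on the residuals.
- **mitoPopCons-style element calling** — a two-state HMM (constrained vs
  unconstrained) over $o_i$ with a fixed transition matrix (default:
  symmetric, stay probability 0.99), emission-only Baum–Welch training
  (transition freezing by $10^9$ pseudocounts, 10 random restarts),
  functional-state labeling by the trained probability of emitting
  monomorphic sites, and Viterbi decoding into elements. This is the
  package's central model: `mitopopcons()` returns a fitted object with
  `print`, `summary`, `coef`, `logLik`, `predict`, `plot` and `simulate`
  methods.
- **Evaluation** — a seeded permutation test for base-pair overlap between
  element sets on the circular genome ($p = (1+\#\{\mathrm{perm} \ge
  \mathrm{obs}\})/(1+N)$, default $N = 10{,}000$), genic/intergenic
  summaries, multivariate-hypergeometric allele downsampling, and a
  power-versus-sample-size curve over the grid 100–1,800 (step 100) plus
  1,864.
- **A synthetic-data generator** — a seeded, byte-reproducible
  mitochondrial-like genome (16,569 bp, 16,411 sampled chromosomes, gene
  mosaic, per-site constraint, $D_{\mathrm{ssH}}$-modulated Poisson
  mutation, $1/k$ frequency spectrum, coupled divergence tracks) so the
  entire pipeline is exercisable and testable without any downloads.

Standard formats are read and written (FASTA, BED, fixedStep
wiggle/bedGraph, TSV SNP tables), plus an alignment-based coordinate
liftover between two reference dialects of the same molecule.

## Worked example

```r
library(mitopopcons)

cfg    <- synthetic_config(seed = 42)        # the default study conditions
lay    <- generate_layout(cfg)               # genes + constraint truth
sites  <- simulate_site_alleles(cfg, lay$truth)
tracks <- simulate_divergence(cfg, lay$truth)

sites
#> site_table: 16569 bp (circular)
#>   distinct-allele counts 1:4 = 9951 / 4265 / 1458 / 895
#>   polymorphic sites: 6618 (39.9%)
#>   sample sizes: 16411-16411 chromosomes/site

spearman_cor(sites$allele_count, tracks$negated_phylop$values)
#> Spearman's rho = 0.2858 ; P  < 2.2e-16 ; n = 16569 (midranks, ties present)

fit <- mitopopcons(sites, seed = 42)         # fixed transitions, 10 restarts
fit
#> mitoPopCons two-state allele-count HMM
#>   sites: 16569  log-likelihood: -15899.08 (best of 10 restarts)
#>   functional state: 1 (P(monomorphic) = 0.655 vs 0.168)
#> element_set (popcons_hmm): 15 elements, 14779 bp total, mean length 985.3 bp

ov <- overlap_bp(fit$elements, lay$truth$elements)
100 * ov / sum(lay$truth$elements$end - lay$truth$elements$start)
#> [1] 98.0   # percent of truly constrained bp recovered
```

The correlation says polymorphism tracks divergence site-by-site (the
signature of purifying selection acting on both); the fitted HMM finds one
state that emits monomorphic sites with probability 0.655 (the constrained
state) versus 0.168, and its Viterbi elements recover 98% of the bases the
simulation actually constrained.

The whole analysis — simulate (or load files), bias-correct, correlate,
segment, evaluate — runs as one call:

```r
res <- run_pipeline(list(seed = 42), out_dir = "out/")
res$report$correlations   # site/window/gene-level rho, significance tally
res$report$evaluation     # overlap p, genic fractions, truth recall
```

or from a shell via `inst/scripts/run_pipeline.R --config config.yaml`.

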