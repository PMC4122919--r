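---
title: "Detecting purifying selection from ultradense polymorphism: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting purifying selection from ultradense polymorphism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopopcons)
```

## The problem

Purifying selection removes deleterious mutations, so functional DNA shows
both reduced between-species divergence and reduced within-species
diversity. Cross-species conservation scores exploit the first signal; this
package implements the second route for a small circular genome sampled at
extreme depth (a human-mitochondrial-like setting where tens of thousands
of genomes yield more than one SNP per two base pairs). The analyses are:

1. **Polymorphism–divergence correlation.** At each site the diversity
   measure is the number of distinct alleles observed (1–4; depth makes
   allele *counts* informative even where frequencies are unavailable),
   correlated with a negated conservation score (larger = more divergent)
   at site, window, gene and codon-class resolution.
2. **Mutational-bias correction.** Mitochondrial mutation rate varies with
   the time a site's heavy strand spends single-stranded during asymmetric
   replication (D~ssH~). A Poisson GLM of allele counts on D~ssH~ yields
   residuals; the polymorphism–divergence correlation recomputed on those
   residuals is the selection signal with the replication gradient removed.
3. **Element calling.** A two-state HMM over per-site allele counts, with
   fixed transitions and emission-only Baum–Welch training, is decoded by
   Viterbi into constrained elements, which are compared against
   divergence-based elements by a permutation overlap test.
4. **Power analysis.** Allele counts are recomputed after hypergeometric
   downsampling of the sample to sizes 100–1,864, the HMM retrained each
   time, and detection power traced against sample size.

## The allele-count HMM

`mitopopcons()` fits the central model: hidden states
{constrained, unconstrained}, observation at every genome position the
number of distinct alleles $o_t \in \{1,2,3,4\}$ (monomorphic fill = 1, so
the chain runs genome-wide). The transition matrix is *not* learned: it is
supplied in the conserved-element parametrization (expected element length
$\ell$, expected coverage $\gamma$):

$$a_{cc} = 1 - 1/\ell, \qquad a_{nn} = 1 - \frac{\gamma}{\ell(1-\gamma)} .$$

The package default is $\ell = 100$ bp, $\gamma = 0.5$ — a symmetric matrix
with stay probability 0.99. The matrix used by the original analysis was
inherited from a published conservation HMM and is not recoverable, so the
choice is exposed rather than hidden; sensitivity to it is mild because the
emission contrast, not the run-length prior, dominates at this SNP density.
The initial distribution is the stationary distribution of the fixed
matrix, the standard neutral choice when nothing is known about the first
position.

Training maximizes the likelihood over emissions only, by
expectation–maximization in which the transition M-step is augmented with
pseudocounts $10^9 \times$ the fixed matrix. Expected transition counts are
at most the sequence length ($\sim 10^4$), so trained transitions stay
within $\sim 10^{-6}$ of their fixed values — the mechanism used by the
original analysis, reproduced literally rather than by simply skipping the
update, so the invariance is a *tested property* instead of an assumption.
Emission probabilities are floored at $10^{-10}$ each M-step so EM cannot
create absorbing zeros. Each of 10 restarts draws initial emission rows
from a symmetric Dirichlet (restart $r$ seeded `seed + r - 1`); the restart
with the highest final log-likelihood wins. Convergence: log-likelihood
gain below $10^{-6}$ or 500 iterations. The state with the higher trained
probability of emitting monomorphic sites is labelled *functional*, and the
called elements are the maximal functional-state runs of the Viterbi path
(ties broken deterministically toward the lower state index). The genome is
treated as a linear chain — no circular wrap in the HMM — matching standard
practice for tracks on this molecule; the approximation affects at most the
two ends of one element.

Numerics: the forward/backward passes use per-step scaling, Viterbi works
in log space, and the recursions are compiled (Rcpp), so a $10^5$-site
chain neither underflows nor dominates run time.

## D~ssH~ and the Poisson correction

During strand-displacement replication, leading-strand synthesis starts at
the heavy-strand origin O~H~; a site at leading distance $d$ becomes
single-stranded when the fork passes it. Lagging synthesis starts at the
light-strand origin O~L~ (leading distance $D$) and proceeds the other way.
With unit fork speeds the single-stranded duration is

$$D_{\mathrm{ssH}}(d) = \begin{cases} 2(D - d) & d \le D \\ \max(L - 2(d - D),\, 0) & d > D \end{cases}$$

in bp-time units on a circle of length $L$. The cited single-strandedness
model gives no closed formula, so this piecewise form is derived from the
fork mechanics and verified site-by-site against a discrete-time fork
simulation in the test suite; fork-speed ratio and direction are
configurable, and sites on the minor arc can be excluded instead of using
the wrap-around branch (`minor_arc = "exclude"`) since the original
treatment of those sites is unstated. The control region is omitted from
all D~ssH~ analyses.

The correction fits allele counts as a Poisson response with log link on
D~ssH~ by IRLS (relative deviance change $< 10^{-8}$, max 100 iterations).
The response is the raw count 1–4, taken literally from the description of
the original model. Deviance residuals are the default corrected
polymorphism signal (the default residual convention of the statistical
environment the original analysis likely used); Pearson and response
residuals are selectable. The IRLS routine is authored here because the
package's contracts require the per-iteration deviance trace; the tests
cross-check coefficients, standard errors and residuals against `stats::glm`.

## Correlation conventions

Spearman correlations use midranks — mandatory, since allele counts take
four values and ties dominate — and a $t$-approximation p-value with
$n - 2$ df, accurate at genomic $n$; printed reports floor p at
$2.2 \times 10^{-16}$ while the raw value is retained. The package always
correlates polymorphism with the *negated* conservation score, so positive
rho means diversity tracks divergence (the selection signature); the
original report mixed sign conventions between its text and its per-gene
table, and fixing one convention removes the ambiguity. Per-gene tables
carry raw p-values (matching the original, which applied no
multiple-testing correction) plus a clearly separate Benjamini–Hochberg
column as an extension. Windows are adjacent by default (10 bp), sliding
with `step = 1`; the genome is treated as linear for windows unless
`circular = TRUE`. A trailing partial window is kept when it spans at least
half a window.

Codon classification reads protein genes 5'→3' on the coding strand under
the vertebrate mitochondrial code (translation table 2): position 2 of
each codon is the nonsynonymous proxy class, position 3 is four-fold
degenerate when the first two bases determine the amino acid. Trailing
partial codons (and sites claimed by an earlier overlapping record) are
skipped with a warning and counted.

## The synthetic genome

The generator is a deliberate caricature, not a coalescent. Real mtDNA is
non-recombining — every site shares one genealogy — but all analyses under
test treat sites marginally, so independent sites give clean, assertable
statistics. Per site:

$$m_i \sim \mathrm{Poisson}(\mu_i), \qquad
  \mu_i = \theta (1 - c_i)\, e^{\beta\, D_{\mathrm{ssH}}(i)},$$

with constraint $c_i \in [0,1]$, distinct alleles $\min(1 + m_i, 4)$, and
each mutation's derived count drawn from the neutral spectrum
$P(k) \propto 1/k$, truncated; remaining chromosomes carry the reference
allele. Defaults (fixed once, with the reasoning below):

| parameter | default | why |
|---|---|---|
| genome length | 16,569 bp | the mitochondrial reference length |
| sample size $n$ | 16,411 | the depth of the ultradeep SNP collection emulated |
| $\theta$ (neutral) | 1.8 | gives $\approx 0.54$ segregating mutations per site genome-wide under the default layout — the observed density of that collection ($8{,}944/16{,}569$) |
| $\beta$ (D~ssH~ slope) | $5 \times 10^{-5}$ per bp-time | a weak gradient: divergence–D~ssH~ correlation much smaller than the selection signal |
| class constraint | tRNA/rRNA 0.9, protein 0.8 (codon-modulated, below), control 0.2, intergenic 0 | RNA genes are the most conserved mitochondrial features; the control region is regulatory but fast-evolving |
| divergence track | $2(1 - c_i) + N(0, 0.5)$ | signal-to-noise chosen so the site-level correlation is strong but far from 1 |
| conservation probability | logistic$(6(c_i - 0.5))$ | deterministic, saturating at the class extremes |
| SFS truncation | $\max(2, \mathrm{round}(2.5 \times 10^{-4} n))$ | see below |
| constrained frequency cap | $2 \times 10^{-4}$ | deleterious derived alleles stay at a few copies |
| truth threshold | $c > 0.5$ | truth elements = gene-like blocks |

Two defaults deserve their own account.

**Codon modulation and the truth threshold.** Within protein genes,
constraint is codon-position-specific by default: first positions 0.8,
second positions 0.9, four-fold degenerate third positions 0.55, other
third positions 0.7. Without this within-gene contrast the per-gene
correlation table would be degenerate (block constraint makes within-gene
variation pure noise, so the significance tally would sit at the false
positive rate), whereas the gene-level analysis this emulates is driven
precisely by codon-scale variation. The four-fold level is deliberately
*above* the 0.5 truth threshold — mitochondrial synonymous sites are weakly
but genuinely constrained — so truth elements remain contiguous gene-scale
blocks; had four-fold sites been assigned strong neutrality (say 0.1), the
maximal-run definition of truth would fragment into 1–2 bp pieces that no
segmentation with a ~100 bp run-length prior should be scored against.
Analyses that need strong synonymous/nonsynonymous contrast (the
codon-class comparison) lower the four-fold level explicitly. Note that
tRNA/rRNA genes have uniform constraint, so their per-gene correlations
are null by construction — only protein genes carry within-gene signal in
synthetic data, unlike real RNA genes with internal structural variation.

**The frequency spectrum.** The truncation and the constraint cap shape
only *frequencies*, never full-sample allele counts (any $k \ge 1$
segregates), so they matter solely for the downsampling analyses and the
MAF analysis. Untruncated $1/k$ puts roughly a third of its mass on alleles
common enough ($> 3\%$) to survive any subsample of 100+, so detection
power would saturate at the bottom of the 100–1,864 grid. The emulated
population is a rapidly expanded one whose variation is overwhelmingly
rare; truncating the neutral spectrum at $\approx 2.5 \times 10^{-4}$ of
the sample reproduces the regime where the number of recovered alleles —
and with it detection power — grows logarithmically across the whole
sampled range (a pilot sweep of truncations confirmed: coarser truncations
complete their growth by $n \approx 400$–1,100; finer ones make the
$n = 100$ end non-identifiable). Under constraint the cap is tighter
($2 \times 10^{-4}$, i.e. a few copies), keeping deleterious alleles rarer
than neutral ones — the mechanism that makes minor allele frequency
positively correlated with divergence. Note the direction: a cap must bite
at *moderate* derived frequencies to lower the folded MAF; excluding only
near-fixed derived alleles (frequency $> 0.9$) would remove *low*-MAF
sites and invert the signal.

What passing tests on this generator do **not** show: behavior under a
shared genealogy (background selection, hitchhiking, the variance inflation
of a single non-recombining locus), recurrent-mutation hotspots beyond the
smooth D~ssH~ gradient, nucleotide-specific mutation spectra, or realistic
haplogroup structure. Conclusions about real data rest on the analyses, not
on the generator.

## Evaluation choices

**Overlap permutation test.** The statistic is the number of base pairs
constrained according to both element sets. "Permuting the coordinates" is
ambiguous; the default places each element of the query set at an
independent uniform start on the circle with lengths preserved (overlaps
among placed elements allowed — the union is what counts), and a
`rotation` scheme preserving all spacing is offered. The empirical p-value
uses the +1 correction, $p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(1 + N)$,
so it is never 0 and is reported as $< 1/(N+1)$ when unbeaten; $N = 10{,}000$
by default.

**Downsampling.** A multivariate hypergeometric draw per site (sequential
binomial–hypergeometric decomposition), then alleles recounted. Tables
without per-allele counts are refused — allele-count-only collections
cannot be downsampled, which is exactly why the original power analysis
switched data sources.

**Power.** Power at size $n$ is base-level recall of reference-constrained
bp by the retrained HMM's elements (the original metric is unstated;
precision and F1 are reported alongside). Within a replicate the per-size
subsamples are nested — each size drawn from the next larger draw — which
leaves every per-size distribution unchanged (a without-replacement
subsample of a without-replacement subsample is one of the original) while
cancelling most between-size Monte-Carlo noise: the standard
common-random-numbers construction for estimating a monotone curve from
few (default 3) replicates.

**Problem sizes.** The test suite exercises the full 16,569-site genome
where the contract concerns genome-scale behavior (Baum–Welch contracts,
emission recovery, the full 100–1,864 power grid with 3 replicates) and
2,000–10,000-site toy genomes elsewhere; exhaustive-enumeration oracles run
at $T \le 12$, alignment oracles at string lengths $\le 8$.

## Coordinate handling and liftover

Internally everything is 0-based half-open; 1-based inputs (SNP tables,
wiggle) convert at the boundary. Mapping positions between two reference
dialects of the same molecule uses one global pairwise alignment with
affine gaps (match +1, mismatch −2, gap open −5, extend −1 per base; the
original conversion used an external multiple aligner, but two sequences
need only a pairwise map). `N` matches nothing — the placeholder base in
one common reference copy must not anchor an alignment. The resulting map
is monotone with at-most-once target use by construction; unaligned source
bases lift to `NA`.

## Known limitations

- The fixed transition matrix is a stand-in for an unpublished one; element
  counts and mean lengths shift with $(\ell, \gamma)$ even though
  base-level calls are robust.
- Independent-site simulation understates the variance of every genome-wide
  statistic relative to a shared genealogy.
- The permutation schemes do not condition on composition or gene
  structure (no GAT-style matching).
- The HMM has exactly two states: graded constraint is thresholded, and
  weakly constrained regions inherit whichever state is closer.
- p-values from the $t$ approximation are approximate under heavy ties at
  small $n$; at genomic $n$ the approximation error is far below the
  reporting floor.
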