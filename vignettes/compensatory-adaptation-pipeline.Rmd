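---
title: "Analysing compensatory adaptation from resequenced evolved lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing compensatory adaptation from resequenced evolved lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compwalk)
```

## The scientific problem

In an evolve-and-resequence design for compensatory adaptation, a haploid
ancestor carrying a costly resistance mutation founds replicate lines that
evolve asexually in a permissive environment; fitness recovers, and the
question is how many and what kind of genomic changes did the recovering.
The study system this package emulates is *Aspergillus nidulans*: a
fludioxonil-resistant ancestor (resistance mapping to the HOG stress-response
pathway histidine kinase *nikA*), eight evolved lines sequenced after 800
generations, four from a small-bottleneck regime (~500 spores, "S") and four
from a large one (~50,000 spores, "L").

Two layers of inference meet here. *Fitness trajectories* yield
maximum-likelihood estimates of the number of adaptive steps per line (one
to three in this system; these estimates are an **input** to this package,
never recomputed). *Whole-genome resequencing* yields the derived mutations
actually fixed. Comparing the two quantifies how much of molecular evolution
during an adaptive walk is hitchhiking rather than adaptation.

## Pipeline stages and their assumptions

### Consensus variants and the ancestral/derived partition

Variant callers disagree, so a call is trusted when at least `min_callers`
callers (default 2 of 3) report the identical chromosome, position and
alleles, with depth at least 3. Alleles are first reduced to a minimal
representation (common suffix then prefix trimmed, keeping the VCF anchor
base), which unifies caller-specific padding of the same indel. True
left-alignment against the reference is not performed: the pseudo-callers of
the synthetic cohort emit consistent representations, and external data
normalized with standard tools (`bcftools norm`) arrive left-aligned
already. The cross-verification rule itself is a free design choice —
"compare across callers" admits anything from 1-of-n to unanimity — and
2-of-3 is the weakest rule that actually uses the comparison; it is
configurable, as is an exception admitting indels from a dedicated indel
caller alone.

A consensus variant present in the ancestor *and every* evolved line
predates the experiment (ancestral); one absent from the ancestor but
present in some line arose during selection (derived). Variants present in
the ancestor but missing from a subset of lines fit neither definition;
they are reported as *ambiguous* and never silently merged into either set.

### Mutation classes, severity and regulatory tags

Each derived mutation receives exactly one class. Coding SNPs are translated
through the standard genetic code with strand handling; a changed residue is
*nonsynonymous*, an unchanged one *synonymous*, and a gained (or lost) stop
joins frame-shifts and in-frame codon indels in the *coding other* class.
Amino-acid replacements are scored against six physicochemical classes —
hydrophilic uncharged (S, N, T, Q), aliphatic uncharged (A, G, V, L, I),
nonpolar uncharged (C, M, P), acidic (D, E), basic (K, R, H), aromatic
(F, Y, W) — conservative within, radical across; all *coding other* events
are radical. Stop-loss is grouped with stop-gain (the class definitions are
silent on it; both disrupt the reading frame's product). A variant touching
a CDS boundary is classified by the affected CDS base if any; overlap
priority is CDS > UTR > intron, mirroring effect severity.

Intergenic variants (UTRs included — the class system is CDS/intron-based)
are screened for regulatory potential: inside an annotated 5'-UTR, or within
100 bp upstream of a transcription start site (strand-aware; a variant
upstream of two genes is assigned the nearer TSS).

The candidate-resistance filter is a two-step reduction of the *ancestral*
variant set: keep protein-changing variants, then intersect the affected
genes with a genetic mapping interval supplied as explicit coordinates
(marker-based interval ends, such as "between the centromere and *cys2*",
must be resolved to coordinates by the user since they are genome-build
specific).

### Coverage anomalies

Depth is averaged in 1 kb bins; bins strictly above 1.8x or strictly below
0.20x the sample's genome-wide mean are flagged (ties are not anomalies),
maximal same-direction runs become candidate regions, same-direction
candidates separated by at most 200 bp are collapsed, and a region must
exceed 500 bp. Two rules the thresholds do not pin down:

* With 1 kb bins the 500 bp and 200 bp rules only bind below bin
  resolution. When per-base depth is available, `call_regions(depth = )`
  refines region boundaries to the outermost contiguous beyond-threshold
  base within the flanking bins before merging; the default reports at bin
  resolution.
* Merging never crosses an intervening flagged region of the opposite
  direction, and never crosses a chromosome boundary. (With a 200 bp gap
  and 1 kb bins the first case cannot arise; it matters only for
  exploratory large gaps.)

Regions of missing coverage shared by the ancestor and every line indicate
sequence present in the reference assembly but absent from the sequenced
strains — background divergence, not derived events; their genomic footprint
is reported by `summarize_masked_fraction()`.

### GO-Slim enrichment and the parallelism probability

For each namespace, terms carried by fewer than 5% of the annotated query
genes are dropped; each remaining term is tested with a 2x2 chi-square of
query vs rest-of-genome against term vs not-term, one-tailed by directional
halving (p/2 when fold > 1, else 1 − p/2); Benjamini–Hochberg runs within
namespace at FDR 0.15; a term is flagged when additionally observed/expected
≥ 1.2. Two ambiguities are settled as defaults and kept switchable: the
background excludes the query ("rest of the genome"), and the 5%
representation denominator is the *annotated* query genes (unannotated genes
cannot carry terms). Gene counts, not mutation counts, fill the table. No
continuity correction is applied by default; `yates = TRUE` is available.

The parallelism statistic answers: if *n* genic mutations land uniformly at
random across *G* protein-coding genes, how surprising is it that the *k*
mutations observed in a designated *m*-gene pathway are exactly the ones
that hit it? The default `specific_hit` mode computes
$(m/G)^k (1-m/G)^{n-k}$ — the probability that those *k* designated
mutations hit and the remaining $n-k$ miss. The more conventional tail
$P(X \ge k)$, $X \sim \mathrm{Binomial}(n, m/G)$, is available as
`binomial_tail` and is never smaller for $k \ge 1$ (it sums the
$\binom{n}{k}$ arrangements and all larger counts); the specific-hit form is
the default because it is the quantity the emulated analysis reports.

### Adaptive-walk statistics

All summary statistics are deliberately elementary, so that every printed
number is auditable: SE is the n−1 sample standard deviation over √n;
Pearson significance uses $t = R\sqrt{n-2}/\sqrt{1-R^2}$ on n−2 df; the
variance comparison is a one-tailed F of the larger over the smaller
variance; treatment contrasts on per-line proportions (synonymous share of
coding SNPs; putatively neutral share = intergenic + intron + synonymous
over total) use Welch's unequal-variance one-tailed t with alternative
S > L (pooled variance by flag). The substitution rate is
total / (callable bp x generations x lines). The coding-share test is a
1-df goodness of fit against an *expected coding fraction supplied by the
user*: the coding share of a genome is an empirical quantity (roughly 50%
here), not a constant the package should hard-code.

Mutations-per-step ratios are quoted against the step-number mean at
printed precision (two decimals, rounded half-up — `round_half_up()`
exists because `round()` banks 2.125 to 2.12), keeping reported ratios
consistent with the summary values they are derived from. Leave-one-out
correlation screening recomputes R and p excluding each line in turn and
flags lines whose exclusion changes significance at 0.05; in the emulated
study this isolates line 25S, which combines a high step estimate with few
point mutations (it carried the experiment's only large structural variant,
which point-mutation counts do not see).

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` produces a complete, self-consistent toy study with
known ground truth. Its defaults *are* the emulated study conditions:

| parameter | default | rationale |
|---|---|---|
| lines | 4 S + 4 L, named 9S…59L | study design |
| generations | 800 | study design |
| derived mutations | the published class-by-line counts (144; 87 genic) | `evolved_line_counts()` |
| step table | steps 3,2,3,3,1,1,2,2; mean 2.13, SE 0.30 | `evolved_step_table()` (reconstruction, see below) |
| ancestral variants | 740 SNPs + 456 indels | ancestor-vs-reference divergence |
| pathway subset | 22 genes, exactly 2 hit | HOG-pathway parallelism |
| regulatory hits | 5 in 5'-UTRs, 8 in promoter windows | intergenic follow-up counts |
| coverage | mean 83x, 1 kb bins, Poisson bin noise | mapping summary |
| shared absent regions | 1.7% of the genome, bin-aligned | reference-assembly divergence |
| GO annotation missing | 57/56/54% per namespace | annotation coverage |
| planted enrichment | one stress-response-like term, 2.1-fold | detected functional signal |
| caller errors | fn 0.05, fp 0.5/Mb per caller, independent | mild realistic noise; set to 0 in exactness tests |
| toy genome | 8 x 400 kb, 1000 genes, 50% coding | full per-line density at tractable size |

The per-line step values deserve a note: the published per-line table is a
supplementary resource, so the preset is a *reconstruction*. Constraining
integer steps in {1,2,3} to the published mean (2.13) and SE (0.30) fixes
the multiset to two 1s, three 2s and three 3s; of the 560 assignments to
lines, exactly one reproduces the published step-vs-mutation correlations
(all lines 0.562, without 25S 0.884, within-S 0.181, within-L 0.966)
simultaneously — that assignment is the preset. The fitness column is a
synthetic stand-in on a relative growth-rate scale, back-solved only to
approximate the reported step-vs-growth-rate correlation; it is never
asserted in tests.

Gene models are single-transcript and non-overlapping with explicit 5'-UTRs
(the regulatory tag needs TSS and UTR coordinates); introns sit at codon
boundaries, so annotation and planting share exact codon arithmetic; CDS
sequence is built from sense codons with a terminal stop, so every codon is
safely mutable. Pseudo-caller errors are independent across callers — the
simplest model that exercises consensus logic. Coverage noise is Poisson
around the bin mean. Indels are short (1–10 bp).

What the generator does **not** emulate, and hence what green tests do not
certify about real data: no reads or mapping artifacts (FASTQ-level error,
mappability, paralogy), no correlated caller errors (real callers fail
together on hard regions, so 2-of-3 precision gains are optimistic here),
no structural variants beyond coverage fold changes, no linkage between the
coverage layer and the variant layer (planted derived mutations avoid
zero-coverage regions, but ancestral variants are placed independently of
coverage), and no GO-graph structure (the table is flat, as a Slim set is).

## Numerical choices and degenerate inputs

Coordinates are 1-based inclusive in VCF/GFF3 space and 0-based half-open
in BED/coverage space, matching each format's convention. Determinism: all
generator randomness derives from the single config seed (each stage seeds
its own stream at a fixed offset, so stages are also reproducible when run
standalone); identical configs give byte-identical outputs. Degenerate
inputs are contracts, not crashes: zero genes still emits a sequence;
empty queries error in `go_enrich()` but report NA fractions in
`annotation_coverage_report()`; a line with zero coding SNPs is excluded
from the synonymous-share contrast with a warning; n = 1 yields a mean
without an SE; masks with start > end, thresholds with low ≥ high, and
overlapping planted coverage events raise explicit errors.

Test problem sizes are package choices tuned for the value of the check:
exactness tests run noise-free cohorts on a 2 x 200 kb genome with 80
genes (the full 144 + 1196 planted variants at full per-line density);
property tests sweep 200 random tracks against a brute-force run/merge
oracle and 200 null enrichment cohorts; the end-to-end default (8 x 400 kb,
1000 genes) runs in a few seconds.

## Known limitations

* **Small-count chi-square is liberal in its far tail.** At the emulated
  study's scale (~37 annotated query genes, per-term expected counts 2–8)
  the asymptotic one-tailed chi-square underestimates the discrete tail,
  and the BH comparison probes exactly that tail: the realized familywise
  false-flag probability exceeds the nominal 0.15 substantially. This is a
  property of the enrichment recipe itself, not of the FDR machinery — the
  type-I control test therefore runs at query sizes where expected counts
  put the chi-square in its calibrated regime. Treat borderline q-values
  from small queries with caution (a Fisher-style exact test is the
  conservative alternative; the Yates flag only partially compensates).
* Consensus matching is representation-based; run external VCFs through a
  left-aligning normalizer first.
* The ambiguous partition class (ancestor-present, some lines absent) is
  reported but not modelled; in real data it usually signals caller
  dropout, not biology.
* Boundary cases of the "coding other" class (stop-loss, start-loss) are
  counted as radical by assumption.
* The substitution-rate denominator (callable genome length) is an input;
  with masked and absent regions excluded it is smaller than the assembly
  size, and reported rates scale accordingly.
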