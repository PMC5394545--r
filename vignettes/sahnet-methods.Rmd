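---
title: "Methods: lncRNA-mRNA co-expression analysis for SAH RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA-mRNA co-expression analysis for SAH RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sahnet)
```

## The analysis problem

Experimental subarachnoid haemorrhage (SAH) in mice, induced by
endovascular perforation, triggers early brain injury within the first
24-72 hours. Bulk RNA-seq of cortex compares SAH animals against sham
controls, with tissue lysates of three mice pooled into each sequenced
sample — so a typical design has three pooled samples per group, six
samples in total. The analysis asks three questions: which transcripts
(mRNA and lncRNA) are differentially expressed; which assembled
transcripts are previously unannotated lncRNAs; and which lncRNA-mRNA
pairs co-vary so tightly across samples that a regulatory relationship is
plausible. `sahnet` implements that pipeline end to end, together with a
synthetic-data generator that makes every stage testable without raw
sequencing reads.

## Quantification

Expression is reported as RPKM, $C \cdot 10^9 / (N \cdot L)$, where $C$
is a transcript's read count in a sample, $N$ the sample's **total
mapped reads** (not the catalogue-assigned count — the two differ, and
`count_matrix` stores library sizes independently of column sums), and
$L$ the transcript's exonic length in bp. Downstream analyses use
$\log_{10}(\mathrm{RPKM}+1)$; the `expression_matrix` records its
transform state so the log cannot be applied twice silently.

GC-content normalization is a documented simplification of within-lane
loess-based methods: transcripts are stratified into GC-quantile bins
(default `n_bins = 10`), each bin's counts are rescaled within each
sample so the bin median matches the median of bin medians, the sample is
rescaled to its original total, and values are integerized with
largest-remainder rounding per bin (totals preserved within ±`n_bins`).
The procedure is idempotent up to rounding and exactly the identity when
all transcripts share one GC stratum. The original method's loess
internals are not reproducible from its description; bin-median matching
is, and its effect (removing a monotone GC trend in count medians) is
asserted by simulation in the test suite. The pipeline default applies GC
normalization (when enabled) *before* RPKM; the order is configurable
because the original description does not fix it.

## Differential expression

The test is the conditional binomial ("random sampling") test on
group-pooled counts: under the null hypothesis of equal relative
expression, $k_1 \mid (k_1{+}k_2) \sim \mathrm{Binomial}(k_1{+}k_2,
N_1/(N_1{+}N_2))$, and the two-sided p-value sums the probabilities of
all outcomes no more probable than the observed one. Exact enumeration is
used up to pooled totals of $10^4$; beyond that, a normal approximation
with continuity correction (the two branches agree to ~1% at the
boundary). Counts are *pooled* (summed) across the samples of a group
rather than averaged — with pooled-lysate samples the sum is the natural
sufficient statistic, and the alternative is not distinguishable from the
original description.

Two properties deserve emphasis:

* **Calibration is model-relative.** The binomial null models counting
  (technical) noise only. Under biological over-dispersion the test is
  anticonservative by construction — a well-known property of this test
  family — so the type-I-error test in the suite simulates its null with
  Poisson noise (`nb_dispersion = 1e-9`). With over-dispersed counts the
  p-values should be read as a ranking device, exactly as in the original
  analysis, with the fold-change threshold doing the heavy lifting.
* **Fold change** is $(\bar{x}_B + c)/(\bar{x}_A + c)$ on group-mean CPM
  with pseudocount $c = 0.5$ guarding zero means (set `pseudocount = 0`
  to reproduce printed textbook values exactly).

Multiple testing uses Benjamini-Hochberg step-up by default (implemented
directly, cross-checked against `stats::p.adjust` in the tests); a Storey
variant (`method = "storey"`, $\hat\pi_0 = \min(1, 2\,\overline{p{>}0.5})$)
is available because the original toolchain historically used
Storey-style q-values, but BH is deterministic and is the default.
Significance requires $|\log_2 FC| > 1$ **and** $q < 0.05$; the heat-map
selection tightens the fold-change threshold to 1.5 and caps at the top
100 transcripts per biotype (ranked by $q$, then $|\log_2 FC|$, then id;
rows standardized, constant rows emitted as zeros; row order from
average-linkage hierarchical clustering on Euclidean distance with rows
pre-sorted by id so ties break deterministically).

## Novel lncRNA classification

A candidate transcript is a novel lncRNA iff (i) it matches no known
transcript — same chromosome and strand, exonic overlap at least 50% of
the shorter transcript's exonic length; (ii) its exonic length is
strictly greater than 200 bp; (iii) it lacks coding potential. The
original analysis does not name its coding-potential method; `sahnet`
operationalizes it as *longest ORF < 100 aa* (ATG-initiated,
stop-terminated, three forward frames; both strands behind a flag), a
common lncRNA convention, with the threshold exposed
(`max_orf_aa`). Published coordinate tables confirm that transcript
"length" is exonic length under 1-based fully-closed coordinates
(single-exon length = end − start + 1), the convention used throughout.
Cis-proximal genes are reported within a closed 100 kb window of the
lncRNA span, distance 0 when overlapping, strand-blind.

## The co-expression network

The core procedure scores every lncRNA × mRNA pair — by construction the
network is bipartite, never containing lncRNA-lncRNA or mRNA-mRNA edges —
on $\log_{10}(\mathrm{RPKM}+1)$ profiles across **all samples of both
groups jointly** (the log scale stabilizes variance; the scale is
configurable). COR is the raw Pearson r; the published headline values
(e.g. 0.999) lie on the r scale, so the $|COR| > 0.95$ threshold applies
to r itself, before any standardization.

With $n < 8$ samples, parametric correlation tests are unreliable, so
significance comes from a permutation test: the null distribution of r
under relabelings of one vector's sample order. For $n \le 9$ all $n!$
permutations are enumerated (identity included), giving
$p = \#\{|r_{perm}| \ge |r_{obs}|\}/n!$; larger designs use seeded
Monte-Carlo sampling with the add-one correction
$p = (1 + \mathrm{hits})/(n_{perm} + 1)$. The statement that "Z score
values normalize the PCC" is ambiguous in the original description;
`sahnet` standardizes $r_{obs}$ against the permutation null,
$z = (r_{obs} - \mu_{null})/\sigma_{null}$, reports z alongside the
permutation p (the operative p-value), and the two-sided convention
matches the $|COR|$ thresholding. No multiple-testing correction is
applied across pairs — faithful to the published $p < 0.05$ rule, and
deliberately liberal; `adjust_q` can be applied to the edge table when a
corrected network is wanted.

Two consequences of exhaustive permutation worth knowing:

* p-values are discrete with granularity $1/n!$; at $n = 6$ the smallest
  two-sided p is $2/720 \approx 0.0028$, and the achievable false-positive
  rate at $\alpha = 0.05$ is $35/720 \approx 0.049$.
* at $n = 3$ the smallest p is $2/6 = 1/3$: **no pair can ever reach
  p < 0.05**, which is why at least two groups of three samples are
  needed before the network stage can return anything.

Edges require $|COR| > 0.95$ and $p < 0.05$ jointly. Node attributes
carry the transcript kind and regulation direction; edges carry r, z, p
and sign; exports are SIF plus attribute tables, GraphML (via igraph), or
a plain edge TSV, all byte-stable. `select_top_nodes` ranks nodes by
their maximum incident $|COR|$ (ties by degree, then id) to reproduce
"top-k hub" selections, and `rank_partner_correlations` orders an mRNA's
lncRNA partners by $|COR|$.

## The synthetic world

`sim_config` states the world the tests run in:

| parameter | default | rationale |
|---|---|---|
| `samples_per_group` | 3 | pooled design of the study (3 mice per pooled sample) |
| `n_mrna` / `n_lncrna_known` / `n_lncrna_novel` | 300 / 150 / 50 | desk-scale catalogue; large enough for stable fractions, small enough for second-scale tests |
| `nb_dispersion` | 0.05 | moderate biological over-dispersion typical of bulk tissue |
| `mean_log_expression`, `sd_log_expression` | 6, 1.2 (log2) | right-skewed baseline around ~64 expected counts |
| `de_fraction`, `de_log2fc_range` | 0.2, [2, 4] | strong planted effects, the regime the published filters target |
| `n_planted_pairs`, `planted_cor` | 10, 0.99 | "pairs with correlation near ±1" |
| `latent_sd` | 3.5 (log2) | see below |
| `library_size_range` | 0.8-1.2 × 10⁶ | per-sample depth variation |
| `region_fractions` | 78.73 / 16.27 / 4.73 / 0.27 % | the published control-sample read-region profile |

Counts are Gamma-Poisson: $C_{ij} \sim \mathrm{NB}(\mu_{ij},
1/\phi)$ with $\mu_{ij} = 2^{b_i + \delta_i \mathbb{1}[j \in SAH] +
\lambda_{ij}} \cdot s_j$. Three generator design choices are deliberate
and worth recording:

* **Planted correlations are realized, not expected.** The two latent
  vectors of a planted pair are built by Gram-Schmidt so their *sample*
  correlation equals `planted_cor` exactly. Planting only in expectation
  would leave the realized r with a Fisher-z standard deviation of
  $1/\sqrt{n-3} \approx 0.58$ at $n = 6$ — sampling noise, not the
  generator, would then decide whether a "planted" pair is recoverable,
  and a 0.99 target would be recovered barely ~90% of the time even with
  zero counting noise. With realized planting, recovery failures measure
  the pipeline, not the dice.
* **`latent_sd = 3.5`** makes the latent variance ($\approx 12$ in log2
  units) exceed the NB noise floor at the boosted pair baseline
  ($\approx 0.1$) by two orders of magnitude, so the observed correlation
  is the planted value attenuated by under 1%. Biologically this is the
  strongly co-regulated regime (inflammatory response genes swing over
  100-fold after SAH), which is exactly the regime the published network
  captures.
* **Library sizes are declared depths, not column sums.** The RPKM
  denominator is total mapped reads; the generator declares
  $N_j = \mathrm{target}_j / 0.85$ (85% of mapped reads assigned to the
  catalogue) and scales means with a *constant* expected-total factor.
  Normalizing by realized column sums instead would let the heavy-tailed
  pair channel modulate every transcript's RPKM through the denominator —
  a compositional common mode that produced ~5% spurious edges among
  independent transcripts in early testing. Real data do carry (much
  milder) composition effects; the generator's null pairs are exactly
  null by design, because the validity tests require it.
* **Planted effects are disjoint**: a transcript never carries both a
  fold-change shift and a pair latent channel, so every ground-truth
  label is unambiguous (the latent would otherwise swamp the shift at
  $n = 6$). Pair members may still *incidentally* pass the DE filter —
  their latent channel can differ between groups by chance — which echoes
  the real study, where the headline lncRNA-mRNA pair was itself
  differentially expressed.

What a green test does **not** establish: the generator has no
read-level error model, no isoform structure, no length/GC bias in
counts (GC bias is injected only in the GC-normalization tests), no
mouse-level variance component (pooling is emulated as one sample per
pool), and mild composition effects only. Recovery rates on this world
are upper bounds for real data.

## Numerical choices and degenerate inputs

* Table-style percentages are rounded half-up to 2 decimals (base R's
  banker's rounding would be platform-ambiguous at ties).
* Permutation hit-counting uses a $10^{-12}$ tolerance so exact ties
  count as hits (conservative).
* Zero-variance expression vectors are excluded from the network with a
  warning; a zero permutation-null SD yields `z = NA` with p still
  reported; zero pooled counts make a transcript untestable (`p = NA`).
* GC bins with fewer than two transcripts are merged leftward with a
  warning; an all-identical GC vector makes normalization the identity.
* Heat-map rows with zero variance are flagged and emitted as zeros.
* The exhaustive permutation branch refuses $n > 9$ ($9! = 362{,}880$)
  and points to Monte-Carlo mode.

## Open choices resolved

* Whether the study sequenced 3 samples per group is implied, not stated;
  `samples_per_group` defaults to 3 and is configurable.
* BH vs Storey q-values: not recoverable from the text; BH default,
  Storey behind a flag.
* Pooled vs averaged group counts for the DE test: pooled sums.
* GC normalization before or after RPKM: before, configurable.
* "Splicing" reads: defined as reads whose aligned blocks hit two or more
  distinct exons of one transcript, with precedence splicing > exonic >
  intronic > intergenic and an exonic majority rule (≥ 50% of bases) for
  junction-free reads that straddle exon boundaries; each read gets
  exactly one label.
* The enrichment stage is generic over-representation on user-supplied
  GMT sets; reproducing any specific ontology database is out of scope.
  During testing we found that the upper-tail hypergeometric p is
  monotone non-increasing in the universe size for fixed overlap — a
  fixed overlap becomes *more* surprising in a bigger universe — and the
  property tests assert that direction.

## Known limitations

* The DE test ignores biological dispersion (inherited from the method it
  re-implements); modern count models would be less anticonservative.
* With six samples the permutation p floor (0.0028) makes p < 0.05 an
  extremely weak filter next to $|COR| > 0.95$; the COR threshold is the
  operative one, as in the original analysis.
* ORF length is a crude coding-potential proxy; CPC/CPAT-style models are
  deliberately out of scope.
* The network applies no cross-pair multiple-testing correction by
  default (faithful, liberal); use `adjust_q` on the edge table for a
  corrected variant.
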