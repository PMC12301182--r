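---
title: "Methods: co-acquisition statistics for benchmarking HGT inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-acquisition statistics for benchmarking HGT inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hgtbench` evaluates horizontal gene transfer (HGT) inference by a signal
internal to the data: genes transferred together in one DNA segment start
out as chromosomal neighbors in the recipient. This vignette records the
models, parameters and numerical choices behind each layer, and what the
synthetic experiments do and do not establish.

## The co-acquisition statistic and its null model

Given a set of inferred gains at one stringency, a **co-acquisition** is an
unordered pair of genes from two different families gained on the same
terminal branch, with both genes on the same chromosome. Genes are
**neighbors** when at most `t` genes lie between them (`t = 1` by default;
positions are 0-based and gapless, so the count of intervening genes between
positions p < q is q − p − 1). Three filters keep small-number noise out:
only terminal-branch gains are evaluated (positions exist only in extant
genomes), chromosomes with fewer than 1,000 genes are excluded, and
stringency levels with fewer than 20 pairs are marked excluded.

Under the null hypothesis that the two gains of a pair arose independently,
a gene on a chromosome of $g_i$ genes has $t+1$ neighboring slots on either
side, so the chance that a second, independently placed gene is a neighbor
is $2(t+1)/g_i$ (a boundary-gene approximation). With $c_i$ co-acquisitions
on chromosome $i$ the expected neighbor percentage is

$$100 \cdot \frac{2\sum_i (t+1)\,(c_i/g_i)}{\sum_i c_i},$$

which reduces to $100 \cdot 2(t+1)/g$ for a single chromosome (0.4% at
$g = 1000$, $t = 1$). The test suite validates this formula against
Monte-Carlo random placement (10^5 replicates, 12 parameter combinations,
agreement within 3 standard errors); the boundary approximation biases the
formula upward by under $10^{-3}$ percentage points at these sizes, well
inside Monte-Carlo noise. $c_i$ counts *pairs*, not genes — with multi-copy
families every cross-family pair of member genes is a separate
co-acquisition, the simplest faithful reading of "a pair of genes".

When a method reports donor branches, a pair whose two genes share a donor
is a **co-transfer**. Both co-transfer percentages (all co-transfers, and
neighboring co-transfers) are reported out of *all* co-acquisitions, so
their ratio is the neighbor fraction among co-transfers; methods without
donors get an error rather than silent zeros, because for them the quantity
is undefined, not small. If the same family on the same branch is assigned
conflicting donors at one stringency, its pairs degrade to "unknown" rather
than guessing.

## The genome-evolution simulator

The simulator provides ground truth with the statistical structure the
statistic assumes — segmental, multi-gene transfer — without pretending to
be a full evolutionary model.

* **Species tree**: Yule (pure birth) via `ape::rphylo`, depth normalized
  to 1, so branch lengths are fractions of the root-to-tip span and event
  rates are "expected events per full tree depth".
* **Root genome**: one linear chromosome of `root_size` single-copy
  families in order. The default `root_size = 1200` keeps extant
  chromosomes above the evaluation's 1,000-gene filter under the default
  loss rate: with ~5–8 branches root-to-leaf and 2% loss per gene per
  branch, a 1,200-gene root genome ends near 1,020–1,100 genes.
* **Per branch**, in order: (1) each gene is lost independently with
  `p_loss = 0.02`, the order closing the gap; (2) `Poisson(hgt_rate × bl)`
  transfer events (`hgt_rate = 15`), each inserting a contiguous donor
  segment of geometric length (`p_seg = 0.3`, mean 3.3 genes, so 30% of
  events move a single gene) at a uniform position; with `p_novel = 0.1`
  the segment is replaced by brand-new families, exercising
  taxon-restricted-family edge cases; (3) `Poisson(rearr_rate × bl)`
  translocations (`rearr_rate = 1`) excise a geometric-length block and
  reinsert it elsewhere, eroding neighborhoods the way real rearrangement
  does.
* **Donors**: the donor branch is drawn uniformly among branches off the
  recipient's root path, with no time-consistency check — the evaluation
  never consults donor timing. Because genomes are evolved in preorder, a
  donor in an unvisited subtree has no finalized genome yet; its segment is
  read from the deepest already-evolved node on the donor's own root path
  (at minimum the root). Segments are therefore always contiguous in a
  concrete donor-lineage genome, which is all the truth log guarantees.
* **Truth log**: every transfer with donor, recipient and ordered segment;
  every loss; a derived per-branch gain list in which each gained gene maps
  to exactly one event.

`corrupt_inference()` turns truth into a method with dialable error: each
true event is dropped with probability `fnr`, and false events —
uniformly random (family, terminal branch) pairs not in the truth — are
added at a count of `fpr/(1−fpr)` times the retained truth, so `fpr` is the
expected false fraction of the output. Confidences are Beta(8,2) for true
and Beta(2,8) for false events, and stringency levels 1–10 are confidence
deciles; thresholding therefore enacts a stringency sweep whose precision
rises, which the tests verify in expectation over seeds.

`simulate_sequences()` gives each taxon an order-0 nucleotide composition
(GC drawn uniformly in [0.35, 0.65]); genes gained on the terminal branch
are sampled with GC displaced by `shift` toward the farther GC boundary, so
the mean |GC difference| equals `shift` exactly and clamping at [0.05,
0.95] never triggers for `shift ≤ 0.3`. Order-0 composition (not order-7)
is deliberate: at desk scale (hundreds of genes of a few hundred bp) 8-mer
counts are hopelessly sparse, and the detector's k is configurable instead.

**What this does not emulate**: nucleotide substitution and amelioration
(the compositional signal of a transferred gene decaying over time), rate
variation across lineages, gene duplication, within-population processes,
and chromosome structure beyond a single linear order. Passing tests show
the statistic and detectors behave correctly *given* segmental transfer and
a compositional contrast; they do not calibrate absolute performance on
real genomes.

## Asymmetric Wagner parsimony

Per family, a Sankoff dynamic program over presence states {0, 1} on the
species tree, with cost r for a gain (0→1), 1 for a loss (1→0) and 0
otherwise; the gain/loss penalty ratio r is the stringency axis (default
sweep 1–8). Three conventions the literature leaves open are fixed here:

* **Root charging**: presence at the root is charged one gain (cost r),
  reported with the root label as recipient, and the root state is chosen
  to minimize the total including that charge. Every present family is
  then gained exactly somewhere, making gain counts comparable across
  families.
* **Tie-breaking**: among minimum-cost labelings the top-down traceback
  prefers absence. This is the conservative convention (fewest inferred
  presences, hence fewest spurious gains) and makes the per-family gain
  count deterministic and non-increasing in r, which the suite checks
  against exhaustive enumeration on all labelings of random ≤6-leaf trees.
* **Binary presence**, not copy numbers: the evaluation consumes
  (family, branch) gains, so copy-number machinery would add nothing
  testable.

For r above the leaf count the reconstruction collapses to a single origin
per family (the Dollo limit), also verified.

## The Wn-style typicality detector

The detector scores each gene against its host genome's k-mer composition,
rank-orders the scores ascending, and cuts the atypical head of the curve.

* **Score**: the negative Kullback–Leibler divergence of the gene's
  empirical k-mer frequencies from the genome background (all genes plus
  reverse complements, pseudocount 0.5 on every k-mer),
  $\mathrm{score} = \sum_w p_\mathrm{gene}(w)\log_2 \frac{f_\mathrm{genome}(w)}{p_\mathrm{gene}(w)}$.
  This is 0 for a background-matched gene and decreases in every direction
  of composition space. The simpler cross-entropy
  $\sum_w p_\mathrm{gene}(w)\log_2 f_\mathrm{genome}(w)$ was rejected after
  analysis: it is *linear* in the gene's composition, so it ranks genes
  that exaggerate the background's dominant k-mers above background-matched
  genes — on synthetic genomes, GC-shifted genes landed at the *typical*
  end of the curve whenever the shift pointed along the background's GC
  skew, inverting the detector. KL divergence measures the dissimilarity of
  the two frequency vectors directly. The score is length-normalized;
  self-concatenating a gene changes it only through the k−1 junction
  windows and the smaller estimation bias at twice the window count,
  O(k/L + 4^k/L) in practice.
* **Smoothing window**: Savitzky-Golay (order 3), candidate windows
  5, 7, …, 101. A rule that lengthens the window while the RMSE of the
  smoothed curve against the *original* decreases can never trigger — that
  RMSE grows monotonically with window length — and would always return
  the smallest window, leaving the double derivative noise-dominated. The
  rule used instead keeps the longest filter whose output is still
  *converging*: candidates are tried ascending and lengthening stops at the
  first window whose RMSE against the previous filter's output is no lower
  than the preceding comparison. A curve the filter reproduces exactly
  (any ≤3rd-degree polynomial) short-circuits to the smallest window, and
  a curve shorter than the smallest candidate gets no smoothing.
* **Cut rule**: with the smoothed ascending curve's second central
  differences d2, the cut is the largest rank in the lower half of the
  curve where |d2| exceeds s × MAD0, and genes ranked below it are flagged;
  the multiple s is the stringency (sweep 4–13). MAD0 — "the MAD of the
  double derivative around zero" — is measured on the *raw* curve's second
  differences. This choice is load-bearing: the raw-curve MAD estimates
  the order-statistic noise floor, so only structure that survives
  smoothing (a genuine kink where the atypical head joins the bulk) beats
  the threshold. Measuring MAD0 on the smoothed curve instead rescales the
  threshold with the smoothing and leaves it comparing the curve against
  its own intrinsic tail curvature — a *noiseless* Gaussian quantile curve
  then flags 12.5% of genes at s = 4, and simulated null genomes flagged
  11–48%, swamping any real signal. With the noise-floor MAD, null genomes
  flag ~2% at s = 4 and implanted genes (5%, GC shift 0.3, k = 4) are
  recovered with recall 1.0 in the synthetic experiments. A curve with
  MAD0 at floating-point zero (e.g. perfectly linear) flags nothing, by
  message rather than error.
* **k**: default 8 as used on real genomes; the synthetic experiments use
  k = 4 (and k = 2–3 in unit tests) because 8-mers are undersampled on
  300-bp genes — with 4^8 = 65,536 k-mer types and ~300 windows per gene,
  per-gene frequencies at k = 8 are pure noise at this scale. Background
  counting is chunked so the 4^k-column count matrix never materializes
  for a whole genome at once. Taxa with fewer than 30 genes are skipped
  with a warning: the rank-curve geometry is meaningless below that.

The detector assigns no donors (parametric methods cannot), and its flag
sets shrink weakly as s grows, by construction of the cut rule.

## Method comparison

Events are keyed by (family, recipient branch) — donors are dropped so
donor-bearing and donor-less methods can be intersected. Similarity between
two inference sets is the maximum Overlap Coefficient
|A∩B| / min(|A|, |B|) over the Cartesian product of their stringency
levels (empty levels skipped; an all-empty set is an error, not zero);
distance is 1 − maxOC. UPGMA clustering is implemented directly (~30
lines) rather than through `hclust` so that ties merge by the
lexicographically smallest pair of cluster names and the output newick is
bit-reproducible; a test confirms its heights equal
average-linkage `hclust` heights halved on generic matrices. Merge height
is half the merge distance, so root-to-tip path lengths are ultrametric.

## Problem sizes and runtime

The synthetic experiments are sized for a laptop-class single core: 30-taxa
trees with 1,200-gene root genomes for the false-positive-rate experiments
(10 seeds; observed ordering 6.6% > 5.2% > 2.9% neighbors at fpr 0/0.2/0.5,
10/10 seed-wise wins), 1,000-gene genomes with 300-bp genes for the
detector experiments, 10^5 Monte-Carlo replicates for the null-model
oracle, and 1,000 random ≤6-leaf instances for the parsimony
brute-force comparison. The full test suite runs in about 90 s; the
acceptance script in about one minute.

## Known limitations

* The null-model formula inherits the boundary-gene approximation; it is
  exact only up to O(t²/g²).
* The simulator's donor-genome proxy (deepest evolved ancestor) means a
  donor's segment may predate gains on the donor's own terminal branch.
* Wn performance depends on k relative to gene length; the default k = 8
  is appropriate for full-length genes on real genomes, not for the
  synthetic scale, and no amelioration dynamics are modeled, so synthetic
  recall overstates what aged transfers would show.
* Only terminal-branch gains are evaluable; methods are compared on the
  subset of their inferences that reach extant genomes.
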