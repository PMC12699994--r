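---
title: "Topic-model phylogenetics: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic-model phylogenetics: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

topictree estimates species and population trees from multilocus DNA
without requiring an alignment.  This vignette explains the model behind
each stage, the tunable parameters and their defaults, what the bundled
simulator does and does not emulate, and the numerical choices that make
the results reproducible.

## The pipeline in one paragraph

Each locus is a small text corpus: every taxon (or population) contributes
one "document", namely its DNA sequence cut into consecutive,
non-overlapping k-mers ("words").  A latent Dirichlet allocation (LDA)
topic model fitted to each locus summarizes every document as a vector of
topic frequencies `theta` of length M.  Dropping one topic per locus (the
frequencies sum to one) and taking square roots, the topic frequencies
become continuous characters; concatenated over loci they form a
tips-by-characters matrix of dimension `n x sum_l (M_l - 1)`.  An unrooted
tree is then estimated by restricted maximum likelihood (REML) under
Brownian motion, the classic treatment of drifting allele frequencies.
Uncertainty is assessed by bootstrapping alignment columns (aligned data)
or each document's k-mer multiset (unaligned data) and summarizing the
replicate trees into a majority-rule consensus with percentage supports.

## k-mer decomposition

Sequences are tokenized from their first position into windows of length
k; a trailing remainder shorter than k is discarded, and windows never
overlap (overlap adds memory and compute without adding much information,
since adjacent windows are nearly redundant).  The window length balances
two failure modes: short k-mers match by chance, long k-mers never match.
Given a document of n residues and a target probability q of observing a
random k-mer, inverting `P(K in X) = 1 - (1 - |A|^-k)^n` gives

```
k_hat = ceiling(log_|A|(n (1 - q) / q))
```

with alphabet size |A| = 4.  The default q = 0.01 yields k = 9 for
documents around 1000 bp and k = 8 for the 300-420 bp range typical of
Sanger-era population loci; it is the unique round value consistent with
both regimes, and it is exposed as a parameter.  `k_hat` is computed per
document and aggregated over the documents of a locus by the maximum
(conservative against chance matches in the longest document; `median`
and `mode` aggregation are available).  For very long documents —
megabase-scale pooled reads — the formula keeps growing while empirical
accuracy plateaus, so a fixed k around 20 is the sensible manual choice
there; `locus_k(mode = "fixed")` supports single lengths and mixtures.
No reverse-complement canonicalization is applied: k-mers are words on
the strand as given.

Gap and ambiguity handling is explicit because it changes the science:

* `keep_all` — "-" is an ordinary symbol; gap-bearing k-mers encode indel
  placements and carry real signal in aligned data.
* `drop_gap_kmers` — windows are cut on the alignment and gap-containing
  windows are removed; surviving windows stay anchored to homologous
  columns.
* `strip_gaps` — gaps are excised first, i.e. the data are treated as
  unaligned; indels upstream of a window shift its reading frame.
* `drop_gap_columns` — gapped alignment columns are removed first
  (aligned loci only).

Windows containing "N" or "?" can be dropped (`drop_ambiguous`); all
other IUPAC codes pass through verbatim on the assumption they are rare.

## The per-locus topic model

LDA is the standard generative model: topic proportions `theta_d ~
Dir(alpha)` per document, word distributions `beta_m ~ Dir(eta)` per
topic, words drawn from the topic each token is assigned to.  The
package fits it by batch variational Bayes (Blei-style coordinate
ascent on a factorized posterior), implemented in C++ for speed; any
optimizer maximizing the same bound would do, and the tests pin the
behaviour that matters: rows of `theta` and `beta` sum to one within
1e-8, a fixed seed reproduces the fit bit-for-bit, and on corpora drawn
from the generative model with well-separated topics the recovered
`theta` is within 0.15 total-variation of the truth on average.

Defaults: M = 5 topics per locus with symmetric priors alpha = eta = 1/M,
at most 50 passes with early stopping when the evidence lower bound
stabilizes (relative change below 1e-4); each model is fitted to its
locus independently — no vocabulary sharing across loci, which is what
lets loci be processed in parallel and keeps the per-locus characters
independent.  Vocabulary pruning removes k-mers seen fewer than
`min_corpus_freq = 2` times in the locus corpus (singleton k-mers are
overwhelmingly private noise); documents left without tokens receive
uniform topic frequencies and a warning, so the character matrix stays
rectangular.  A fixed topic count is the default; `select_num_topics()`
offers the UMass-coherence alternative, scoring each candidate M by the
mean over topics of `log((D(w_i, w_j) + 1) / D(w_j))` over ordered top
word pairs and taking the argmax (ties to the smaller M).  In practice a
fixed M = 5 performs as well and is far cheaper, and all headline
analyses here use it.

## From frequencies to a tree

Treating each topic like an allele at an independent locus, the net
change of a frequency after t units of drift is approximately normal
with variance proportional to t, and the square-root transform
stabilizes that variance; hence the gene-frequency convention of the
character matrix (drop one topic per locus, take square roots).  Both
steps are optional flags: `drop_last = FALSE, transform = "none"` treats
the raw frequencies as generic continuous characters.

Under Brownian motion the REML likelihood of a tree is the joint density
of the n - 1 independent contrasts produced by pruning,

```
logL = -(p/2) sum_i log(2 pi v_i) - (1/2) sum_i ||u_i||^2 / v_i ,
```

with contrast vectors `u_i` over the p characters and variances `v_i`
determined by the branch lengths.  This equals the multivariate-normal
REML computed from the full tree covariance with one tip differenced out
(the change of contrast basis is unimodular), which the tests verify to
1e-6 on every topology with up to six tips.  The rate constant is fixed
at one — it is not separately identifiable from the branch lengths.  A
tip missing from a locus is an error by default; uniform-frequency
imputation is available and flagged loudly, since it dilutes rather than
fabricates signal.

Two exact numerical devices keep this fast.  First, the likelihood
depends on the data only through the scatter matrix `S = X X'`, so X is
replaced by an n-by-n square root of S (p is kept for the determinant
term); evaluations become O(n^2) regardless of the number of characters.
Second, branch lengths are optimized by coordinate ascent with
golden-section line searches under a non-negativity constraint,
sweeping until the likelihood gain falls below 1e-6 (cap 1000 sweeps);
zero-length proposals are kept at zero and floored at 1e-8 only inside
the variance computation.  The ascent never returns a likelihood below
its starting point.

The topology search is stepwise addition — tips join in input row order,
every edge is scored as an insertion point with a cheap
branch-length optimization, ties keep the first candidate — followed by
nearest-neighbor-interchange sweeps; with `global_rearrangements = TRUE`
(default) sweeps restart until no swap improves the likelihood, and the
final tree is re-optimized at full tolerance.  The search is
deterministic given the row order.  On five tips it provably attains the
exhaustive optimum over all 15 topologies (tested), and insertion-order
permutations reach the same optimum there.

## Bootstrap and consensus

Aligned loci are resampled by drawing alignment columns with replacement
(identically across rows, independently across loci; loci themselves are
not resampled).  Unaligned data are resampled at the k-mer level: within
each document, as many k-mers are drawn with replacement as the document
holds, conserving document sizes exactly.  Resampling is per document
rather than pooled across documents — pooling would move k-mers between
taxa and destroy precisely the signal the tree is built from.  The k-mer
length is estimated once from the original data and held fixed across
replicates.  Replicate seeds are derived deterministically from the
master seed, so runs are reproducible and replicates could be computed
in any order.  Majority-rule consensus keeps bipartitions occurring in
strictly more than half of the replicate trees (a compatible set by
construction) and labels them with integer percentage supports.

## The simulator, and what it does not emulate

`simulate_locus()` grows a root sequence of 1000 bp from the base
frequencies and evolves it down a guide tree: per branch of length t,
insertion and deletion event counts are Poisson with mean `rate * t` per
site for each process, positions are uniform, tract lengths are
geometric with mean 12 bp, inserted residues are drawn from the base
frequencies, and substitutions follow Jukes-Cantor (HKY with
transition/transversion bias and unequal frequencies is available).
Column identity is tracked through the whole event history, so the true
alignment and the gap-free sequences are both returned and agree exactly
(stripping gaps from any alignment row reproduces that taxon's
sequence).  Indel events are applied before the branch's substitutions
rather than interleaved in a full Gillespie scheme; at the rates studied
the difference is negligible.

The two guide-tree shapes (7 and 14 species, the second joining two
copies of the first) use external branches of 0.05 and internal branches
of 0.02 substitutions/site.  These defaults were chosen once so that
moderate-indel loci (rate 0.02/site, mean tract 12 bp) land in a
realistic 800-2000 bp alignment-width band; at the extreme rate
(0.2/site) alignments inflate to roughly 3 kb because every insertion
anywhere on the tree adds columns.  Geometric tract lengths match the
single moment we target (mean 12); real indel-length distributions are
heavier-tailed (power-law-like), and real loci also violate the
simulator's other simplifications — no rate heterogeneity across sites,
no base-composition drift, no selection, loci strictly independent and
identically distributed.  Passing the simulation study therefore
demonstrates correctness of the machinery under the stated model, not
performance guarantees on empirical data.

A consequence worth stating plainly: with these branch lengths the
gap-stripped ("unaligned") treatment of the extreme-indel 14-species
scenario retains enough in-frame k-mer signal that 1000 loci usually
recover the topology.  Pairwise k-mer sharing under gap-stripping is
dominated by reading-frame coincidence rather than homology — we verify
this directly — but overwhelming the honest signal with that noise
requires substantially deeper trees than the width band permits under
our event-rate parameterization.  Deeper calibrations make the
unaligned treatment fail while aligned and gap-kmer-dropping treatments
keep working; the qualitative ordering of treatments is robust, the
collapse point is calibration-dependent.

## Scoring reconstructions

Robinson-Foulds (RF) distance counts bipartitions present in exactly one
tree; the weighted variant sums absolute branch-length differences over
the union of bipartitions (pendant edges included, absent bipartitions
contributing their full length).  A reconstruction is "close" to the
truth when its RF distance is at most 4: one NNI changes at most one
bipartition per side, so two rearrangements correspond to RF <= 4; the
threshold is exposed (`max_rf`) because "a small number of
rearrangements" admits other operationalizations.  Random-tree baselines
use uniformly distributed labeled unrooted binary topologies generated
by sequential addition to a uniformly chosen edge.

## Problem sizes used by the bundled studies

The package's own validation runs use 10 replicates per scenario at 1000
loci for the simulation studies, 10,000 random trees for the 90-taxon RF
baseline, and 1000 bootstrap replicates for the 9-population
consensus demonstration; these sizes give stable proportions (binomial
SE below 0.16 at C near 1) while keeping a full validation run on a
single core in the tens of minutes.

## Known limitations

* Topic frequencies are treated as independent Brownian characters; their
  sum constraint and sampling covariance within a locus are ignored, as
  in the classical gene-frequency treatment.
* LDA fits on very long documents (hundreds of tokens per document with
  few documents) tend toward one-hot topic assignments, discretizing the
  characters; the tree then rests on co-assignment patterns across loci.
* Branch lengths are in units of accumulated topic-frequency drift, not
  substitutions; compare topologies, not lengths, across methods.
* The consensus tree reports support only for bipartitions above 50%;
  weakly supported structure collapses into polytomies.
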