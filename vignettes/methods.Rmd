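---
title: "Methods: heterology-index prediction of prophage SOS dependency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterology-index prediction of prophage SOS dependency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sosdep)
```

## The model

LexA represses the SOS regulon — and classically, prophage lytic genes —
by binding a conserved palindromic operator, the SOS box (canonical
E. coli form `TACTG(TA)5CAGTA`). The binding potential of a candidate
window is modeled by its heterology index against a position count
matrix built from aligned operator sites:

$$HI(w) \;=\; \sum_{i=1}^{L} \ln
\frac{n_i(\text{consensus}_i) + p}{n_i(w_i) + p}$$

with pseudocount $p = 0.5$ (the classical formulation; configurable).
HI is zero exactly when every position carries a count-maximal base,
non-negative everywhere, and additive over positions. Lower HI means
stronger predicted binding.

The central empirical observation the predictor exploits is that the
genome-wide HI distribution of core-matching windows is bimodal: a small
low-HI component (real operators, under purifying selection) is well
separated from a large high-HI component (chance core matches). The two
components are recovered per genome by clustering, and their inner edges
become the classification thresholds:

* `HI_C1` — maximum of the low cluster (upper edge of "binds");
* `HI_C2` — minimum of the high cluster (lower edge of "does not bind").

A prophage is then called by the minimum HI over its promoter windows:
`HI_min <= HI_C1` → SOS-dependent (SdP); `HI_min >= HI_C2` →
SOS-independent (SiP); strictly between → uncertain (SuP). Boundaries
are inclusive because the thresholds are themselves cluster members: a
value equal to `max(low_cluster)` *is* a low-cluster value.

Assumptions worth stating plainly: (i) LexA-mediated repression is the
only SOS coupling modeled — a prophage whose repression runs through a
non-LexA pathway will be called by its operator content regardless;
(ii) the count matrix transfers across taxa reasonably well because the
operator is conserved, but the thresholds do not — they are derived per
genome and never pooled; (iii) a genome is only callable when its own
LexA autoregulation is visible (lexA present, canonical SOS box in the
lexA promoter).

## Pipeline gates and their parameters

| step | parameter | default | why |
|---|---|---|---|
| lexA detection | `lexa_min_score` | 1.0 | local-alignment score per reference residue (BLOSUM62); identical full-length LexA scores ≈ 5, unrelated proteins < 0.5 |
| CSB confirmation | `csb_cutoff` | 12 HI units | generous ceiling that accepts any operator plausibly in the low component; used **only** to confirm CSB presence, never for classification |
| promoter windows | `upstream_len` / `into_gene_len` | 300 / 50 bp | wide enough to contain operators near any realistic transcription start; windows are per-CDS and deliberately not merged or clipped at neighboring CDSs |
| PSB candidacy | core match + `mismatch_allowance` | CTG at 3–5, CAG at 16–18; 0 mismatches | reproduces a selected candidate set with a bimodal HI distribution instead of scoring all windows; the core is the invariant heart of the palindrome |
| clustering | `method`, `bandwidth`, `min_psb_count` | mean shift, Silverman, 10 | see below |

The promoter window length and the exact PSB candidacy rule are genuine
design choices: the method description we reimplement does not pin them
down, so both are exposed as parameters, and the package treats the
defaults as its own convention rather than a confirmed match to any
external implementation. The same holds for the CSB confirmation rule (a
fixed HI ceiling rather than cluster membership — confirmation must
happen *before* clustering is attempted).

## Threshold derivation

One-dimensional mean shift with a Gaussian kernel is the default: every
point ascends the kernel density estimate to its mode; points whose
modes coincide (within half a bandwidth after sorting) form a cluster.
It needs no cluster count, and the procedure is deterministic and
order-invariant, which the test suite asserts directly. The bandwidth
defaults to Silverman's rule, $0.9\,\min(\sigma, IQR/1.34)\,n^{-1/5}$,
and is flag-overridable.

Two deliberately simple baselines are included for comparison:
`kmeans2` (2-means with deterministic quantile starts) and `otsu` (the
classical between-class-variance threshold). On cleanly bimodal samples
all three agree with a brute-force KDE-valley split; mean shift is the
default because it degrades most gracefully when a component is skewed.

Guard rails: fewer than `min_psb_count = 10` values, all-identical
values, a single recovered mode, or inverted edges
(`HI_C1 >= HI_C2`) all yield `AMBIGUOUS` — a reportable outcome, not an
error, and downstream prophages are emitted with class `NA`. With more
than two clusters the extreme clusters define the thresholds and
intermediate points belong to neither (they fall into the SuP gap,
preserving the threshold semantics). A prophage whose promoters contain
no candidate operator at all is called SiP with an explicit
`no_psb_flag`: under the model, LexA repression without an operator is
impossible; the flag keeps the policy auditable.

## Numerical conventions

* Internal coordinates are 0-based half-open; every report emits 1-based
  inclusive with a `# coords=1-based` header comment.
* Windows containing `N` are skipped by all scanners.
* Forward and reverse-strand windows over the same interval are
  deduplicated keeping the lower-HI orientation; because the packaged
  matrix is palindromically symmetrized the two scores are equal, and
  only a difference beyond 1e-9 counts as a strand preference (round-off
  ties resolve to `+`).
* Consensus ties in `build_sos_matrix()` break toward the canonical
  E. coli box base, then alphabetically; the consensus is always
  recomputed from counts on load, never trusted from a file.
* Percentages are rounded half-up (2 decimals in class summaries,
  1 decimal in validation reports); `exact_binomial_ci()` is the
  Clopper–Pearson beta-quantile closed form, chosen because the exact
  method's boundary form $(\alpha/2)^{1/n}$ reproduces published
  validation intervals.
* Replicons are treated as linear by default; `circular = TRUE` wraps
  scan windows and promoter extraction across the origin instead of
  truncating.

## The packaged scoring matrix

The default matrix (`inst/extdata/sosbox_matrix_synthetic.tsv`) is a
constructed stand-in, not a published site alignment: counts over 50
pseudo-sites arranged around the canonical box, with an invariant
CTG/CAG core, realistic per-position degeneracy, and exact palindromic
symmetrization (`counts[i][b] = counts[L+1-i][complement(b)]`, so both
strands of any window score identically). It is labeled synthetic in its
filename and header and is a documented, user-replaceable input — for
organism-specific work, supply a matrix built from curated sites in the
same TSV format. Its maximum reachable HI with the core fixed is ≈ 27,
comfortably above the high-HI component it needs to represent.

## What the synthetic fixtures emulate — and what they do not

`generate_fixture()` builds a fully annotated replicon (~33 kb by
default): a planted lexA gene carrying the packaged reference
translation with a consensus CSB ending 80 bp upstream of its start
codon; 30 background genes whose promoters carry operators designed to a
low/high HI mixture (15 from N(7, 1) clamped to [5, 9] and 15 from
N(22, 2) clamped to [19, 25], mirroring the two components observed in
E. coli); and four prophage regions whose single operator is designed to
HI 3, 4, 25 and 26 — at least 2 HI units clear of any threshold the
mixture can produce, so planted-truth recovery is a sharp test. The
operator designer is a greedy hill-climb over non-core positions
(exact, because HI is additive), with a two-substitution fallback for
targets near the reachable extremes; designs land within ±0.25 of
target. The background is scrubbed of accidental `CTG-N10-CAG` cores,
so the planted operators are provably the only scannable candidates and
the truth tables are exact. Generation is byte-deterministic in the
seed.

What this does *not* emulate: real intergenic composition and operator
clustering, overlapping genes, multi-operator promoters, compound
(join) CDSs, plasmids, or hosts whose HI mixture is skewed or poorly
separated. Passing the planted-truth suite therefore demonstrates that
the machinery is correct under the stated statistical structure — not
that real genomes always present so clean a bimodality. The one check
that ties the pipeline to a real genome (the E. coli K12 HI bimodality
with components near 7.3 and 22.3) requires downloading that genome and
is reported as unmet when the file is not staged.

## Problem sizes

The shipped test and acceptance runs use: 20 fixture genomes (~33 kb,
39 CDSs, 35 planted operators, 4 prophages each) for planted-truth
recovery; 100 random 5 kb sequences against the brute-force scan
oracle; 1,000 random 20-mers against per-position hand summation of HI;
and 5 two-component samples of n = 200 against the KDE-valley oracle.
These sizes were chosen so the whole suite exercises every code path in
a couple of minutes while keeping every oracle comparison exhaustive at
its scale.

## Known limitations

* Published survey-scale figures (tens of thousands of genomes, genus
  distributions, feature contrasts between prophage classes) are out of
  desk-scale reach and are not asserted anywhere; the package computes
  the per-genome quantities from which such surveys are built.
* The PCO statistic ("proportion of CDS overlap") has no published
  formula; this package defines it as pairwise-overlapping CDS bases
  over total CDS bases, `(sum of lengths − union) / sum of lengths`,
  and documents it prominently since alternatives exist. Likewise the
  nucleotide-frequency divergence is implemented as a cosine distance
  on k-mer frequencies (k configurable, 1 and 2 reported) as a
  reasonable reading of an underspecified metric.
* GenBank support covers the single-interval CDS subset the package
  consumes and emits; compound `join(...)` locations are skipped with a
  warning (supply GFF3 for such annotations).
* LexA detection uses similarity to packaged reference sequences; a
  profile-HMM search would extend reach into distant taxa but would add
  a heavyweight dependency for no gain at the scales tested here.
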