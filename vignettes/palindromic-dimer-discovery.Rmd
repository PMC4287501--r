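---
title: "Palindromic dimer discovery in metagenomic promoters: models and methods"
author: "palinreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Palindromic dimer discovery in metagenomic promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palinreg)
```

# The problem

Prokaryotic transcription factors frequently bind DNA as homodimers, and
their binding sites are correspondingly often inverted repeats: a short
word, a stretch of unconstrained spacer bases, and the reverse
complement of the word. `palinreg` exploits this structural signature to
discover candidate transcription-factor binding sites (TFBS) *de novo*
in promoter collections extracted from metagenomic reads — without any
reference to known motif databases, so that well-studied taxa are not
favoured over the rest of a community.

The package covers the whole protocol: (1) extraction of proximal
promoter regions from long reads using protein-alignment evidence for a
downstream gene, (2) enumeration and Poisson scoring of palindromic
dimer motifs, (3) downstream statistics that treat the per-promoter
count of distinct significant motifs as a measure of *regulatory
potential*, and (4) randomization controls. A synthetic-data module
generates every input with planted ground truth, so each stage is
testable end to end.

# Promoter extraction

A read contributes a promoter when

* it is at least `minReadLength` (default 800) nt long — long enough to
  hold both a recognizable gene fragment and a full upstream window;
* it carries a protein alignment of at least `minAlignmentAA`
  (default 150, inclusive) amino acids at *strictly more* than
  `minIdentity` (default 50) percent identity;
* at least `requireNoncoding` (default 300) nt of the read lie upstream
  of that gene (downstream of it, for minus-frame hits) and no other
  accepted alignment intrudes into that window. The overlap rule is how
  the package operationalizes "non-coding": operon-internal genes,
  whose upstream neighbourhood is coding, are skipped.

The promoter is the `upstreamLength` (default 300) bases adjacent to
the coding start, reverse-complemented for minus-frame hits so that
every promoter reads 5'→3' towards its gene and its last base abuts the
coding start. When a read has several acceptable alignments, the single
best one (highest bitscore, ties by leftmost start, then subject id) is
used, so a read yields at most one promoter; this conservative policy
keeps downstream per-promoter statistics independent of local gene
density.

Internally all coordinates are 0-based half-open on the read's forward
strand; the tabular alignment dialect (1-based, inclusive, with
reversed coordinates encoding minus frames) is converted at the file
boundary only. IUPAC ambiguity codes in input sequences are mapped to
`N` with a counted warning — Sanger-era reads contain them, and
dropping such reads silently would bias counts — while any other
character is an error. `N` positions never match any motif word.

Redundancy is removed by greedy single-linkage-style clustering at
`dedupIdentity` (default 0.98) global-alignment identity (matches over
alignment columns, Needleman–Wunsch with match +1 / mismatch −1 and
affine gap costs). Promoters are visited in a deterministic order
(descending informative-base count, then id), so the representative
set is reproducible; re-running the clustering on the representatives
is a fixed point. Externally detected contaminants — eukaryotic reads,
ncRNA, re-predicted coding regions, CRISPR arrays — are removed via
id lists supplied by the user; the package does not re-implement those
detectors.

# The dimer model and its statistics

A candidate motif is a **palindromic dimer** $D = W_1 N^{s} W_2$ with
$W_2 = \mathrm{revcomp}(W_1)$, word width $|W_1| \in \{3,4,5\}$ and
spacer $s \in \{0,\dots,30\}$: $4^3+4^4+4^5 = 1344$ words times 31
spacers $= 41\,664$ candidates, spanning motif lengths 6–40 nt. Every
pattern is its own reverse complement, so scanning one strand finds all
instances on either strand; overlapping instances all count, and no
masking is applied.

For each dimer the package counts the observed instances $n(D)$ over
the pooled promoter set and compares them with the expectation under an
independence background. With $n(W_1)$, $n(W_2)$ the total (overlapping)
occurrences of the two words, and the *effective length*

$$L_\mathrm{eff}(\ell) = \sum_r \max\!\big(0,\; L(r) - \ell + 1\big)$$

the number of positions where a pattern of length $\ell$ can sit, the
expected count is the frequency product

$$n_\mathrm{exp}(D) \;=\;
  \frac{n(W_1)}{L_\mathrm{eff}(|W|)} \cdot
  \frac{n(W_2)}{L_\mathrm{eff}(|W|)} \cdot
  L_\mathrm{eff}\!\big(L(D)\big).$$

Each word's per-position frequency is estimated from the data itself, so
the background absorbs the (possibly skewed) word composition of the
promoter collection, and only the *co-occurrence* of the two words at
the prescribed distance is scored. An alternative `"simple"` form,
$n(W_1)\,n(W_2)/L_\mathrm{eff}(L(D))$, is available for sensitivity
analysis; the frequency-product form is the default because it is the
one whose totals match simulated null counts (the test suite checks
observed-versus-expected totals on i.i.d. uniform promoters within
three binomial standard errors).

Significance is the upper Poisson tail

$$P(D) = \sum_{k \ge n(D)} e^{-n_\mathrm{exp}}\,
         \frac{n_\mathrm{exp}^k}{k!},$$

computed through the regularized incomplete gamma function
(`stats::ppois`), with $P = 1$ exactly when $n(D) = 0$. Because planted
or strongly overrepresented motifs routinely push $P$ below the double-
precision underflow threshold, the log-scale tail is stored alongside
and used for ranking, so "the motif with the smallest p-value" remains
well-defined.

A motif is called significant when $P < 1/N_\mathrm{motif}$, a
Bonferroni-style threshold in which $N_\mathrm{motif}$ is the number of
candidate dimers *observed at least once* in the data. Reading the
family size off the observed candidates makes the threshold
data-dependent but reproducible; counting the full candidate space
instead is available via `alphaFrom = "all"`. On 500 signal-free
uniform 300-nt promoters this calibration yields essentially no
significant calls (far below 1% of candidates), while a dimer planted
in 30% of the same promoters is recovered as the single most
significant motif.

Motif names use the compact field shorthand `"<spacer> <width> <word>"`
— `"10 3 ATC"` is the pattern `ATCNNNNNNNNNNGAT` — and the codec
round-trips the entire candidate space.

# Regulatory potential and functional statistics

The per-promoter count of *distinct* significant motifs (default; total
occurrences available via `mode = "occurrences"`) is the promoter's
regulatory potential. On top of it the package provides:

* **Density.** $D(x) = n_\mathrm{sites} / (N \cdot T_\mathrm{bp})$,
  sites per base pair of promoter sequence in environment $x$ (with
  $T_\mathrm{bp}$ the fixed promoter length, 300 bp). The statistic is
  invariant under duplicating promoters together with their sites, so
  environments of very different sequencing depth are comparable.
* **Top-k% groups.** Promoters ranked by count; the top-k% group is the
  smallest prefix holding $\lceil kn/100 \rceil$ promoters, extended
  across boundary ties, making membership a function of the counts
  alone. Groups are nested over the default list 1, 5, 10, 20, 30, 40.
  Coarse low/medium/high bins are cut at count tertiles with boundary
  ties assigned to the lower bin.
* **Within-environment enrichment.** For each group, hierarchy level
  and function label, a 2×2 table of group versus complement against
  has-function versus lacks-function over the annotated promoters of
  the environment, tested one-sided (enrichment) with Fisher's exact
  test and Bonferroni-corrected within each (group × level) family.
  Hierarchical SEED-style labels (`"Parent;Child"`) are tested at every
  prefix level, each level forming its own correction family. The
  group-versus-complement construction was chosen over group-versus-
  whole because it avoids counting a promoter on both margins.
* **Cross-environment comparison.** The same function compared between
  two environments' top groups, two-sided (the question is whether an
  enrichment is *maintained*, in either direction).
* **Co-occurrence by bin.** For each low/medium/high bin, the number of
  distinct (environment, function) assignments whose function occurs in
  exactly 1, 2, … environments, plus a Spearman correlation between a
  promoter's count and the number of environments sharing its function.
  Function sharing is computed on presence/absence, not abundance.
* **Kruskal–Wallis density tests** across environments (midrank tie
  correction, asymptotic chi-square p), with the degenerate all-equal
  case defined as $H = 0$, $p = 1$.

Exact tests go through `stats::fisher.test` / `stats::kruskal.test` /
`stats::cor.test`; the test suite verifies them against independent
brute-force enumeration (all 2×2 tables with $N \le 30$ against
`choose()`-based hypergeometric sums; a $3\times5$ Kruskal–Wallis toy
against $10^5$ rank permutations).

# Randomization control and known-motif comparison

The discovery pipeline is re-run on a copy of the promoters shuffled
within consecutive non-overlapping 20-nt windows. Permuting *within*
windows (rather than permuting the windows) was chosen because it
destroys motif structure while preserving local nucleotide composition
— the quantity the background model conditions on — so any real-versus-
shuffled difference reflects positional signal, not composition. By
default the significance threshold is re-estimated on the shuffled data
(`reuseAlpha = TRUE` reuses the real-data threshold). The two
per-promoter count distributions are compared with a two-sided
Mann–Whitney test; fully tied samples are reported as $p = 1$. On
planted data the test separates the distributions at $p < 0.01$; on
signal-free data it is calibrated.

Predicted sites can additionally be matched against a user-supplied
library of IUPAC consensus strings (RegPrecise-style). Matching is
exact consensus matching on both strands; PWM scanning is deliberately
out of scope. The headline number is the fraction of predicted sites
containing at least one known-motif match, and per-environment
per-motif counts feed the density statistic above.

# The synthetic-data module

The generators define the conditions under which the package's
guarantees are demonstrated:

* **Background promoters**: i.i.d. bases, default 500 promoters × 300
  nt at GC 0.5 — the promoter length matches the extraction default,
  and the set size keeps a full 41,664-candidate scan in seconds while
  leaving expected null dimer counts well away from zero.
* **Planted motifs**: default `TGACA` with spacer 8 in 30% of
  promoters, one copy each at uniform positions, spacer bases drawn at
  random so that only the flanking words carry signal.
* **Read fixture**: 18 read classes that place one read on each side of
  every extraction boundary (799/800 nt, 149/150 aa, 50.0/50.1%
  identity, minus frames, a 250-nt upstream case, an operon-like
  second gene, exact/5-mismatch/10-mismatch duplicate windows, an
  excluded read), with a truth table sufficient to predict every report
  count without running the pipeline.
* **Annotations**: one two-level label path per promoter, optionally
  biased so a designated promoter subset carries a designated label —
  giving a constructed enrichment outcome — or exchangeable for
  calibration checks.

What these fixtures emulate is the *logic* of the real inputs, not
their biology: there is no phylogenetic structure, no sequencing error,
no codon bias, and the background is exactly the model the scoring
assumes. Passing tests therefore demonstrate correctness of the
computations and calibration under the stated model, not performance on
real communities, where composition deviates from i.i.d. and the
Poisson background is only an approximation.

# Numerical and design choices

* Seeds are mandatory arguments of every stochastic operation and are
  applied to a private RNG stream, never global state.
* P-value ranking uses log-scale tails; ties below underflow cannot
  occur.
* Degenerate inputs have defined outcomes: empty FASTA → empty set with
  a warning; no observed motif → no significant set with an undefined
  threshold flagged; constant vectors in correlation tests → `NA` with
  a warning; fully tied rank-sum samples → $p = 1$.
* Whether words should be counted on both strands is genuinely open;
  the package counts the stored strand only. Dimer instance counts are
  strand-invariant anyway (the pattern is its own reverse complement);
  only the background word frequencies could shift slightly.
* One read yields at most one promoter (best hit). Data where several
  genes per read have genuine independent promoters would require
  relaxing this; the conservative default matches the non-coding
  filter's intent.

# Problem sizes

The shipped tests and the reproduction script use 30–500 promoters of
300 nt, the full 41,664-candidate space (reduced spaces for repeated
calibration loops), exhaustive 2×2 enumeration to $N = 30$, and $10^5$
permutations for the rank-test oracle — sizes chosen so the whole suite
completes in a few minutes on one CPU while keeping every estimate's
Monte-Carlo error far below the tested tolerances.

# Session info

```{r}
sessionInfo()
```
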