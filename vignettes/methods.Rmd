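---
title: "Methods: ancestral reconstruction and chronology analysis in srpAncestry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestral reconstruction and chronology analysis in srpAncestry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srpAncestry)
```

`srpAncestry` reconstructs ancestral protein sequences at deep nodes of the
SRP-system (Ffh/FtsY) and SecY family trees and asks whether those
ancestors were depleted in the amino acids recruited last into the genetic
code. This vignette is the package's own account of the models, the
parameters that matter, the synthetic-data generator, the numerical
choices, and what the tests do and do not establish.

## The substitution model

All residue likelihoods use the WAG empirical amino-acid model: a
reversible continuous-time Markov chain assembled from the published
symmetric exchangeabilities $s_{ij}$ and equilibrium frequencies $\pi$,
with rate matrix $q_{ij} = s_{ij}\pi_j$ normalized so that one unit of
branch length equals one expected substitution per site
($-\sum_i \pi_i q_{ii} = 1$). The parameters ship as a plain-text file in
the standard PAML "dat" layout (`inst/extdata/wag.dat`), residues in the
canonical order `ARNDCQEGHILKMFPSTWYV`; keeping the published ordering
explicit everywhere prevents silent index mismatches between the rate
table and the frequency vector.

Transition matrices $P(t) = e^{Qt}$ come from one symmetric
eigendecomposition of $D^{1/2} Q D^{-1/2}$ with $D = \mathrm{diag}(\pi)$,
cached inside the model object. This makes $P(t)$ exactly reversible up to
round-off and cheap to recompute for every branch of every replicate tree.
Tiny negative entries from round-off are clamped to zero and rows
renormalized.

Discrete-gamma rate heterogeneity (`wagModel(k, shape)`, category rates
normalized to mean 1) is available but **off by default**: the
reconstruction workflow this package implements is defined on plain WAG,
and no among-site rate variation is assumed anywhere in the defaults. This
is a deliberate design decision; reconstructions are conditioned on the
simplest stated model rather than a richer one the workflow never claimed.

## Marginal reconstruction and its gap semantics

Per-column likelihoods use Felsenstein pruning over all columns at once
(partial-likelihood matrices per node, column-sum rescaling with log
accumulators against underflow). Marginal posteriors at an internal node
combine the "up" partial (data below the node) with a "down" pass carrying
the rest of the tree and the $\pi$ root prior. Gaps (`-`) and unknown
residues (`X`) are missing data in the residue process: partial likelihood
1 for every state, so an all-gap column has log-likelihood exactly 0.

The residue process never decides where gaps go. That decision belongs to
a separate binary character per column — present (1) / absent (0) — evolved
under a 2-state reversible model with equal stationary frequencies and a
single indel rate. The rate is estimated by maximizing the binary
likelihood over the natural-log rate in $[-5, 2]$ (golden-section search,
tolerance $10^{-4}$); the bounds span indel processes from effectively
frozen ($e^{-5} \approx 0.007$ changes per substitution unit) to several
times the substitution rate. Columns are scored independently: no
multi-column indel blocks, because nothing in the workflow defines a block
model, and the simplest documented choice is preferable to an undocumented
one.

**Threshold semantics.** "An X% threshold for inferring gaps" means: call
the ancestral column a gap iff its absence posterior is $\ge X/100$.
Raising the threshold therefore monotonically lengthens the called
sequence — the direction in which replicate reconstructions behave in this
workflow (10% thresholds give the shortest, 90% the longest ancestral
sequences). Residue calls take the maximum-posterior residue with ties
broken alphabetically by one-letter code, for determinism.

## Resampling, consensus, clustering

Large alignments are reduced before reconstruction: sequences are grouped
into clusters, each replicate dataset draws one random member per cluster,
and the guide tree is pruned to the draw (`ape::keep.tip`; collapsed
unary nodes sum their branch lengths). Replicate alignments are **row
subsets of the master alignment** — columns are never realigned — so all
replicate reconstructions live on the same column coordinates and a
per-column simple-majority consensus is well defined. The consensus
alphabet includes the gap as a votable symbol; ties prefer residues over
the gap, then alphabetical order.

When no cluster file is supplied, a greedy single-linkage clustering on
percent identity substitutes: visit sequences in seed-randomized order;
join the cluster with the highest single-linkage identity if it reaches
`minIdentity` (default 30%, roughly the twilight zone below which
percent identity stops implying homology); if that cluster is full
(`softMax`), divert to the best unfilled cluster within 5 identity points,
else found a new cluster. The published workflow used a different
clustering tool; clustering here is a dataset-reduction device, not a
scientific claim, so a simple documented rule with file-based clusters as
the fidelity path (`parseClusterFile`) is the right trade-off. The greedy
rule as stated needs a join floor to be well defined (otherwise
mutually-unrelated sequences would chain into one cluster), which is why
`minIdentity` exists.

Randomness contract: replicate $r$ uses the seed substream
`seed + r`, and each null simulation $i$ uses `seed + i`, so results are
reproducible individually and independent of execution order.

## The simulation null and the depletion test

To ask whether an ancestral reconstruction is depleted in the late-code
residues (Cys, His, Phe, Met, Tyr, Trp), the observed count is compared
with reconstructions of sequences that *cannot* be depleted: tip datasets
simulated from the WAG equilibrium along the same tree, given the
empirical gap structure (gaps are copied from the template alignment per
taxon and column — indels are never simulated stochastically), then pushed
through the same reduction-reconstruction machinery. Each simulation
produces **one** cluster-reduced dataset, mirroring the simulation arm of
the workflow; the gap threshold for the simulation arm defaults to 10%.
The test reports the empirical one-sided p-value
$p = (1 + \#\{\text{null} \le \text{observed}\})/(n_{\mathrm{sims}}+1)$,
which is in $(0, 1]$, grows with the observed count, and is exact under
exchangeability; a z-score against the null moments accompanies it when
the null variance is positive. The p-floor is $1/(n_{\mathrm{sims}}+1)$,
so a null of at least 19 simulations is needed to reach $p \le 0.05$; the
package requires $n_{\mathrm{sims}} \ge 20$.

## The synthetic-data generator

`simulationScenario` fixes the study conditions the tests run under:

- **Tree**: rooted, with a basal duplication joining an `Ffh_` and a
  `FtsY_` paralog subtree, each split into a bacterial and an archaeal
  clade; internal nodes `preLUCA` (root), `LUCA_Ffh`, `LUCA_FtsY` are
  named. Balanced shape by default (every branch = `branchScale`), or a
  pure-birth shape rescaled to the same mean branch length.
- **Sequences**: root drawn i.i.d. from configurable root frequencies
  (default: WAG equilibrium), evolved along each branch through the model's
  transition matrices. The true root sequence is returned for recovery
  tests.
- **Gaps**: only by overlay from a template alignment, never simulated.
- **Depletion scenarios**: root frequencies with the six late residues at
  one tenth of their WAG values (renormalized) emulate an ancestor that
  predates the completion of the genetic code.

Problem sizes used by the verification suite, chosen as the smallest
scales at which each property is meaningfully exercised: brute-force
oracle checks on 2–4 taxa × 6 columns (full state enumeration is $20^3$
states per column at 4 taxa); threshold monotonicity on 16 taxa × 150
columns with shared N-/C-terminal gap blocks; depletion power and
calibration on the 64-taxon duplication tree, branch scale 0.3,
400 columns, 20 experiments of 20 null simulations each; null sanity on
16 taxa × 400 columns × 200 simulations at branch scale 0.05 (short
branches put reconstruction accuracy near its ceiling, so the
reconstructed Trp count is binomial to good approximation and the
$3\,\mathrm{SE}$ band around $L\pi_W$ is a sharp test).

What the generator does **not** emulate: real indel processes (gaps come
from masks), compositional heterogeneity across sites and lineages,
alignment error, and model misspecification (data are simulated under the
same WAG model used for inference). Passing tests therefore establish the
correctness and internal calibration of the machinery, not the robustness
of the biological conclusion to violations of WAG.

## Numerical and degenerate-input choices

- Column-sum rescaling of partial likelihoods with per-column log
  accumulators; a zero-likelihood column raises an error rather than
  returning `-Inf` silently.
- Argmax ties: alphabetical; consensus ties: gap last, then alphabetical.
- Isoelectric point: bisection on $[0, 14]$ to width $10^{-6}$; the net
  charge is strictly decreasing in pH and has opposite signs at the
  interval ends for every sequence under the default pK set, so
  convergence is guaranteed; a convergence guard flags
  $|Q(\mathrm{pI})| \ge 10^{-3} \cdot \text{length}$.
- `X` is excluded from hydropathy numerator and denominator; all-`X`
  sequences are a domain error.
- Pairwise identity: the pair denominator excludes gap–gap columns and
  counts residue–gap columns as mismatches; "positive" requires a strictly
  positive BLOSUM62 score. The exact gap convention of published identity
  figures is unstated, so these values are treated as soft anchors, not
  exact targets.
- Trimming: the conserved/flank thresholds default to their minimum
  (⌊n/2⌋+1) and 0.85·n; the relaxed preset (stretch 100, block length 2,
  gaps allowed everywhere) matches the permissive parameterization used
  for divergent protein alignments. Byte-equivalence with the original
  Gblocks binary is not claimed — its flank-scanning order is
  under-documented — only the published rule set.
- The localization call from mean hydropathy is an explicitly labelled
  heuristic (threshold 0.6, boundary inclusive); proprietary classifier
  internals are not reproduced.

## Known limitations

- Marginal, not joint, reconstruction: per-column posteriors are exact,
  but the called sequence is a column-wise argmax, not the jointly most
  probable sequence.
- The indel model is the simplest identifiable one (2 states, equal
  frequencies, one rate); agreement with richer indel-inference tools is
  qualitative (threshold-length monotonicity), not parameter-for-parameter.
- Branch lengths and tree topology are taken as given; no re-estimation.
- The depletion test conditions on the guide tree and the cluster
  structure; uncertainty in either propagates into neither the null nor
  the p-value.
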