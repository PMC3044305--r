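---
title: "Clustering ncRNAs from alignment and structure ensembles"
author: "bplaClust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering ncRNAs from alignment and structure ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(bplaClust))
```

## The problem

Hierarchical clustering of unannotated noncoding RNAs needs a similarity
measure that is sensitive to conserved secondary structure, because most
ncRNA families share less than 60% sequence identity and cannot be grouped
from primary sequence alone.  Exact structural alignment (the Sankoff
recursion) costs $O(|x|^3|y|^3)$ per pair and is unusable for
all-against-all comparisons; heuristic restrictions of it (LocARNA-style
banding, FOLDALIGN-style score thresholds, stem kernels) lose exactly the
suboptimal alignments and low-probability structures that carry the signal
at low identity.

`bplaClust` implements the opposite strategy: give up on *joint* structural
alignment entirely and instead use the **complete ensembles** of the two
tractable sub-problems —

* all pairwise **sequence alignments**, through the local alignment (LA)
  kernel, a Smith–Waterman recursion in which max is replaced by sum; and
* all **secondary structures** of each sequence, through base-pairing
  probabilities computed by a McCaskill-style partition function.

## The similarity measure

For sequences $x, y$ the LA kernel is

$$K(x,y) \;=\; \sum_{\pi \in \Pi_{xy}} e^{\beta\,\mathrm{Score}(\pi)},$$

summing over every local alignment $\pi$ (chains of matched position pairs
with affine gaps: open $g$, extension $d$), computed in $O(|x||y|)$ by the
sum-product recurrences over states $M, I_X, I_Y, T_X, T_Y$ with cell
weights $e^{\beta S_{xy}(i,j)}$, $e^{\beta g}$, $e^{\beta d}$ and
termination $K = 1 + T_X + T_Y + M$.  The reported similarity is the
normalized logarithm

$$\hat K(x,y) = \frac{\log K(x,y)}{\sqrt{\log K(x,x)\,\log K(y,y)}}
  \in [0,1],$$

and clustering operates on the distance $1 - \hat K$ with WPGMA linkage.

The position score $S_{xy}(i,j)$ is where structure enters.  For fixed
structures, matching two positions scores $\alpha$ if both pair downstream,
$\alpha$ if both pair upstream, and the substitution score $s(x_i, y_j)$ if
both are unpaired (zero in the four mixed cases).  Taking the expectation
over the two *independent* Boltzmann ensembles turns the binary
pairing-state indicators into the marginal profiles
$p^L, p^R, p^U$ (with $p^L + p^R + p^U = 1$ at every position):

$$S_{xy}(i,j) = \alpha\left(p^L_x(i)p^L_y(j) + p^R_x(i)p^R_y(j)\right)
  + s(x_i,y_j)\,p^U_x(i)p^U_y(j).$$

Two variants are provided.  `scoring = "bpla"` replaces every probability
product by its square root — the BPLA-kernel form, equivalent to
coefficients $C = (p\,p')^{-1/2}$ — which up-weights low-probability
("unsure") structure since $\sqrt{p} \ge p$ on $[0,1]$.
`scoring = "sequence_only"` drops structure entirely
($S_{xy}(i,j) = s(x_i,y_j)$, no folding), giving the plain LA-kernel
baseline.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 1.0 | weight of the paired-state match term (score units) |
| `beta` | 0.1 | inverse-temperature weight inside the kernel sum; larger values concentrate the sum on near-optimal alignments |
| `gapOpen` | −27 | first gapped residue of a block (score units) |
| `gapExtend` | −0.1 | each further gapped residue |
| `subst` | RIBOSUM85-60 | symmetric 4×4 single-nucleotide log-odds scores |

These are the published BPLA-kernel settings and are kept as the package
defaults.  At `beta = 50` the scaled log kernel
$\tfrac1\beta \log K$ reproduces the optimal Smith–Waterman score to
within 0.1 (tested), which is the sanity anchor for the DP.

## Folding backends

`foldPartition()` implements a deliberately minimal ensemble model: the
Boltzmann weight of a nested structure is
$\prod_{(i,j)\in\theta} e^{\,\mathrm{score}(x_i x_j)/T}$ over the six
canonical/wobble pair types, with a minimum hairpin loop of 3 and, by
default, every pair type scored 1.  Probabilities come from an
inside–outside recursion over the unambiguous grammar
$S \to aS \mid (S)S$ in $O(n^3)$, carried in log space so that no length
overflows.  This model has no stacking or loop entropies **by design**: its
ensembles can be enumerated exhaustively for sequences up to ~16 nt, so
every probability the DP produces is checked against brute-force Boltzmann
averages at $10^{-9}$, and closed forms (a two-structure ensemble gives
$p = w/(1+w)$) hold exactly.

The price of that simplicity is diffuse, weakly informative profiles on
realistic sequences: without stacking cooperativity, a conserved 10-bp
helix does not dominate the ensemble the way it does thermodynamically.
`foldWithBackend(seq, "vienna")` therefore adapts the ViennaRNA `RNAfold
-p` partition function (the full nearest-neighbor model) to the same
`BasePairProfile` contract, and this is the backend the package's own
end-to-end demonstrations use.  The builtin model remains the default for
unit-level verifiability and for environments without RNAfold.

## The synthetic benchmark

`makeBenchmark()` generates the three dataset conditions used throughout
the tests and the acceptance script:

* **normal** — `nFamilies` families, each grown from a random ancestor
  carrying an embedded multi-hairpin consensus (stems of 7–13 bp, loops of
  4–8 nt, unpaired spacers; pair types GC-biased).  Members mutate
  independently at rate $1 - \mathrm{targetIdentity}$: paired positions by
  compensatory redraws from the six canonical/wobble types, unpaired
  positions freely, plus rare single-nucleotide indels confined to
  unpaired runs.  For two members mutated at rate $\mu$ the expected
  pairwise identity is roughly $(1-\mu)^2 + \tfrac14(1-(1-\mu)^2)$, which
  stays within ten points of the target across the supported band — the
  generator is calibrated by that relation, not by fitting to outcomes.
* **flanks** — every sequence gains 5′ and 3′ flanks of a quarter of its
  length (round half up), sampled from a first-order Markov model fitted
  to the sequence itself with add-one smoothing, emulating unknown
  transcript boundaries with matched dinucleotide content.  (Exact
  dinucleotide preservation is impossible at a quarter length; for
  same-length decoys an exact Altschul–Erikson shuffle is available.)
* **unrelated** — one quarter as many singleton decoy clusters as true
  families, each a random sequence matched in length and dinucleotide
  model to a randomly chosen real member, emulating transcriptional noise.

What the generator does **not** emulate: phylogenetic correlation between
members (all descend independently from the ancestor), realistic indel
length distributions, rate heterogeneity along the sequence,
pseudoknots, and the family-size/length skew of curated benchmark
collections.  A clean pass on these data therefore shows that the measure
recovers conserved base-paired structure under compensatory divergence —
not that it reproduces any particular curated-benchmark figure.

## Evaluation

A clustering is scored against the known families by pairs-based ROC:
cutting the WPGMA tree at a threshold partitions the leaves, every
unordered pair is TP/FP/TN/FN by agreement between reference and resultant
co-membership, and the threshold sweeps 0 and every distinct merge height
$+ 10^{-12}$ (the step points of the curve).  AUC is the trapezoid over the
achievable step points, completed horizontally to fpr = 1; tie geometry can
shift rectangle-rule variants slightly, which is why the integration rule
is fixed and tested against an independent integrator.  Decoy singletons
contribute no same-reference pairs, so their effect is captured entirely
through false-positive pairs, as intended.

## Numerical and design choices

* **Kernel arithmetic** is log-space throughout (`log-sum-exp`); $K$ itself
  overflows doubles near length 500 at default parameters, $\log K$ never
  does.  The normalization consumes $\log K$ directly.
* **Recurrence fidelity**: the five-state DP is transcribed exactly as
  specified, including the asymmetric treatment in which a gap-in-$x$
  block may follow a gap-in-$y$ block but not vice versa (that ordering
  canonicalizes gap blocks so each alignment is counted once).  Symmetry
  of $K$ is obtained by computing each unordered pair once.
* **Normalization form**: the geometric-mean normalization of $\log K$ is
  the standard normalized log-LA-kernel; since $K \ge 1$ always, the logs
  are non-negative and the value clips cleanly to $[0,1]$.
* **WPGMA ties** are broken by the lexicographically smallest pair of
  cluster representatives (the representative being a cluster's smallest
  leaf id), so trees are reproducible and independent of input order.
* **Cut semantics** are strict (`height < threshold`), so a threshold equal
  to a merge height splits that merge; with monotone WPGMA heights the
  merges below any threshold form a prefix of the merge sequence.
* **Profiles** are validated to $p^L + p^R + p^U = 1$ within $10^{-9}$ at
  every position; sub-tolerance drift is clamped, anything larger is an
  error rather than a silent renormalization.
* **Degenerate inputs**: empty sequences are legal only in the kernel
  ($K = 1$); folding requires length ≥ 1; self-kernels with
  $\log K \le 0$ (possible only under pathological scoring) abort with the
  offending sequence named.

## Problem sizes

The shipped tests verify the kernel DP against brute-force enumeration of
all local alignments on hundreds of random pairs up to length 5, the
partition function against exhaustive structure enumeration on a hundred
random sequences up to length 12, WPGMA against the reference `mcquitty`
agglomerator on a hundred random 8-leaf matrices, and the end-to-end
discrimination property on 4-family × 4-member datasets of ~120 nt at
25–40% identity over five replicate seeds — sizes at which the exhaustive
oracles are exact and the full suite runs in well under a minute.
`scripts/acceptance.R` re-runs the end-to-end computation from scratch and
writes the resulting AUCs; see the README for how to reproduce it.

## Known limitations

* The builtin energy model is a verification instrument, not a
  thermodynamic one; quantitative work should use the `"vienna"` backend.
* Folding decoys and flanked sequences can pair flank against core; at low
  identity the flanked condition is markedly harder, and the package
  reports whatever the computation yields rather than correcting for it.
* Only nested structures are modeled (no pseudoknots), IUPAC ambiguity
  codes are rejected, and no multiple alignment or exact structural
  alignment is attempted.
```{r teaser, eval = FALSE}
bench <- makeBenchmark(4, 4, 120, c(0.25, 0.40), "normal", seed = 1)
run <- evaluateRun(bench$sequences, bench$reference,
                   scoring = "expected", backend = "vienna")
run$auc
```
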