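---
title: "Methods: inter-protein coevolution by mean-field DCA"
author: "pairdca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inter-protein coevolution by mean-field DCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairdca)
```

# The problem and the model

Two interacting proteins accumulate compensatory substitutions across
their shared interface. Given one sequence of each protein per species,
the species-wise concatenation behaves like a single protein family, and
any covariation between a column of protein A and a column of protein B
is a candidate inter-protein contact. `pairdca` quantifies that
covariation two ways.

**Mutual information.** For columns $i, j$ with single- and pair-column
frequencies $f_i(a)$ and $f_{ij}(a,b)$ over the $q = 21$ state alphabet
(20 amino acids plus the gap as a full state),

$$\mathrm{MI}_{ij} = \sum_{a,b} f_{ij}(a,b)\,
  \ln \frac{f_{ij}(a,b)}{f_i(a) f_j(b)} \quad \text{(nats)} .$$

MI is a model-free dependence measure, but it also picks up *transitive*
correlation: if $i$ couples to $k$ and $k$ to $j$, then $i$ and $j$
co-vary without touching.

**Direct information.** To separate direct from transitive signal, the
package fits the maximum-entropy pairwise (Potts) model consistent with
the one- and two-column statistics, in the mean-field (small-coupling)
approximation: with the connected correlations
$C_{ij}(a,b) = f_{ij}(a,b) - f_i(a) f_j(b)$ restricted to the reduced
alphabet ($q - 1$ states, the gap acting as the reference state of the
gauge), the couplings are

$$e_{ij}(a,b) = -\left(C^{-1}\right)_{(i,a),(j,b)}, \qquad i \neq j .$$

Each pair's *direct* two-site distribution
$P_{ij}(a,b) \propto \exp(e_{ij}(a,b))\, h_i(a)\, h_j(b)$ is then
completed by auxiliary fields $h$ chosen so its marginals equal $f_i$
and $f_j$, and

$$\mathrm{DI}_{ij} = \sum_{a,b} P_{ij}(a,b)
  \ln \frac{P_{ij}(a,b)}{f_i(a) f_j(b)} .$$

DI retains only the coupling the pair carries itself; in the package's
synthetic benchmarks it is what cleanly separates planted interaction
pairs from correlated background.

The model assumes sequences are independent draws from one family-wide
distribution. Real ortholog sets violate this through phylogeny, which is
mitigated (not removed) by similarity reweighting: each sequence gets
weight $1/n$, where $n$ counts sequences within $1 - \theta$ fractional
identity of it, and all sums use these weights. The weighted count
$M_\mathrm{eff} = \sum_m w_m$ is the effective sample size.

# Pipeline conventions

**Concatenation and spacer.** Sequences are concatenated A-then-B with a
spacer of 20 alanines between them. The spacer exists purely to make the
A/B boundary recoverable after external alignment; it is reference-
aligned like any other stretch, but its columns are excluded from the
analysed column set (they are artificial and have no variance), and pair
indices are reported in concatenated coordinates so the position map
translates them to per-protein residue numbers.

**Insert columns.** A column is an insert iff the designated reference
sequence (user-selectable; the first record by default) carries a gap
there. Removing inserts makes the cleaned length equal the reference's
ungapped length and gives every column a unique (protein, residue
number) label. This reference-based convention is the standard one; the
alternative (occupancy thresholds) would break the 1:1 residue mapping
the reporting depends on.

**Proximity filter.** Pairs with $|i - j| \le 5$ (boundary included) are
removed before any ranking, eliminating trivially covarying sequence
neighbours. Because the filter runs in concatenated coordinates and the
spacer is at least as wide as the threshold, it can never remove an
inter-protein pair. The boundary-included reading of "within five
residues" was chosen because it is the conservative one (it removes
more); `min_sep` is a parameter.

**Anchor ranking.** Domain spans (e.g. a PAS-domain interval) are user
configuration, not constants; ties in the sort score are broken by
ascending partner residue number so rankings are reproducible.

**Distances.** The default distance is the minimum over heavy-atom pairs:
reported side-chain contacts of 2–4 Å are invisible to Cα–Cα distances,
which remain available as a mode. When one segment maps to several
chains (a dimeric kinase), the minimum over chains is reported, since
which protomer a covarying pair touches is not identifiable from
sequence. Pairs whose residues are missing from the model keep an `NA`
distance rather than aborting the annotation.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `theta` | 0.2 | identity fraction | reweighting threshold: sequences within $1-\theta$ identity share weight; 0.2 is the conventional choice for protein families |
| `pseudocount` | 1 | multiple of $M_\mathrm{eff}$ | prior mass $\lambda$; $\lambda = M_\mathrm{eff}$ (a 50/50 mix) keeps $C$ well-conditioned for inversion |
| `spacer_len`, `spacer_char` | 20, `"A"` | residues | boundary marker between the proteins |
| `min_sep` | 5 | columns | proximity filter threshold |
| `di_tol` | 1e-4 | max marginal mismatch | convergence of the two-site field iteration |
| `di_max_iter`, `di_damp` | 500, 0.1 | — | fixed-point controls (see below) |
| distance `mode` | `heavy_atom_min` | Å | contact definition on the structure |

MI is computed from the *reweighted, un-pseudocounted* frequencies; the
pseudocounted model is used only where it is needed, for the inversion
and DI. A pseudocount of order $M_\mathrm{eff}$ would otherwise shrink
MI by a large factor and bias it far from the population value — with
the convention used here, the estimated MI of a planted pair at
$M = 5000$ stays within 10 % of the closed-form truth (the residual gap
is mostly gap-state dilution plus the usual positive finite-sample
bias, of order $(q^2-1)/2M$ nats).

# Numerical choices

- **Gauge and invertibility.** The inversion runs on the
  $(q-1)N$-dimensional reduced space with the gap as reference state;
  with $\lambda > 0$ all frequencies are strictly positive and $C$ is
  invertible in practice. A singular $C$ raises an error that suggests a
  larger pseudocount rather than silently regularising.
- **Field iteration.** The two-site fields are iterated from the
  deterministic start $h_i \propto f_i$ with light damping (0.1),
  tolerance $10^{-4}$ on the worst marginal mismatch, at most 500
  iterations. Strongly coupled pairs can oscillate; any pair that fails
  is retried once with heavy damping (0.8) and a 10-fold iteration
  budget, and only then reported as a convergence error naming the pair.
  The DI values are therefore reproducible to about the tolerance, which
  is why DI regression tests compare at 1e-3, not machine precision.
- **Zero-variance columns** are retained: pseudocounts keep every
  computation finite and a fully conserved column simply scores
  MI ≈ 0. Spacer columns, by contrast, are excluded up front (they are
  artefacts, not observations).
- **Degenerate inputs.** An all-gap reference row, an empty record list,
  mismatched map/alignment widths, residues outside the 20-letter
  alphabet (folded to the gap state with a warning, keeping the 21-state
  model closed), and absent anchor residues each have a defined error or
  warning path, exercised in the test suite.

# The synthetic generator and its oracles

`synthetic_spec()` describes a paired MSA with known structure: planted
inter-protein column pairs drawn iid per sequence from stored joint
tables, independent background columns with per-column Dirichlet(1)
profiles drawn once at construction, iid gaps, and optional mutated
clones emulating phylogenetic redundancy. Planted pairs form a matching
(no column reused), so sequences factorise over pairs: sampling is exact
(no MCMC), each pair's true MI follows by direct summation over its
joint, and — because each planted pair is the only coupling touching its
columns — the generator's own direct model is the joint itself, making
true DI equal true MI. The default joint (a 6-state permutation mixed
85/15 with a uniform background) has a true MI of 1.60 nats.

Defaults (30 + 40 residues, $M = 2000$, five planted pairs, 5 % gaps)
are the package's reference validation conditions: big enough that
mean-field inference is in its working regime, small enough that the
full pipeline runs in seconds. The validation suite uses $M$ up to 5000
for estimator-consistency checks and ten replicate seeds for recovery
rates; the larger completeness checks run 200-column alignments.

What the generator does *not* emulate: tree-structured phylogeny (clones
are star-shaped around their parent), alignment errors, column-count
variation between species (all sampled records are already the same
length, and the reference row is kept gap-free by default so cleaning is
the identity and planted column indices survive), and negative design or
multi-body constraints. Passing the recovery benchmarks therefore shows
the estimator chain is correct and well-calibrated on its own model
class — not that real interfaces are recoverable at any given alignment
depth.

# Known limitations

- Mean-field inversion is a first-order approximation; for very strong
  couplings or tiny $M_\mathrm{eff}$, pseudolikelihood methods dominate.
  They are out of scope here, as are average-product correction and
  benchmark scoring against contact databases.
- The pipeline consumes a pre-computed complex model; distances inherit
  whatever error the docking carries, and the minimum-over-chains
  convention can only underestimate the protomer-resolved distance.
- Ortholog curation (which sequences are true one-to-one partners) is
  the user's responsibility; mispairing directly injects noise into the
  pair statistics.
- Scores carry no significance calibration; rankings are relative
  within one alignment.

# A compact demonstration

```{r demo, eval = FALSE}
spec <- synthetic_spec(M = 1000, seed = 11)
rec <- sample_paired_msa(spec)
cc <- concatenate_with_spacer(rec)
seqs <- cc$sequence; names(seqs) <- cc$species_id
aln <- remove_insert_columns(alignment_matrix(seqs))
map <- build_position_map(aln, len_a = 30, spacer_len = 20)
fit <- dca(aln, position_map = map)
inter <- restrict_inter_protein(filter_proximal_pairs(fit$pairs, 5), map)
evaluate_recovery(inter, spec, k = 5, by = "di")$precision
plot(fit)   # MI vs DI; planted pairs separate on the DI axis
```
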