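---
title: "Cone-based graphical and statistical descriptors for alignment-free protein comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cone-based graphical and statistical descriptors for alignment-free protein comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Alignment-based phylogenetics becomes fragile when sequences are highly
diverged, rearranged, or simply numerous. Alignment-free methods sidestep
this by mapping each sequence to a fixed-length numerical descriptor and
comparing descriptors instead of residues. `fegs` implements one such
descriptor for proteins: a fusion of *graphical* features -- geometry-derived
summaries of a 3D curve built from the sequence -- with the two classical
*statistical* features, amino-acid composition (AAC) and dipeptide
composition (DPC).

## The graphical model

### Cone embedding

Each descriptor component starts from one physicochemical property index:
a table assigning one real value to each of the 20 standard amino acids
(the AAindex1 database is the canonical source; `read_aaindex()` parses its
flat-file layout). The amino acids are sorted by ascending property value
and placed, in that order, on the unit circle of the base plane (height 1)
of a right circular cone:

$$\phi(\Omega_i) = \left(\cos\frac{2\pi i}{20},\ \sin\frac{2\pi i}{20},\ 1\right),
\qquad i = 1, \dots, 20,$$

so the last-sorted amino acid sits at angle $2\pi$, i.e. at $(1, 0, 1)$.
Only the *rank order* of the property values enters the construction; the
magnitudes are qualitative labels. Ties in property values are broken by
ascending one-letter code -- the sources that define such indices do not
dictate a rule, and a deterministic one is required for reproducible
layouts. Each ordered amino-acid pair is placed a quarter of the way along
the chord from its first vertex to its second:

$$\phi(\Omega_i\Omega_j) = \phi(\Omega_i) + \tfrac14\left(\phi(\Omega_j) - \phi(\Omega_i)\right),$$

which leaves self-pairs on their vertex and all 400 pair points in the
base plane.

### The 3D curve

A sequence $S = s_1 s_2 \cdots s_N$ is traced as a path from the origin:

$$\psi(S_i) = \psi(S_{i-1}) + \phi(s_i) +
  \sum_{\Omega_1\Omega_2} f_{\Omega_1\Omega_2}\,\phi(\Omega_1\Omega_2),$$

where $f_{\Omega_1\Omega_2}$ is the frequency of the dipeptide
$\Omega_1\Omega_2$ among the $i - 1$ overlapping adjacent pairs of the
prefix $s_1 \cdots s_i$. "Frequency" admits two readings and
`protein_path()` implements both behind the `freq` flag:

* `"count"` (default): raw occurrence counts. This is the simpler literal
  reading, and because every mapped point has $z = 1$ it gives the exact
  closed form $z_i = i(i+1)/2$, which the test suite asserts.
* `"relative"`: counts divided by $i - 1$, giving $z_i = 2i - 1$ for
  $i \ge 2$.

The naive inner sum over 400 pairs collapses to a running cumulative sum of
the points of the dipeptides actually observed, so path construction is
O(N).

### From curve to number

For the curve points $P_1, \dots, P_N$ (the origin anchor $P_0$ is *not* a
curve point and contributes no row -- it anchors the recursion but
corresponds to no residue), the **L/L matrix** has entries

$$M_{ij} = \frac{\lVert P_i - P_j \rVert_2}
               {\sum_{k=i}^{j-1} \lVert P_{k+1} - P_k \rVert_2},
  \qquad M_{ii} = 0,$$

the ratio of straight-line (chord) to along-curve (arc) distance. It is
symmetric and nonnegative, off-diagonal entries lie in $(0, 1]$, and
consecutive pairs give exactly 1. Its leading eigenvalue -- equal to the
spectral radius, computed with a dense symmetric eigensolver
(`eigen(symmetric = TRUE)`; for a homopolymer the matrix is $J - I$ and the
value is exactly $N - 1$) -- summarizes the curve's shape, and dividing by
the sequence length $N$ removes the length bias. One property index thus
yields one number; the curated 158-index configuration yields the
158-dimensional graphical block $V_g$.

## Statistical features and fusion

AAC is the 20-vector of residue frequencies (denominator $N$); DPC is the
400-vector of overlapping-dipeptide frequencies with denominator $N - 1$,
the number of windows, which makes it a probability vector (the standard
convention; the defining sources leave the denominator implicit). Pairs are
indexed first-letter-major: AA, AC, AD, ..., YY. The final descriptor is
the concatenation

$$V = [\,V_g\ (158) \mid V_a\ (20) \mid V_d\ (400)\,] \in \mathbb{R}^{578},$$

and a dataset of $N$ sequences gives an $N \times 578$ matrix (`fegs()`),
with columns named `g001..g158`, `aac_A..aac_Y`, `dpc_AA..dpc_YY`.

## Downstream phylogeny

* **PCA** (`fegs_pca()`): column centering only by default; a `scale` flag
  adds unit-variance scaling (constant columns are left unscaled). The
  component count is user-set or chosen as the smallest number reaching a
  95% cumulative-variance target -- published analyses of specific datasets
  pin specific counts (e.g. 28 for one 50-sequence globin set), so the
  count is always reportable and overridable. Each component's sign is
  fixed so its largest-magnitude loading is positive, making scores, trees
  and distances platform-reproducible.
* **Cosine distance** (`cosine_dist()`): $d = 1 - \cos\theta \in [0, 2]$;
  all-zero rows are rejected by name.
* **Trees** (`linkage_tree()`): agglomerative clustering under single or
  complete linkage via `stats::hclust`; both linkages are monotone, so
  merge heights never decrease. `to_newick()` exports an ultrametric
  phylogram (leaf-to-leaf path length equals merge height, i.e. heights
  halved per branch, the usual dendrogram convention).
* **Flat clusters and evaluation**: `cut_tree()` undoes the last $k - 1$
  merges; `adjusted_rand_index()` computes the Hubert--Arabie
  chance-corrected agreement (via `mclust`) between the cut and a
  taxonomic labelling, matching on sequence id.

## Synthetic data: what it does and does not emulate

Two generators make the package fully testable offline:

* `synthetic_properties()` draws i.i.d. standard-normal property values.
  Since the curve uses only rank orders, random continuous draws give
  distinct, valid orderings with probability one. Accessions are prefixed
  `SYN` to mark them as synthetic; the bundled
  `extdata/aaindex_synthetic.txt` is likewise a synthetic fixture in the
  genuine AAindex1 record layout (including one missing-value record and
  one exact duplicate, so the filter rules are exercised).
* `simulate_proteins()` / `simulate_protein_families()` draw i.i.d.
  residues (uniform by default) and derive family members from a common
  ancestor by independent per-site substitution. Defaults -- lengths
  100--200 aa (typical single domains; the worked analyses use 130--170,
  bracketing the ~150 aa of globins), 5 families of 10, 10% divergence --
  model closely related, well-separated families.

What passing tests on these data show: the descriptor and pipeline are
implemented to specification, are deterministic, and recover a clean known
partition exactly. What they do not show: performance on real protein
families, which have indels, site-rate variation, compositional bias and
overlapping clades -- published accuracy figures on curated datasets
(obtained from sequence accessions and the curated 158-index AAindex
selection) cannot be checked without those inputs. `select_properties()`
exists precisely so a published index selection can be pinned from an ID
list and reproduced exactly.

## Numerical and design choices

* **Missing-value indices** are dropped before deduplication: an index
  with an `NA` cannot totally order the amino acids, so it cannot define a
  cone.
* **Duplicate** means bitwise-identical 20-value vectors, no tolerance --
  reproducible and faithful to "duplicate". A $10^{-9}$ perturbation is
  not a duplicate. The first of each duplicate group, in file order, is
  kept.
* **Eigenvalues**: dense symmetric solve; the suite cross-checks against
  power iteration at $10^{-10}$ relative tolerance.
* **Linkage ties**: `stats::hclust` resolves ties deterministically;
  random continuous distances are tie-free almost surely, and the
  brute-force reference in the tests compares merge heights, which are
  tie-invariant.
* **Sanitization**: FASTA input is uppercased; non-standard residues
  (B, J, O, U, X, Z, gaps, stops) are stripped with a warning by default,
  or rejected with the offending record and position under
  `policy = "reject"`.
* **Problem sizes**: the shipped tests and the acceptance script use 50
  sequences of 130--170 aa under the full 158-property configuration
  (about 30--60 s for extraction on one core) plus fast unit fixtures with
  the bundled 6-index set; brute-force oracles run at $N \le 10$.

## Known limitations

* Property magnitudes are used only through rank order; quantitative use
  is out of scope.
* Only the 20 standard amino acids are modelled; reduced alphabets and
  ambiguity codes are not.
* Trees are ultrametric single/complete-linkage dendrograms -- no
  neighbor-joining, likelihood methods, or bootstrap support.
* Peak memory is one $N \times N$ L/L matrix per sequence/property pair
  (matrices are built and discarded per property), so very long sequences
  (tens of thousands of residues) are compute- and memory-hungry.
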