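---
title: "Clustering crystallographic multi-data sets by correlated differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering crystallographic multi-data sets by correlated differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalclust)
```

## The problem

A fragment-screening campaign yields a *multi-data set*: `N` crystallographic
data sets, one crystal each, of the same protein soaked with different
compounds. Downstream per-voxel statistics (mean and standard deviation of
electron density across the collection, Z-maps of deviations) expose weak
ligand events — but only if the collection is homogeneous. Real collections
are not: unit cells drift, domains shift as rigid units, crystal morphology
changes over the campaign. Those variations widen the per-voxel
distributions and wash out ligand signal. Partitioning the collection into
internally homogeneous clusters first, and analysing each cluster as its own
run, restores that signal.

The discriminating quantity is deliberately *not* the correlation of
absolute amplitudes or coordinates between data sets — those are dominated
by the shared signal and leave subtle variation inside the noise. Instead,
every data set is compared to the collection average, and the *differences*
are correlated pairwise: two data sets that deviate from the average in the
same concerted way belong together, whatever the magnitude of that
deviation.

## The procedure

**Average sets.** With amplitudes `F(i,n)` and Cα positions `c(j,n)`, the
averages are `F̄(i) = Σ F(i,n) / Nₙ(i)` and `c̄(j) = Σ c(j,n) / Jₙ(j)`,
each sum running over the data sets actually recording that reflection or
modelling that residue. Missing observations therefore neither block the
average nor bias it toward zero. Where a residue has alternate
conformations, only the first Cα conformer encountered in file order enters
— a fixed, label-independent rule. A resolution cutoff (default 3.5 Å)
restricts the reflection analysis to low resolution, which is where
concerted structural differences live and keeps the comparison cheap; the
cutoff is a parameter (`d_min`) and d-spacings are computed from each data
set's own unit cell by the full metric tensor, so heterogeneous and even
triclinic cells are handled.

**Equal-volume shell scaling.** Each data set carries its own global
isotropic B factor, damping amplitudes by `exp(−B s² / 4)` with
`s = 1/d`. Left in place, this fabricates strong spurious correlations
between data sets of similar B (the test suite demonstrates a mean bounded
coefficient of ≈ 0.3 from B factors alone, removed to ≈ 0.02 by scaling).
Reciprocal space is divided into `n_bins = 20` concentric shells of equal
volume — boundaries follow the cube-root law
`r_b = r_max (b / n_bins)^{1/3}`, with `r_max` the largest recorded `|s|`
across the collection so that every reflection is binned (we read the
outermost boundary as a radius; a diameter reading would leave half the
data outside all shells). Per data set and shell, amplitudes are multiplied
by `k = Σ F̄(i) / Σ F(i,n)` over the commonly recorded reflections: the
linear least-squares-through-origin scale that makes each shell's sum match
the average, removing the B-factor envelope to within within-shell
curvature. Shells with no common reflections keep `k = 1` with a warning;
a shell whose amplitude sum is zero is an error, not a silent division.

Two refinements stabilise the reference. First, when
`scale_multidataset()` builds the average itself, each data set is
pre-normalised by its mean amplitude (the grand mean restores the overall
scale): otherwise one data set recorded on a very different overall scale
dominates the average *non-uniformly* (through its missingness pattern),
and the whole correlation matrix would depend on arbitrary per-set scale
factors. With the normalisation, the pipeline is invariant under per-set
positive rescaling to floating-point precision, which the suite asserts.
Second, after scaling, the average is recomputed once from the scaled sets
(`refresh_average = TRUE`), so first-order B-factor bias is also removed
from the reference itself.

**Bounded correlation.** For a pair `(m, n)`, the series compared span only
the observations present in both data sets (and the average): amplitude
deviations `F(i,·) − F̄(i)`, or Cα deviations with the x, y, z components
of each common atom contributed consecutively. The textbook Pearson
coefficient is clamped to `[0, 1]`: anti-correlated deviations carry no
evidence of shared behaviour and are treated like uncorrelated ones (the
clamp, not an affine `(r+1)/2` remap — uncorrelated pairs must sit at the
scale's zero). Pairs sharing fewer than `min_common = 10` observations, or
with a zero-variance difference series (a data set identical to the
average), fall back to 0 with a warning rather than an undefined value;
Pearson on tiny overlaps is noise.

**SVD and embedding.** The `N × N` matrix `M` of bounded coefficients (zero
diagonal, exactly symmetric by construction) is decomposed `M = U W Vᵀ`.
Groups of data sets deviating concertedly produce heavily weighted axes;
the weight *ratios*, not absolute values, say how many axes carry
structure. Each data set is embedded by its row of `U` restricted to three
chosen axes — raw `U` columns by default (the embedding is a submatrix of
`U`; a flag multiplies columns by their weights for readers who prefer
variance-true distances). Because singular vectors are sign-ambiguous,
each column's largest-magnitude entry is made positive, so repeated runs
are bitwise identical and plots reproducible.

**Assignment and subclustering.** The published workflow selects clusters
manually in a 3-D viewer. To keep the method scriptable and testable, the
package offers (a) seeded k-means on the embedding (`nstart = 25`), with
labels deterministically renumbered by descending cluster size then
lexicographically smallest member, and (b) an assignment-file path that
reproduces any manual selection from an exported embedding. The number of
clusters `k` is a user decision, as in the manual process. Subclustering
reruns matrix → SVD → embedding → assignment on one tree node, in either
comparison mode (reciprocal-space first, Cα differences below is the usual
pattern for conformational substructure), with averages either
*recalculated* over the subset — sharpening variation local to it — or
*inherited* from the parent. Nodes smaller than twice the minimum cluster
size are marked complete instead of split. Terminal nodes always partition
the data-set ids; the exported tree records mode, axes, average policy and
completeness per node.

**Outlier models.** Models deviating grossly from the average Cα positions
would bias it. Each model is scored by its mean Euclidean Cα deviation from
`c̄`; scores above `median + 5·MAD` are removed and the average recomputed.
The MAD is floored at 0.1 Å so that an essentially identical collection
(MAD ≈ 0) removes nothing. The threshold (in MADs) is a parameter; the
published procedure identified outliers visually and gives no number, so a
conventional robust 5-MAD fence is the default.

**Symmetry collapse.** Data sets of one collection may be modelled in
different symmetry-equivalent frames, making direct Cα comparison
meaningless. Candidate operators (xyz triplets, e.g. `"-x,-y,z"`, applied
in fractional coordinates) are tried per model and the one minimising the
mean deviation to `c̄` is kept, ties going to the earlier list entry; the
identity must be in the list, so a collapse never increases a model's
deviation. Against an average built from a *mixture* of frames the first
pass can sit near a tie, so one refresh pass recomputes the average from
the collapsed models and re-collapses; the reported operator is the net
transformation over both passes. A second collapse of collapsed models is a
no-op, which the suite asserts. Operator lists are supplied by the user
(generation from a space-group symbol would need symmetry tables this
package does not carry).

**Indexing-ambiguity resolution.** In lattices with an indexing ambiguity,
amplitude lists from different crystals may be indexed in geometrically
equivalent but incomparable ways. Each candidate remapping (integer
triplets, e.g. `"k,h,-l"`, |det| = 1) is applied per data set and the
*unclamped* Pearson correlation of its amplitudes against the reference is
evaluated over common indices — sign matters for an orientation choice.
The first pass uses a single data set (the most complete one) as the
reference: an average over a mixture of orientations supports every
orientation equally and cannot break the ambiguity. Subsequent passes
recompute the average from the adopted orientations and iterate to a fixed
point (cap 10; fixtures converge in 2). Remappings leaving a data set with
fewer than 3 common reflections are skipped with a warning.

## The synthetic generator

`generate_multidataset()` emulates the phenomena above so every stage is
testable without downloads: log-normal base amplitudes (positive,
right-skewed, like real structure-factor moduli); a cluster-specific random
perturbation direction applied multiplicatively; per-observation noise;
per-set isotropic B damping; per-set unit-cell jitter (tetragonal-like by
default, `a = b`, so the `k,h,-l` flip is geometrically valid); random
missingness; per-cluster rigid-body shifts and rotations of a common random
fold; per-atom noise and dropout; optional indexing flips. All randomness
derives from one seed, and regeneration is bitwise reproducible.

Defaults are the standard study conditions used throughout the suite: 3
clusters × 20 data sets, 500 reflections and 120 Cα atoms per complete
set, 10% concerted amplitude perturbation against 5% observation noise
(signal-to-noise 2), B factors over 0–30 Å² (0–60 Å² in the dedicated
scaling checks), 10% missingness, 0.6 Å / 1.5° rigid shifts. The 5%
observation noise is typical of merged amplitude precision; the rigid-body
magnitudes are of the order seen between real crystal morphologies.

What passing tests on these fixtures shows — and does not. The generator
plants *linear, concerted* amplitude perturbations and *rigid* coordinate
shifts with homoskedastic noise. Real heterogeneity also includes anchored
regions (crystal contacts that do not move when the rest does), resolution-
dependent noise, anisotropic B, partiality and radiation damage, none of
which are modelled. Recovery of planted clusters at signal-to-noise 2
therefore demonstrates the machinery end to end, not performance on any
particular real screen, where cluster boundaries can be genuinely diffuse
and the choice of `k` is the analyst's.

## Numerical choices and degenerate inputs

* Exact contracts: shell volumes equal to ~1e-14 relative; post-scaling
  shell sums match the reference exactly (float rounding only); the
  correlation matrix is exactly symmetric with an exactly zero diagonal;
  SVD reconstruction and orthonormality hold to 1e-10 on matrices up to
  N = 50.
* Ties: first operator in the list (symmetry collapse), first conformer in
  file order (PDB), `which.min`/`which.max` first-index semantics
  throughout; k-means ties are resolved by the seeded restarts plus
  deterministic relabelling.
* Degenerate inputs: identical data sets give zero-variance difference
  series → coefficients 0 with a warning (a zero matrix, whose *weighted*
  embedding collapses to the origin); empty shells keep k = 1; an
  all-identical collection removes no outliers (MAD floor); N < 2 is a
  configuration error everywhere.
* All file outputs (partition lists, assignment table, tree document,
  embedding, matrix, reports, provenance) are sorted deterministically and
  written locale-independently; identical configuration and seed reproduce
  every byte, which both the suite and the acceptance script verify.

## Problem sizes

The suite and `scripts/acceptance.R` run on N = 40–60 data sets with
200–500 reflections and 25–120 atoms per set — small enough to iterate
comfortably, large enough that every code path (missingness, shells,
subclustering, flips) is exercised; the planted-recovery check repeats the
full pipeline over 20 seeds. The implementation is vectorised (the pairwise
matrix is one `cor()` call on an observation-by-data-set difference matrix),
so collections of several hundred data sets with full reflection lists
remain interactive.

## Limitations

Amplitude comparison assumes a consistent space group per collection branch
and user-supplied operator lists; intensities are not converted to
amplitudes; anisotropic B is not modelled; the choice of `k` and of axes
beyond the default three is left to the analyst, mirroring the manual
character of the original workflow.
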