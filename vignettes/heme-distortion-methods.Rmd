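---
title: "Methods: quantifying heme porphyrin distortion with hemeNSD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying heme porphyrin distortion with hemeNSD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemeNSD)
```

## The model

Heme porphyrins in proteins are rarely planar. Their deviation from the
ideal planar, four-fold-symmetric (D4h) Fe-porphine geometry modulates
redox potential, ligand affinity and spectroscopy, and different protein
families imprint characteristic distortion patterns. Normal-coordinate
structural decomposition (NSD) turns a distorted 25-atom skeleton (Fe,
4 pyrrole N, 20 ring C) into a handful of interpretable numbers: the
displacement of the observed structure from the planar reference is
projected onto the low-frequency normal modes of the reference, so that
each heme is summarized by signed amplitudes for saddling, ruffling,
doming, waving(x/y), propellering (out-of-plane) and meso-stretching,
N-pyrrole stretching, translation(x/y), breathing, rotation (in-plane).

The decomposition has three ingredients, each built by this package:

1. **A reference structure.** `build_reference_porphine()` constructs an
   exactly planar, exactly D4h-symmetric Fe-porphine from five bond
   lengths (defaults: Fe-N 2.00, N-Ca 1.38, Ca-Cb 1.44, Cb-Cb 1.35,
   Ca-Cmeso 1.39 A) plus one closure angle. These are standard porphine
   values; every parameter is overridable, and the macrocycle closure is
   verified to 1e-9 A at construction.
2. **A mode basis.** A harmonic valence force field (stretches on the
   bonded-pair graph, bends on every bonded angle, out-of-plane bends
   per atom) is differentiated numerically (central differences, step
   1e-4 A) to a 75 x 75 Hessian; the mass-weighted secular equation
   `|M^(-1/2) (grad^2 E) M^(-1/2) - lambda I| = 0` is solved by exact
   diagonalization; eigenvectors are classified by D4h symmetry and the
   lowest internal mode per named slot forms the 12-mode basis.
3. **A projection.** Each heme's skeleton is rigidly superposed on the
   reference (unweighted Kabsch fit over all 25 atoms, proper rotations
   only) and the residual displacement `D` is projected by plain inner
   products `d_k = q_k . D` onto the unit mode vectors. No mass
   weighting and no pseudo-inverse enter the projection: the basis is
   used exactly as normalized, and it is "almost orthogonal" rather
   than orthogonalized (in this build the largest cross inner product
   is ~1e-12, because modes in different irreducible representations
   are exactly orthogonal).

## Why a model force field is sufficient

Only the mode *shapes* enter the projection; eigenvalues (frequencies)
are never used downstream. Shapes of symmetry-distinct low modes are
dictated largely by symmetry and connectivity, not by the precise force
constants: the tests verify that rescaling any force constant by 20%
changes every named mode direction by less than cos = 0.95. The
defaults (stretch 1.0, bend 0.3, out-of-plane 0.1 in internal units)
give the canonical ordering of out-of-plane modes (saddling < ruffling
< doming < waving < propellering). Users who possess a
quantum-chemistry-derived basis can load it with `load_mode_basis()`;
the file format is a 12-block xyz-style text and round-trips to 1e-9.

Two details of the force field matter and were genuinely open choices:

* **Out-of-plane terms must respect D4h exactly.** Each atom gets a
  harmonic restraint on its height above a plane of three reference
  atoms. The plane-atom rule must commute with the symmetry group or
  the Hessian's degenerate blocks mix across representations: iron
  averages over the four cyclic nitrogen triples, three-coordinate
  atoms use their neighbors, beta carbons use (adjacent alpha, adjacent
  beta, ring N) and meso carbons use (both alpha neighbors, Fe).
* **Mode classification is by symmetry expectation values,** not by
  visual templates: each internal eigenvector's expectations under C4,
  C2, sigma_v and sigma_h identify its irreducible representation
  (B2u = saddling, B1u = ruffling, A2u = doming, Eg pair = waving,
  A1u = propellering, A1g = breathing, A2g = rotation, Eu pair =
  translation). The two in-plane B1g/B2g slots are told apart by which
  candidate concentrates more displacement on the meso carbons.
  Degenerate pairs are gauge-fixed by diagonalizing sigma_v within the
  pair (the symmetric member is the x mode) and every mode's sign is
  anchored by making its first large component positive, so amplitudes
  are comparable across runs and machines.

## Superposition and the rigid-body subspace

Mass-weighted eigenvectors are orthogonal to rigid motions in the
mass-weighted metric, but not in the plain Cartesian metric (iron is
much heavier than C/N). A fitted displacement, however, always lies in
the Cartesian orthogonal complement of the rigid-body space. If the
stored doming/waving/translation/rotation vectors kept their Cartesian
rigid components, the superposition step would systematically shrink
exactly those amplitudes (by up to several percent for doming) even for
noiseless single-mode structures. The package therefore projects each
mode vector onto the rigid-complement subspace before normalizing.
This preserves all symmetry properties (the rigid space is
D4h-invariant) and makes every injected amplitude recoverable to
machine precision; it is the package's own convention and is applied
identically to computed and loaded bases.

## Structural descriptors

* **Out-of-plane iron displacement**: distance from FE to the
  least-squares plane of the four pyrrole nitrogens, computed from the
  eigenvectors of their 3 x 3 coordinate covariance; the normal's sign
  is arbitrary, so it is oriented toward the first axial ligand when
  one is known and flagged otherwise.
* **Axial ligands**: any residue or molecule with an atom within 3.1 A
  of FE; per candidate the distance is the minimum over its atoms; at
  most the two nearest are kept (coordination number 0-2). Waters
  count by default (they can coordinate); the heme's own atoms never
  do; an `exclude_comps` argument makes the inclusion rule explicit.
  Organism strings are truncated to their first two words and EC
  numbers to three class labels.
* **Propionate orientations**: signed torsions C1A-C2A-CAA-CBA
  (dihedral1) and C4D-C3D-CAD-CBD (dihedral2), IUPAC sign convention;
  negative is "up", positive "down". The measure-zero boundary value
  0 (and 180) is assigned "down" so the classification is total.
* **Coverage**: the buried fraction of the skeleton's
  solvent-accessible surface,
  `c = (sum S_heme - sum S_complex) / sum S_heme` over the 25 skeleton
  atoms, with SASA from an in-package Shrake-Rupley implementation
  (probe 1.4 A, 960 deterministic golden-spiral points per atom,
  Bondi-type radii with Fe = 2.00 A, H excluded, and only C/N/O/S/Fe
  atoms participating). `S_heme` is computed on the isolated heme,
  `S_complex` with all complex atoms as occluders but summed over the
  same 25 atoms. Binding-pocket volume is intentionally out of scope;
  external pocket-volume results can be joined onto the entry table by
  identity columns.

## Extraction rules for mmCIF input

One entry is created per heme residue (compound IDs HEM, HEA, HEB,
HEC, HEO) with intact iron + porphyrin ring coordinates; hemes missing
any of the 25 atoms are skipped with a logged reason. For duplicated
atom records, only PDB model 1 is used, and among alternate locations
'.' wins over 'A'; atoms present only under other altloc codes count
as missing. Entry identity is (PDB id, asym id, chain, residue index).
Resolution is read from `_refine.ls_d_res_high`, falling back to
`_reflns.d_resolution_high` — the field preference is a documented
package choice, since several resolution items can coexist. Keyword to
function-label mapping is a shipped, user-editable TSV
(`extdata/function_keywords.tsv`); unmapped keywords stay NA rather
than being guessed.

## Feature analysis

* **Histograms** of each mode amplitude per group, with a resolution
  filter restricted to the supported 1.4-8.2 A window; counts are
  conserved across any grouping.
* **PCA on fitted coordinates**: structures are iteratively fitted to
  their mean (initialize from the first structure, fit all, recompute
  the mean, repeat until the mean moves < 1e-6 A RMSD, at most 50
  iterations), then the coordinate covariance is eigendecomposed.
  Contribution ratios, per-heme scores, and inner products of leading
  eigenvectors with the saddling/ruffling/doming modes are reported;
  eigenvectors and the mean export as xyz.
* **LDA on the 12 amplitudes**: the two-class pooled-covariance
  discriminant `w = S_pooled^-1 (mu2 - mu1)`, normalized, and also
  expressed as a 75-component displacement through the mode basis.
  When the pooled covariance is rank-deficient (12 features can be
  collinear on small synthetic sets) a ridge of 1e-6 x trace/12 is
  added and flagged in the result.
* **Clustering (CAN)** with K-means, spectral, agglomerative (Ward)
  and Gaussian-mixture methods; k always equals the number of target
  groups, hyperparameters are pinned (`nstart = 10`, Ward.D2 linkage,
  default mclust model set, kernlab defaults) under a fixed local seed
  so runs are reproducible.

## What the synthetic generator does and does not emulate

`make_distorted_heme()` produces skeletons with exactly known mode
content (amplitudes up to ~0.5 A, the physiological range), isotropic
Gaussian coordinate noise (sigma = 0.02 A in the standard recovery
conditions, comparable to coordinate uncertainty in good crystal
structures), and arbitrary rigid placement. `make_complex_fixture()`
adds single-atom axial-ligand candidates on the porphyrin normal,
propionate stubs at exact torsions, and concentric dummy-carbon shells
for coverage tests; `write_fixture_mmcif()` emits minimal
standards-conformant files exercising the altloc/model rules.

Synthetic data deliberately omits: correlated (anisotropic) coordinate
error, crystallographic disorder beyond simple altloc duplication,
real protein environments (ligand candidates are bare atoms, occluders
are geometric shells), and covalent heme c linkages. Passing tests
therefore demonstrate the correctness of the decomposition machinery
and rules, not parsing robustness against the full variety of
historical PDB files.

## Numerical choices

* Finite-difference step 1e-4 A (validated range 1e-5..1e-2); the
  energy-based central-difference Hessian is symmetric by construction
  and its rigid-body null space is verified to be exactly
  six-dimensional.
* Rigid modes are identified as the six smallest-magnitude eigenvalues;
  internal modes must have symmetry expectations within 0.1 of +/-1 to
  be classified.
* Superposition rejects reflections (determinant +1 enforced), errors
  on degenerate (rank < 2) coordinates.
* Problem sizes in tests and the acceptance script (30-100 structures
  per analysis, 200 noise replicates, 480-960 SASA points) were chosen
  as the smallest sizes at which the statistical assertions have
  comfortable margins.

## Known limitations

* The built-in basis approximates shapes a quantum-chemical Hessian
  would give; numeric parity with any specific published basis is not
  claimed (load one for exact parity).
* Shrake-Rupley "accessibility" is local sphere overlap: a fully
  enclosed cavity interior still counts as accessible unless occluders
  are within probe reach; coverage fixtures use close shells for this
  reason.
* Coordination is a pure distance rule; no bond-valence or geometric
  chemistry checks are applied.
* HEB entries are stored verbatim (the compound ID conflates heme b
  and c deposits); no reinterpretation is attempted.
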