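---
title: "Point-group detection, character tables and SALCs with molsym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-group detection, character tables and SALCs with molsym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molsym)
```

molsym detects the point group of a molecule from cartesian coordinates,
auto-generates real character tables, constructs symmetry-adapted linear
combinations (SALCs) of real spherical harmonic basis functions, and
projects near-symmetric geometries and molecular-orbital coefficient sets
back onto exact symmetry.  This vignette explains the models and procedures
behind each stage, the tunable parameters, and what the package's synthetic
test data does and does not demonstrate about real inputs.

## Detection: equivalence sets from symmetry-invariant properties

Any symmetry operation of a molecule fixes its centre of mass, permutes
atoms of equal element and mass, and preserves distances.  Detection
therefore starts by centring the coordinates and partitioning the atoms
into *equivalence sets* — candidate orbits of the (yet unknown) group.
Rather than searching over operations, the partition is obtained by
clustering four per-atom scalars that any admissible isometry must leave
unchanged:

* the mean and the euclidean norm of the atom's row of the reduced-mass
  weighted distance matrix \(D_{ij} = \mu_{ij}\,\lvert a_i - a_j\rvert\),
  with \(\mu_{ij} = m_i m_j/(m_i+m_j)\);
* the norm of the reduced-mass weighted sum of unit vectors towards all
  other atoms (a "projection onto a unit sphere");
* the norm of the reduced-mass weighted sum of the components of all other
  atoms perpendicular to the atom's own position vector (a projection onto
  a plane; for an atom at the origin this projection is undefined and the
  term is dropped and flagged).

Atoms are first grouped exactly by (element, mass); only atoms with all
four invariants in agreement can be symmetry-equivalent.  Clustering is
single linkage within a tolerance, and the partition is refined by
recomputing the invariants inside each subset (treated as its own molecule
about the same centre) until a fixed point is reached.  Refinement can only
split, never merge.

**The clustering tolerance** (`rel_tol`, default 0.1) is relative to the
overall magnitude of the invariants, not to each component's own spread.
The reason is a property of highly symmetric orbits: their sphere and
plane projections cancel almost exactly, so the surviving values are
dominated by coordinate noise, and a per-component relative tolerance
shatters orbits at noise levels the geometric tolerance happily accepts.
The global scaling makes the two tolerances consistent: coordinate noise
of order \(\sigma\) perturbs the invariants by a few tens of
\(\sigma/r\) relative, so `rel_tol = 0.1` tolerates the noise the default
`tol_geom = 0.05` Å admits.  A generous tolerance is safe because
over-merging is benign: a union of two orbits of the same group is still
group-invariant, and every candidate element is validated against each set
before it is accepted.  Under-merging, by contrast, destroys the ring
structure the element search relies on.

## Detection: symmetry elements from set geometry

Each equivalence set is analysed through its own inertial tensor
\(\mathbf I = \sum_i m_i\left((a_i\!\cdot\!a_i)E - a_i\otimes a_i\right)\),
diagonalised with a cyclic Jacobi algorithm for 3×3 matrices.  The moment
pattern steers the search:

* a single atom at the origin constrains nothing;
* a collinear-through-origin set carries an infinite-order axis (plus
  \(\sigma_h\) and the inversion when it is centrosymmetric);
* an axial set gets ring analysis: members are grouped into rings by
  height and radius about each candidate axis, the principal order is the
  largest divisor of the gcd of ring sizes whose rotation validates, and
  perpendicular \(C_2\) axes and vertical mirrors are sought at the
  pairwise azimuth midpoints of a reference ring together with its
  height-mirrored partner (a perpendicular \(C_2\) maps a point at
  \((\varphi, h)\) to one at \((2\alpha-\varphi, -h)\), so its azimuth
  bisects such pairs);
* a spherical-top set goes through the polyhedral search: mirror and
  low-order rotation candidates between equidistant point pairs (axes from
  pair sums, normals from pair differences, plus triple sums for small
  sets), with the implied higher-order elements generated by closing the
  validated operations under multiplication.

Validation is mandatory, not optional: an element is only reported if its
matrix maps every member of the set onto a member within `tol_geom`
(default 0.05 Å).  Each accepted operation is immediately refitted to the
permutation it induces by an orthogonal Procrustes solve, which snaps its
axis to the least-squares optimum and keeps errors from accumulating when
operations are multiplied.  Because the principal order is inferred from
ring sizes and validated directly, there is no ceiling on the detectable
axis order: a 47-fold antiprism goes through exactly the same code path as
a 6-fold one.

The per-set element lists are then intersected: a candidate survives only
if it permutes *every* equivalence set.  This realises the reduction rule
for infinite axes automatically — any finite rotation about a collinear
set's axis permutes it, so the intersection of a \(C_\infty\) axis with a
ring's \(C_5\) is the finite \(C_5\).  The surviving elements are
classified by the standard decision tree (linear → polyhedral → principal
axis with perpendicular \(C_2\)s, horizontal/vertical mirrors,
\(S_{2n}\), with \(C_1\) as fallback), relaxed so that a single vertical
mirror or perpendicular \(C_2\) suffices: the remaining ones are implied
and generated.

Finally the element geometry is *symmetrised*: the exact ideal element
arrangement of the assigned group is built in a canonical frame and
aligned to the detected elements (principal-axis pairing plus an
orthogonal Procrustes polish over matched axes, both axis signs tried).
All inter-element angles are exact afterwards; the detected orientation is
retained through the alignment transform.  A mean angular residual above
0.1 rad raises an inconsistency error rather than silently producing a
broken group.

## Groups, classes and permutations

`point_group_from_label()` emits all \(\lvert G\rvert\) operations of any
cyclic/dihedral-family group of any order, and of the polyhedral groups
(by closure from exact generators), as exact orthogonal matrices.  The
canonical ordering is: identity; proper rotations by descending order
(principal axis first, then axis azimuth, then ascending power); improper
rotations; mirrors (horizontal first, then by plane azimuth); inversion.
Conjugacy classes are computed from the multiplication table, and classes
of mutually inverse rotations are merged, because in a real basis the
conjugate pair of complex one-dimensional representations acts as one real
two-dimensional representation — the convention used throughout.

Subgroups are enumerated exhaustively: cyclic subgroups from the powers of
each operation (the permutation cycles of the multiplication table),
closed under pairwise joins until a fixed point.  Every subgroup is then
reachable by induction on generator count.  All distinct subgroups are
kept, without conjugacy deduplication, because partner-function
determination needs concrete oriented subgroups.  For families with
closed-form counts the enumeration is cross-checked (cyclic groups have
d(n) subgroups, dihedral-type groups d(n) + σ(n); the polyhedral counts
are fixed constants).

## Character tables

Cyclic and dihedral families of arbitrary order are generated from the
structure of the group: each is a cyclic or dihedral core over a proper or
improper principal generator, optionally times a \(\sigma_h\) or inversion
factor.  One-dimensional characters are ±1 with signs determined by the
irrep's parities combined with each operation's core power, vertical index
and product-factor exponent; two-dimensional characters follow
\(\chi^{E_j}(C_n^k) = 2\cos(jk\,2\pi/n)\) with an incremental index j;
improper operations additionally carry the irrep's behaviour under
\(\sigma_h\).  Mulliken names are assigned by explicit rules (A/B from the
principal-rotation sign, subscripts from the reference vertical element,
primes from \(\sigma_h\), g/u from the inversion when it is present; at
the even-n boundary j = n/2 the rows are B-type).  Polyhedral tables are
static verified data over the merged classes.

Merged complex pairs are flagged and carry an endomorphism factor s = 2;
the structural theorems then read
\(\sum_\Gamma \dim(\Gamma)^2/s_\Gamma = \lvert G\rvert\) and
\(\sum_c \lvert c\rvert\,\chi^\Gamma(c)\chi^{\Gamma'}(c)
 = s_\Gamma \lvert G\rvert \delta_{\Gamma\Gamma'}\),
which reduce to the familiar forms when every row is of real type.  The
same factor makes the reduction formula count a merged pair once and puts
\(\dim/s\) (not \(\dim\)) in front of its trace projector, since the
merged row is the sum of two one-dimensional projectors.  These corrected
forms are validated for every generated table.

**Linear groups.**  \(C_{\infty v}\) and \(D_{\infty h}\) have infinitely
many operations, so a finite surrogate is used: \(C_{2\ell v}\) or
\(D_{2\ell h}\) with \(\ell = \max(\ell_{max}, 1)\), where
\(\ell_{max}\) is the highest angular momentum the basis carries.  The
vertical and dihedral \(C_2\) and mirror operations are assigned to shared
conjugacy classes, which merges the boundary \(B_1/B_2\) pairs into
two-dimensional rows; every function with \(\lvert m\rvert \le \ell_{max}\)
then splits exactly as under the true linear group, and the irreps carry
linear-style names (Σ±, Π, Δ, ... with g/u parity).

## Real spherical harmonics

Shells are real solid harmonics with the fixed phase in which the
\(\ell = 1\) shell is (y, z, x).  Rotation matrices are built by the
iterative recursion from the \(\ell-1\) matrix and the \(\ell = 1\) seed
(the U, V, W recurrence, with the corrected sign convention in the V
term); the implementation is verified against an independent direct
evaluator of the solid harmonics on random point sets, so the convention
is pinned by numerics, not by trusting any one printed source.  Improper
operations factor through the inversion, which acts as \((-1)^\ell\) on a
shell.  Closed-form characters
(\(\sin(\theta\lvert Y\rvert/2)/\sin(\theta/2)\) for proper rotations,
\(\cos(\theta\lvert Y\rvert/2)/\cos(\theta/2)\) for improper ones, with
the \(\theta\to 0\) and \(\theta\to\pi\) limits handled analytically, and
\(\chi(\sigma) = 1\) always) let shell decompositions be computed without
building any matrices — and double as an internal cross-check, since every
character must equal the trace of the corresponding operation matrix.

## SALCs: projection, subduction, partner functions

For each (equivalence set, shell) block the representation is the outer
product \(D^{SY}(R) = D^S(R)\otimes D^Y(R)\) of the permutation action on
the set and the shell rotation matrices.  The trace projector
\(P^\Gamma = (\dim\Gamma/\lvert G\rvert)\sum_R \chi^\Gamma(R) D^{SY}(R)\)
needs only the character table; its image is extracted by pivoted Cholesky
factorisation (largest diagonal first, ties by index) followed by a
Gram–Schmidt polish with a canonical sign rule, so the basis choice —
which is mathematically free — is deterministic and reproducible.

The trace projector cannot separate the partner components of a degenerate
irrep.  Subduction to a splitting subgroup does: the smallest subgroup H
whose character table has only real rows and in which Γ restricts
multiplicity-free to at least two distinct constituents is selected
(subgroups with complex characters are avoided, since their merged pairs
cannot split a real basis); still-degenerate constituents are split
recursively inside H.  For the five-dimensional icosahedral irreps this
recursion lands, without special-casing, on the two-step chain through
\(D_5\) and then \(C_2\).  Each chain leaf defines a product of stage
projectors; applied within \(V^\Gamma\) it isolates one component
subspace.  Component 1 is extracted directly; every other component k is
generated as \(P^{\gamma^k}\hat R\,\Theta_{m,1}\) for a fixed group
operation R outside H, normalised by the common row norm.  Because that
scale is a group-level quantity, the resulting generator action on
component indices is identical in every block — partner orientation is
consistent across equivalence sets and shells, which is what makes the
stacked SALC matrix block-diagonalise every operation with one common
block structure.

Merged complex-pair irreps need a different split, since no real
one-dimensional projectors exist.  Two cases arise.  The surrogate linear
tables remember their constituent rows, so the merged \(B_1/B_2\) pairs
split by the original projectors (this is exactly separation by angular
momentum projection).  Genuine complex pairs (cyclic families, T, Th) are
split by the first group operation that acts as a non-trivial rotation
inside the pair plane: picking a pivot vector u per multiplicity copy and
setting \(w = (\hat R u - \cos\alpha\, u)/\sin\alpha\) yields components
on which that operation acts as the same 2×2 rotation in every block.

Basis ordering is global and fixed: atoms in molecule order, declared
shells per atom, m from −ℓ to ℓ.  Overlap between basis functions is
assumed zero; overlap-aware orthonormalisation is intentionally out of
scope (it can be applied after this construction).  The full transfer
operator \(P^\Gamma_{kl}\) is intentionally not implemented: it would
require explicit irrep matrices, which the generated tables do not carry,
and the trace-projector-plus-subduction route reproduces everything it
would provide.

## Symmetrisation

**Geometries** are projected onto the totally symmetric subspace of the
(atom ⊗ cartesian) displacement space, using the permutation action times
the 3×3 operation matrices.  The discarded component's norm in the
mass-weighted metric (positions scaled by \(\sqrt m\), as for vibrational
modes) is reported as the error indicator, together with the unweighted
per-atom RMS, since the natural normalisation is a matter of taste.  The
projected geometry is exactly invariant under every group operation, the
projection is idempotent, and a result that collapses two atoms within
\(10^{-3}\) Å signals an inconsistent group assignment.

**Orbital coefficient sets** are analysed against the SALC basis: each
orbital's squared norm decomposes exactly over the irreps, the dominant
irrep is assigned, and the orbital is projected onto that irrep's span and
re-normalised.  Orbitals of degenerate irreps are grouped into partner
sets by comparing their multiplicity-space component vectors, an average
component is computed per set (sign-aligned, then Löwdin-orthonormalised
across sets to avoid order dependence), and the output orbitals are rebuilt
from the averaged component on each partner stack — so partner sets
transform exactly into one another under the group.  An orbital whose
largest irrep fraction does not exceed `min_component` (default 0.5, a
strict majority) is rejected as too symmetry-broken: below that point the
assignment itself is ambiguous and no projection is meaningful.

## Synthetic data: what it emulates, what it does not

The generator builds ideal molecules as group orbits of seed atoms,
optionally with seeded isotropic Gaussian coordinate noise; nanotube-like
fixtures as stacks of antiprismatic rings with exact \(D_{nd}\) symmetry
by construction; and synthetic orbital sets as SALC rows mixed with a
declared fraction of cross-irrep contamination.  Default seeds are drawn
from a fixed sequence with azimuths 1.85°·i, chosen once so that every
seed azimuth and every pairwise azimuth difference stays at least ~1.85°
away from the k·90°/n special-position grids for n ≤ 12 — orbits remain in
general position and no accidental cross-orbit coincidences arise at the
default geometric tolerance.

These fixtures probe the machinery, not chemistry: they have no realistic
bond lengths, no correlated (vibrational-mode-like) distortions, and the
orbital sets have no radial structure or basis-set overlap.  Passing tests
therefore demonstrate correctness of the group theory and of the
detection logic under isotropic noise; they do not show that the default
tolerances are optimal for any particular level of electronic-structure
theory.  For real data the two knobs that matter are `tol_geom` (how far
an atom may sit from its ideal position, in Å) and `rel_tol` (how
aggressively invariant clustering merges), and both are exposed
everywhere.

## Numerical choices and problem sizes

* Degeneracy classification of inertial moments uses a tolerance derived
  from `tol_geom` (about \(4\,\mathrm{tol}/r_{rms}\) relative, floored at
  \(10^{-4}\)): atoms may legitimately sit `tol_geom` away from ideal, and
  a fixed tight tolerance would misroute noisy spherical tops away from
  the polyhedral search.  When a near-degenerate set yields fewer than two
  high-order axes, the axial search runs as well, seeded with whatever
  axes were found.
* Operation identification classifies the identity and the inversion by
  matrix distance before any angle is computed, because arccos near ±1
  amplifies rounding to \(\sqrt\varepsilon\).
* Alignment residuals use \(2\arcsin(\lVert a-b\rVert/2)\), accurate for
  small angles.
* All randomness (noise, contamination partners) is seeded explicitly and
  restores the caller's RNG state.
* Test and regression problem sizes were chosen to exercise every code
  path at moderate cost: the detection regression runs all seven axial
  families at n = 2..12 plus all polyhedral groups plus 13- and 47-fold
  nanotubes (~90 molecules); the prism order-inference sweep samples
  n ∈ {3, 5, 8, 13, 21, 34, 47, 50}; block-diagonalisation fixtures carry
  shells up to ℓ = 3 and groups up to order 48 (benzene) and 20
  (ferrocene); shell characters are cross-checked for ℓ ≤ 6.

## Known limitations

* Single atoms report spherical symmetry and refuse SALC construction;
  the full rotation group is outside the finite-group machinery.
* Colour/magnetic symmetry, double groups and space groups are out of
  scope.
* The error indicator and the orbital fractions assume an orthonormal
  basis; with overlapping atomic orbitals the fractions are qualitative
  until an overlap correction is applied downstream.
* Subgroup enumeration is exhaustive and kept for groups up to order 240;
  icosahedral enumeration (164 subgroups of the full group) takes a few
  seconds.

## A worked example

```{r example}
mol <- generate_symmetric_molecule("D5d")   # two-orbit ideal fixture
g <- detect_point_group(mol)
g
s <- build_salcs(mol, list(C = c(0, 1), N = 0L), g)
table(attr(salc_matrix(s), "irrep"))
```
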