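# molsym

Molecular point-group detection, auto-generated character tables,
symmetry-adapted linear combinations (SALCs) of real spherical harmonics,
and symmetrisation of geometries and wavefunction coefficient sets — in R.

The package is for computational and quantum chemists (and for teaching
group theory) who need to answer, from nothing but an XYZ geometry:

* *What is the point group of this molecule*, including high-order axial
  groups (a D₄₇d nanotube goes through the same code path as D₆d) and the
  polyhedral and linear groups?
* *What are its irreducible representations*, for any axis order, without
  a lookup table?
* *How do my atomic-orbital basis functions combine into symmetry species*
  — the SALCs that block-diagonalise every symmetry operation and the
  Hamiltonian?
* *How symmetry-broken are this geometry and this wavefunction, and what
  is the closest symmetric version of each?*

## What it computes

**Detection.** Atoms are partitioned into equivalence sets (orbits) by
clustering symmetry-invariant per-atom properties: the mean and norm of
each row of the reduced-mass weighted distance matrix
D_ij = μ_ij·|a_i − a_j| (μ_ij = m_i·m_j/(m_i+m_j)), and the norms of the
reduced-mass weighted projections onto a unit sphere and onto the plane
perpendicular to the atom's position. Candidate symmetry elements (Ĉₙ, Ŝₙ,
σ̂, ı̂) are deduced from each set's geometry — ring azimuths about the
inertial axes for axial sets, an equidistant-pair search with
multiplicative closure for spherical-top sets — validated against every
set, intersected, classified into a Schoenflies label, and replaced by the
exact ideal element geometry aligned to the molecule (orthogonal
Procrustes). Every operation of the group is then generated as an exact
matrix with multiplication table, conjugacy classes and subgroups.

**Character tables.** χ^Γ(R) for cyclic and dihedral families of *any*
order are generated from the group structure (1-dimensional characters ±1
by parity rules; E-type characters 2cos(jk·2π/n)); polyhedral tables are
static verified data; linear groups use finite surrogate groups
(C₍₂ℓ₎ᵥ / D₍₂ℓ₎ₕ with merged vertical classes) that split every basis
function up to ℓ_max exactly like C∞ᵥ / D∞ₕ. Complex-conjugate pairs are
merged into real 2-dimensional rows, the convention appropriate for real
spherical harmonic bases.

**SALCs.** For each (equivalence set, shell) block the direct-product
representation D^SY(R) = D^S(R) ⊗ D^Y(R) is assembled from the permutation
action and real-spherical-harmonic rotation matrices (built by the
ℓ-from-(ℓ−1) recursion and verified against a direct evaluator). The trace
projector P^Γ = (dim Γ/|G|) Σ_R χ^Γ(R) D^SY(R) extracts each irrep's
subspace; subduction to a deterministically chosen splitting subgroup
(avoiding complex characters; the 5-dimensional icosahedral irreps chain
through D₅ and C₂) separates partner components so that every copy
transforms identically across sets and shells.

**Symmetrisation.** Geometries are projected onto the totally symmetric
subspace of the atom ⊗ cartesian space (the discarded mass-weighted norm is
the error indicator); orbitals are assigned to their dominant irrep,
projected onto its SALC span, and partner-averaged so degenerate sets
transform exactly into each other.

## A worked example

```r
library(molsym)
mol <- read_xyz("4
ammonia
N  0.0000  0.0000  0.3800
H  0.9377  0.0000  0.0000
H -0.4689  0.8121  0.0000
H -0.4689 -0.8121  0.0000")

g <- detect_point_group(mol)
summary(g)
#> point group C3v, order 6
#>   class 1: 1 x E
#>   class 2: 2 x C3
#>   class 3: 3 x sigma_v

generate_character_table(g)
#> character table C3v  (|G| = 6)
#>    E 2C3 3sigma_v
#> A1 1   1        1
#> A2 1   1       -1
#> E  2  -1        0

build_salcs(mol, list(N = c(0, 1), H = 0L), g)
#> SALCs for C3v: 7 basis functions, 7 spaces
#>   set 1  l=0  A1     comp 1/1  (1 function)
#>   set 1  l=1  A1     comp 1/1  (1 function)
#>   set 1  l=1  E      comp 1/2  (1 function)
#>   set 1  l=1  E      comp 2/2  (1 function)
#>   set 2  l=0  A1     comp 1/1  (1 function)
#>   set 2  l=0  E      comp 1/2  (1 function)
#>   set 2  l=0  E      comp 2/2  (1 function)
```

The nitrogen s and p_z functions are totally symmetric (A1), its (p_x,
p_y) pair spans E, and the three hydrogen s functions combine into one A1
SALC and one E partner pair — the textbook result. Perturbing the
geometry by 1 mÅ Gaussian noise and projecting it back:

```r
set.seed(1)
noisy <- mol
noisy$xyz <- noisy$xyz + matrix(rnorm(12, sd = 1e-3), 4, 3)
symmetrize_molecule(noisy, detect_point_group(noisy))
#> error indicator: 0.002771 sqrt(amu)*Angstrom, rms 0.001336 Angstrom
```

The restored geometry is exactly invariant under all six operations, and
the error indicator reports the size of the symmetry-breaking component
that was removed.

A thin command-line front end ships in `inst/scripts/molsym`
(`detect`, `chartab`, `salc`, `symmetrize` subcommands).

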