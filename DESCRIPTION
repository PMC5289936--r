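Package: molsym
Title: Molecular Point-Group Detection, Character Tables and Symmetry-Adapted
    Linear Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects the point group of a molecule from cartesian coordinates
    by clustering symmetry-invariant per-atom properties into equivalence sets
    and deducing symmetry elements from their geometry.  Generates character
    tables for cyclic and dihedral families of arbitrary order (with static
    tables for the polyhedral groups and surrogate tables for linear groups),
    builds symmetry-adapted linear combinations (SALCs) of real spherical
    harmonic basis functions via trace projection operators and subduction to
    splitting subgroups, and symmetrises near-symmetric geometries and
    molecular-orbital coefficient sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
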