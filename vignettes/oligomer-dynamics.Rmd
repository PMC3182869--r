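---
title: "Oligomer dynamics: elastic network modes, embedded subsystems and communication pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oligomer dynamics: elastic network modes, embedded subsystems and communication pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligodyn)
```

## The question the package addresses

Many enzymes work as oligomers — dimers, hexamers, rings of dimers — and
their functional motions (domain closure over an active site, allosteric
T/R transitions, ring breathing) are collective: they involve the whole
assembly moving along a handful of low-frequency directions. Two questions
follow naturally. First, how much of a subunit's intrinsic flexibility
survives oligomerization, and what new motions does the assembly create?
Second, through which residues do the subunits talk to each other, so that
an effector bound at one interface is felt across the ring?

`oligodyn` answers both with coarse-grained models that need nothing more
than C-alpha coordinates plus heavy-atom positions: an anisotropic elastic
network for the mechanics, and a contact-based Markov chain for the
communication.

## The elastic network model

Each residue is a node at its C-alpha position; every pair of nodes closer
than a cutoff `r_c` (default 15 Å, bonded and non-bonded pairs alike) is
joined by a Hookean spring with a single uniform force constant `gamma`.
The potential is

    V = (gamma / 2) * sum over springs (|R_ij| - |R_ij^0|)^2

with `R_ij^0` the crystal-structure separation. Second derivatives at the
minimum give the 3N x 3N Hessian **H**, built from 3 x 3 superelements
`-(gamma/|R_ij^0|^2) R_ij^0 (R_ij^0)^T` off the diagonal, with diagonal
blocks closing each row sum to zero. That closure makes uniform
translations and infinitesimal rotations exact null directions, so a
connected network has exactly six zero eigenvalues; `compute_modes()`
verifies this count and treats its failure as the signature of a
disconnected (or mechanism-containing) network. Mode numbering starts at
the first nonzero eigenvalue; eigenvalues are squared frequencies, so the
lowest modes are the large-amplitude "global" motions. Per-mode
quantities follow directly: mean-square fluctuation profiles
(`ms_fluctuations()`, entries `|u_k,i|^2 / lambda_k` summed over a mode
subset), cross-correlations (`cross_correlation()`), deformed conformers
`R^0 + s u_k` (`make_conformer()`; the raw unit eigenvector is used, so
`s` is in Å per unit component — visualisation-scale deformations use
`s = ±20`), and hinge sites as strict local minima of the mobility
profile (`find_hinges()`).

The eigendecomposition is a dense symmetric solve. The assemblies this
package targets (a few hundred to a couple of thousand residues) stay
comfortably within a dense solver's reach, and a full spectrum is needed
anyway for completeness checks, so no iterative/sparse path is offered.

### Numerical conventions

* Zero-mode threshold: `lambda <= 1e-8 * lambda_max` — scale-free, so the
  same rule works for monomers and hexamers regardless of `gamma`.
* Eigenvector signs are arbitrary; they are fixed by making the
  largest-magnitude component positive, and every comparison statistic
  uses absolute values anyway.
* Near-degenerate eigenvalue pairs (relative gap below 1e-6) are
  reported via a message. Ring-symmetric oligomers produce them by
  construction (the E representations of C_n), and individual mode
  indices inside a degenerate pair are not stable; subspace overlap is
  the robust statistic there.

## Subsystem in a dynamic environment

To ask what a monomer's dynamics look like *inside* an assembly, the full
Hessian is partitioned into subsystem (S) and environment (E) blocks and
the environment is allowed to relax to the energy minimum for every
subsystem displacement. The resulting effective Hessian is the Schur
complement

    H_eff = H_SS - H_SE H_EE^-1 H_ES

computed with an eigendecomposition pseudo-inverse of `H_EE` (relative
cutoff 1e-10), which handles environments with internal near-rigid
freedoms exactly; the number of dropped null directions is logged. Two
limits anchor the behaviour and are asserted in the tests: with no S-E
springs, `H_eff = H_SS` exactly; and for a free-standing assembly the six
global rigid motions survive relaxation, so `H_eff` keeps six zero modes
(a tethered environment, by contrast, pins them all). Relaxation can only
soften the subsystem — `H_eff` precedes `H_SS` in the Loewner order — and
the subsystem's mode numbering restarts at 1.

## Comparing mode sets and experimental deformations

All comparison statistics reduce to absolute correlation cosines of
3N-dimensional vectors:

* `overlap(u, v)` — `|u.v|/(|u||v|)`, the conservation of one mode in
  another system, or the fraction of an experimental deformation along
  one mode.
* `deformation_vector(a, b, map)` — the displacement between two
  conformational states over a residue-correspondence map, always after
  least-squares superposition (Kabsch, with an explicit collinearity
  guard); raw coordinate differences are never compared.
* `cumulative_overlap(modes, d, m)` — root-sum-square of the first `m`
  overlaps; equals 1 at `m = 3N-6` once the deformation's rigid-body
  content is projected out, because the nonzero modes span the internal
  deformation space completely.
* `overlap_matrix(A, B)` — all pairwise overlaps, with superset modes
  restricted to the component's residues and renormalised first (a
  restricted mode with no amplitude on those residues reports 0).
* `subspace_overlap(A, B, m, n)` — aggregate similarity
  `sqrt(sum of squared overlaps / r)` with `r` the reference-set size;
  the reference defaults to the first argument and is a caller choice
  because either normalisation is meaningful depending on which spectrum
  is being asked about.
* `correspondence_slope(M)` — weighted least squares of assembly-mode
  index on component-mode index over entries at or above 0.5, weighted
  by squared overlap to emphasise confident correspondences. Slope
  magnitude 1 means the component spectrum is conserved in order;
  magnitude 2 means each component mode reappears two modes deeper, i.e.
  half the component modes are missing from the assembly's
  low-frequency window. The intercept is fitted by default (a
  zero-intercept variant is exposed) since a uniform shift of the
  spectrum is a distinct, weaker statement than dilution.
* `distance_variation(net, modes, k)` — the signed rate of change of
  every inter-residue distance along mode k, scaled by the inverse
  frequency `lambda_k^-1/2` (the eigenvalue being the squared
  frequency; an exponent knob allows `1/lambda` scaling instead). Zero
  blocks over a subunit diagnose rigid-body motion of that subunit.

## Communication pathways

The communication model is built from heavy-atom contacts, not from the
spring network: `N_ij` counts atom pairs across residues i and j within
4 Å, `N_i` is residue i's heavy-atom count, and the affinity is
`a_ij = N_ij / sqrt(N_i N_j)`. Hydrogens never enter (coarse structures
drop them on reading) and neither do HETATM records, so bound ligands do
not contribute contacts; analyses that need a ligand's atoms must supply
them as ATOM records. Column-normalising by the contact density
`d_j = sum_i a_ij` gives the transition matrix `m_ij = a_ij / d_j` — the
probability that residue j hands a signal to residue i in one step — and
`-log(m_ij)` turns likelihood products into additive path lengths, so
Dijkstra's algorithm on the directed graph finds maximum-likelihood paths
(MLPs). Ties between equal-length paths are broken toward the
lexicographically smallest node sequence, making outputs deterministic.
For two subunits, `occurrence_profile()` computes the MLP for every
ordered residue pair (source in A, target in B) and reports, per residue,
the percentage of those paths that pass through it; endpoints count as
on-pathway by default (a flag restricts to intermediates). A residue
whose removal disconnects the subunits necessarily scores 100%.

## The synthetic generator

Real oligomer coordinates cannot ship with the package, so every analysis
stage is exercised on synthetic assemblies built to have the geometric
and statistical features the methods rely on — and only those:

* `make_protomer()` — a compact self-avoiding C-alpha walk (consecutive
  spacing 3.6-4.0 Å, non-bonded pairs at least 3 Å apart) with pseudo
  heavy atoms within 2 Å of each C-alpha, 4-9 per residue by default.
  Contact topology is backbone-like; there is no secondary structure,
  sequence, or side-chain chemistry, so nothing tested here validates
  chemistry-dependent behaviour on real proteins.
* `assemble_oligomer()` — n copies on a C_n ring about z (or with
  alternate protomers flipped, for a dihedral dimer-of-trimers-like
  packing), with the ring radius bisected until the realised fraction of
  inter-protomer springs is within ±20% of the requested
  `interface_density`, and the protomer orientation searched over a
  deterministic grid until the assembled network has exactly six zero
  modes. That rigidity check matters: a near-point-like interface patch
  can leave a genuine torsional mechanism, which is a property of badly
  packed toy assemblies, not of crystal structures. Default conditions:
  six protomers of 40 residues, 5% interface density.
* `make_deformation()` — a second conformer displaced along a known mode
  recipe plus noise that is projected orthogonal to the recipe modes and
  to the rigid-body space, then scaled to `noise_frac` times the signal
  norm. The orthogonalisation is what makes recovery statistics exact:
  a single mode with noise fraction f must be recovered with overlap
  `1/sqrt(1+f^2)`, two equal coefficients give `1/sqrt(2)` each, and the
  tests and the acceptance script assert precisely those closed forms.
* `make_interlocked_dimer()` — two side-by-side helical strands whose
  heavy atoms actually touch across the interface, because a ring
  assembly tuned for *spring* density rarely has enough 4 Å *atomic*
  contacts to carry a connected communication graph. This is the
  fixture for the Markov model.

All generators restore the global RNG state, so they are bit-reproducible
under a fixed seed without perturbing the caller's stream.

## Problem sizes and runtime

The shipped tests and the acceptance script run on protomers of 15-40
residues and assemblies up to a 150-residue hexamer, where every
computation (dense eigensolves included) completes in seconds; these
sizes were chosen because every property asserted — zero-mode counts,
closed-form overlaps, Schur-complement identities, exhaustive path
enumeration — is size-independent. The same code paths handle
crystallographic hexamers (~1700 residues, a ~5000-dimensional
eigenproblem) in minutes.

## Known limitations

* The elastic network is protein-only and residue-level: ligands, waters
  and hydrogens are excluded from both the springs and the contact
  counts, and there is no mass weighting or distance-dependent force
  constant.
* Structural alignment between different proteins is consumed, not
  computed: cross-protein comparisons require an externally produced
  residue-correspondence file.
* Eigenvector-level statements inside degenerate eigenvalue pairs are
  not reproducible across platforms; use subspace overlaps there.
* The synthetic protomer is a random walk, not a fold; conclusions about
  real proteins rest on the method, not on these fixtures.

## A worked example

```{r example, eval = FALSE}
spec <- oligomer_spec(n_protomers = 6, protomer_size = 25,
                      interface_density = 0.05, seed = 2)
hex <- assemble_oligomer(spec)
modes <- anm_modes(hex)

# how well is the isolated AB dimer's dynamics conserved in the ring?
res <- run_conservation_analysis(hex, c("A", "B"),
                                 analysis_config(n_modes = 20))
subspace_overlap(res$modes_isolated, res$modes_embedded, m = 20, n = 20)
autoplot(res$overlap_isolated_vs_embedded)

# recover a planted conformational change
b <- make_deformation(hex, modes, list(c(6, 4)), noise_frac = 0.66,
                      seed = 31)
tr <- run_transition_analysis(hex, b)
autoplot(tr$curve)
```
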