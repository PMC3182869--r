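# oligodyn

Collective dynamics of protein oligomers from coarse-grained models: how
much of a subunit's intrinsic flexibility survives assembly into dimers
and hexameric rings, which motions the assembly creates anew, and through
which residues the subunits communicate.

Amino-acid-kinase-family enzymes (NAGK, carbamate kinase, UMP kinase) are
the motivating systems: the same monomer fold assembles into dimers and
trimers-of-dimers whose allosteric behaviour differs, so the interesting
quantities are comparative — modes of a monomer vs the same monomer
embedded in the oligomer, modes of a dimer vs the hexamer, modes vs the
experimentally observed T/R deformation.

## What it computes

**Anisotropic network model (ANM).** C-alpha nodes, springs between all
pairs within 15 Å, uniform force constant. The Hessian of

&nbsp;&nbsp;&nbsp;&nbsp;V = (γ/2) Σ_springs (|**R**_ij| − |**R**⁰_ij|)²

yields 3N−6 nonzero eigenpairs (λ_k, **u**_k): squared frequencies and
mode shapes. From these: per-residue mobility profiles Σ_k |**u**_k,i|²/λ_k,
mode-k cross-correlations, deformed conformers **R**⁰ + s·**u**_k, hinge
sites, and signed inter-residue distance-variation maps
λ_k^(−1/2)[(**u**_k)_i − (**u**_k)_j]·**R̂**⁰_ij.

**Subsystem in a dynamic environment.** Partitioning the Hessian into
subsystem/environment blocks and letting the environment relax gives the
effective (Schur-complement) Hessian H̃ = H_SS − H_SE H_EE⁻¹ H_ES, whose
modes are "the monomer as it moves inside the dimer/hexamer".

**Mode-conservation statistics.** Overlaps |**u**·**v**| (correlation
cosines), cumulative overlap CO(m) = √Σ_{k≤m}(Δ**r**·**u**_k/|Δ**r**|)²
against a superposed deformation vector Δ**r** between two states,
m×n overlap matrices with restriction-and-renormalisation for
component-in-assembly comparisons, subspace overlaps, and weighted
least-squares slope fits of the mode correspondence (slope magnitude 2 =
half the component modes unrepresented).

**Communication pathways.** Heavy-atom contact affinities
a_ij = N_ij/√(N_i N_j) (4 Å atom cutoff), Markov transitions
m_ij = a_ij/d_j, edge lengths −log m_ij, maximum-likelihood paths by
Dijkstra, and per-residue occurrence percentages over all ordered residue
pairs between two subunits — the profile whose peaks name the residues
carrying intersubunit communication.

**Synthetic oligomers.** Self-avoiding protomer traces assembled into
C_n rings with a tunable inter-protomer spring density, pseudo heavy
atoms for contact counting, and mode-recipe deformations with
orthogonalised noise so recovery statistics have exact closed forms.

## A worked example

```r
library(oligodyn)

spec <- oligomer_spec(n_protomers = 6, protomer_size = 25,
                      interface_density = 0.05, seed = 2)
hex <- assemble_oligomer(spec)

# is the AB dimer's dynamics conserved inside the ring?
res <- run_conservation_analysis(hex, c("A", "B"),
                                 analysis_config(n_modes = 20))
subspace_overlap(res$modes_isolated, res$modes_embedded, m = 20, n = 20)
#> [1] 0.9655276

# plant a conformational change along mode 6 with 66% orthogonal noise,
# then recover it from the two "crystal structures" alone
modes <- anm_modes(hex)
b <- make_deformation(hex, modes, list(c(6, 4)), noise_frac = 0.66,
                      seed = 31)
tr <- run_transition_analysis(hex, b)
tr$best_mode
#> [1] 6
round(tr$curve$overlap[6], 3)
#> [1] 0.835
```

The subspace overlap near 1 says the isolated dimer's 20 lowest modes
are essentially intact when the dimer moves inside the hexamer (its
effective-Hessian modes); the transition scan singles out mode 6 with
overlap 0.835 = 1/√(1+0.66²), exactly the planted signal-to-noise
ratio.

Real structures flow through the same functions: `read_structure()` on a
local PDB file (chains selected verbatim), `read_correspondence()` for an
externally computed alignment when the two states come from different
proteins, and `run_communication_analysis()` for interface pathways. A
thin CLI wraps the same calls
(`Rscript inst/cli/oligodyn.R modes --pdb file.pdb ...` with subcommands
`modes`, `conserve`, `transition`, `distvar`, `comm`, `synth`).

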