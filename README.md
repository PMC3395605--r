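# cgchaperone

Coarse-grained structure-based modelling of electrostatically steered
protein–protein binding, built for the coupled folding-and-binding of
charged intrinsically disordered proteins (IDPs) with folded partners — the
situation typified by a histone chaperone core wrapping a histone dimer.

**Who it is for.**  Anyone who wants to go from a multi-chain PDB structure
to a fully parameterized two-bead Gō-type model with salt-dependent
Debye–Hückel electrostatics, simulate its binding thermodynamics and
kinetics, and analyse the trajectories with the field's standard order
parameters — without a workstation cluster or any external software.

## The model in brief

Each residue is two beads: backbone (Cα) and side-chain centroid (glycine:
backbone only).  The Hamiltonian is the standard structure-based form

V = Σ ½K_b(r−r₀)² + Σ ½K_a(θ−θ₀)² + Σ K_d[(1−cos Δφ) + ½(1−cos 3Δφ)]
  + Σ K_c(C−C₀)²  + Σ ε_ij[5(r₀/r)¹² − 6(r₀/r)¹⁰] + V_ev + V_DH

with a side-chain chirality term (C is a normalized scalar triple product),
Miyazawa–Jernigan "flavored" backbone–backbone contact weights
ε_ij = 1 + α(ε^MJ_ij − ⟨ε^MJ⟩)/⟨ε^MJ⟩, uniform side-chain–side-chain
weights, no backbone–side-chain contacts, and screened electrostatics

V_DH = K·B(κ)·q_i q_j·exp(−κr)/(ε_r r),   κ = 0.329√C Å⁻¹,  ε_r = 80

acting on all charged pairs (Arg/Lys +1, Asp/Glu −1), native and
non-native.  Salt-bridge contacts are rescaled so Gō + DH at the native
distance equals a standard contact; backbone:side-chain dihedral strength
and contact:dihedral strength are both balanced to 2.0.  Langevin (BAOAB)
dynamics, fraction-of-native-contact coordinates (Qb, Qf, regional Q),
free-energy surfaces, binding φ-values, cutoff contact maps, collapse
diagnostics (Rg, charged-motif centroid distances), and a six-rate
encounter/intermediate/bound kinetic decomposition (k = N/MPT with
bootstrap errors) complete the stack.  The methods vignette
(`vignettes/cg-binding-model.Rmd`) documents every choice, default and
limitation.

## Worked example

```r
library(cgchaperone)

# a synthetic complex: folded hairpin chain + short disordered binder
spec <- toy_spec("LVALKEIV", "EKLV", arrangement = "hairpin_dimer", seed = 9)
make_toy_complex(spec, "complex.pdb")
topo <- build_topology("complex.pdb")
topo
#> cg_topology: 24 beads ( 12 BB / 12 SC ), 2 chain(s)
#>   bonds: 22  angles: 18  dihedrals: 6  chirality: 8
#>   native contacts: 10 ( 7 inter-chain, 2 salt bridges )
#>   net charge: 0 e

energy_balance_ratios(topo)
#> dihedral_ratio  contact_ratio
#>              2              2

total_energy(topology_xyz(topo), topo, electrostatics_params(C = 0.15))
#> bond                   0.000000
#> angle                  0.000000
#> dihedral               0.000000
#> chirality              0.000000
#> native_contact       -16.740960
#> excluded_volume       21.202881
#> electrostatic         -3.201363
#> wall                   0.000000
#> total                  1.260558

# a binding trajectory from a dissociated start at 0.15 M salt
start <- generate_dissociated_start(topo, seed = 2, min_separation = 35)
tr <- run(topo, simulation_params(temperature = 0.35, timestep = 0.004,
                                  friction = 0.5, n_steps = 2e6,
                                  save_interval = 500, seed = 21,
                                  initial = "frame", frame = start),
          control = ff_control(wall_radius = 35),
          stop_at_qb = 0.85, stop_hold = 3)
tr
#> cg_trajectory: 1128 frames x 24 beads; kT = 0.35 ; salt = 0.15 M; stop: bound

round(tail(q_series(tr, topo, q_definition(topo, "Qb")), 5), 3)
#> [1] 0.714 0.714 0.857 0.857 0.857
```

The native bonded terms are exactly zero by construction, the balance
ratios re-derive to 2.0 from the stored topology, and the kinetic run stops
once more than 85% of the seven interface contacts stay formed — here after
1128 saved frames, ending with 6/7 contacts (Qb = 0.857).

A thin CLI wrapping build/energy/run/fixture lives at
`inst/scripts/cgchaperone` (after installation:
`system.file("scripts", "cgchaperone", package = "cgchaperone")`).

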