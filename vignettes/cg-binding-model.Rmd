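---
title: "A two-bead structure-based model with Debye-Hückel electrostatics for coupled folding and binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-bead structure-based model with Debye-Hückel electrostatics for coupled folding and binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`cgchaperone` implements a structure-based (Gō-type) coarse-grained model for
the association of a highly charged, intrinsically disordered protein (IDP)
with a folded partner — the setting typified by histone chaperones binding
histone dimers.  Each amino acid is mapped to two beads: a backbone (BB) bead
at the Cα position and a side-chain (SC) bead at the unweighted centroid of
the side-chain heavy atoms; glycine gets a backbone bead only.  The potential
is the standard structure-based form — harmonic bonds and angles, cosine
backbone dihedrals with periods 1 and 3, a 12–10 well for every native
contact — extended with three ingredients that matter for charged IDP
binding:

1. **A side-chain chirality potential.**  Two-bead models can mirror-invert a
   side chain without cost unless handedness is penalized.  We use
   $V = K_c (C - C_0)^2$ where $C$ is the scalar triple product of the two
   local backbone vectors and the BB→SC vector, normalized by the three
   vector norms (so $C \in [-1, 1]$).  $C_0$ is taken from the native
   structure.  The normalized-triple-product form was chosen over an
   improper dihedral because it is cheaper and has no angular singularity;
   both preserve handedness.

2. **Flavored contact weights.**  Backbone–backbone native contacts carry
   amino-acid-dependent Miyazawa–Jernigan weights through
   $\epsilon_{ij} = 1 + \alpha\,(\epsilon^{MJ}_{ij} - \langle\epsilon^{MJ}\rangle)/\langle\epsilon^{MJ}\rangle$,
   with the mean taken over the BB–BB contacts present in the system, floored
   at 0.1 so no contact turns repulsive.  $\alpha = 1$ (the "flavored"
   model) is the default; $\alpha = 0$ recovers the plain unflavored Gō
   model exactly, which is a tested invariant.  Side-chain–side-chain
   contacts are weighted uniformly, and backbone–side-chain contacts are
   never created.  The normalized (mean-relative) form of the MJ weighting
   is one of two defensible readings of the flavoring recipe; it is used
   because it keeps the mean contact strength independent of composition,
   and it is configurable.

3. **Debye–Hückel electrostatics.**  Arg/Lys side-chain beads carry +1,
   Asp/Glu −1, everything else is neutral.  All charged pairs — native and
   non-native alike — interact through
   $V = K\,B(\kappa)\,q_i q_j\, e^{-\kappa r}/(\epsilon_r r)$ with
   $\epsilon_r = 80$, $\kappa = 0.329\sqrt{C}\ \text{Å}^{-1}$ for monovalent
   salt at 298 K, and the finite-ion-size coefficient
   $B(\kappa) = e^{\kappa a}/(1 + \kappa a)$ with ion-exclusion radius
   $a = 1.425$ Å.  Including non-native charged pairs is essential: the
   salt-dependent collapse of a bipolar charged motif is driven entirely by
   non-native attraction.

## Contact map

Native contacts are detected with a structural-unit-style stand-in: a residue
pair is in contact when any heavy-atom pair across the two residues is within
4.5 Å.  The pair is classified by the closest-approach atoms (both backbone →
BB–BB, both side chain → SC–SC; mixed approaches go to SC–SC when both
residues carry an SC bead, else BB–BB), so the model's exclusion of
backbone–side-chain terms holds by construction.  Intra-chain BB–BB contacts
require a sequence separation of at least 4 (bonded terms already govern
closer pairs), SC–SC at least 3.  The cutoff and separations are arguments,
not constants.

## Energy balance

Two ratios organize the relative strength of the terms: backbone-dihedral to
side-chain (chirality) strength is set to 2.0, and total contact strength to
total dihedral-class strength is set to 2.0, where "strength" is the sum of
the respective force constants or well depths.  Only the two ratios are
constrained, so a normalization must be chosen: the backbone dihedral scale
is the anchor (unchanged, $K_d = 1\,\epsilon_0$ per term), chirality and
contacts are rescaled around it.  This makes `balance_energies()` idempotent
and invariant to a uniform pre-scaling of the contact weights, both of which
are tested.

## Salt bridges

A native SC–SC contact between opposite charges would otherwise be counted
twice — once as a Gō well, once electrostatically.  Its well depth is
therefore reduced so that (Gō depth + DH energy at the native distance, at
the reference concentration of 0.15 M) equals the standard side-chain depth.
The rescaling runs *after* balancing, in final energy units, so the defining
identity holds to machine precision in the serialized topology; the amount
subtracted is stored per contact (`dh_comp`), which keeps the post-balance
contact:dihedral ratio exactly 2.0 when salt-bridge contacts are counted at
their combined Gō+DH strength.  Very close pairs whose DH energy exceeds the
standard depth are floored at 5% of it rather than driven negative.

## Units and temperature labels

Lengths are in Å, energies in the reduced unit $\epsilon_0$, $k_B = 1$,
bead mass 1, time in $\tau = \sqrt{m\,\text{Å}^2/\epsilon_0}$.  Kelvin
temperature labels customary in this model family follow the convention
$k_B = 0.00831451\,\epsilon_0/\text{K}$, exposed as
`reduced_temperature()`; the kinetic label "55 K" maps to
$k_BT = 0.457\,\epsilon_0$.  The electric conversion factor is calibrated
(`calibrate_kcoulomb()`) so that the DH energy of a +1/−1 pair at 5 Å and
0.15 M equals one energy unit — i.e. long-range electrostatics at contact
range is as strong as a native contact; the reference point is exposed as
two arguments.

# Dynamics

`run()` integrates Langevin dynamics with the BAOAB splitting
(velocity Verlet when friction is zero), defaults $dt = 5\times10^{-4}\tau$,
$\gamma = 1\,\tau^{-1}$.  Toy-scale tests use $dt$ up to $5\times10^{-3}\tau$,
well inside stability for the stiffest term ($K_b = 100$, period
$0.44\,\tau$).  All randomness — initial Maxwell–Boltzmann velocities and
the thermostat noise — flows from R's seeded RNG, so a (seed, platform)
pair reproduces a trajectory bitwise.  Validation: bond-length variance
equals $k_BT/K_b$ (equipartition), NVE energy drift $< 10^{-4}\epsilon_0$
per $10^4$ steps, thermostatted velocities pass a KS test against the
Maxwell–Boltzmann distribution, and a bistable pair reproduces quadrature
occupancies (detailed balance).

Kinetic runs start from dissociated configurations
(`generate_dissociated_start()`): the disordered chain is melted in a short
high-temperature run of that chain alone, the folded partner stays native,
and the chains are placed at a minimum centroid separation with no native
interface contact formed.  A soft spherical wall (off for plain energy
evaluation) keeps dissociated chains re-encounterable, mimicking a finite
concentration; its energy is reported as a separate component.  Excluded
volume is a $(\sigma/r)^{12}$ repulsion ($\sigma = 4$ Å) over non-native,
non-bonded pairs, shift-truncated at $4\sigma$ (the discontinuity in the
force there is $\sim 5\times10^{-8}\,\epsilon_0/\text{Å}$, far below the
$10^{-6}$ gradient-test tolerance).  Pairs sharing a bond or an angle are
excluded from contacts, excluded volume and electrostatics.

# Reaction coordinates and analyses

Fractions of native contacts use a formed-contact tolerance of
$1.2\,r_{\text{native}}$ (the standard convention; configurable):
$Q_b$ over all inter-chain contacts, $Q_f$ over the IDP's intra-chain
contacts, and regional $Q_N$, $Q_{Motif}$, $Q_C$ over inter-chain contacts
grouped by the IDP-side residue.  The shipped region profile for the
chaperone core (N-helix 81–93, motif 94–115 with acidic 94–103 / neutral
104–111 / basic 112–115, C-helix 116–132) is a named default and fully
overridable.  Free-energy surfaces are plain histograms,
$F = -k_BT\ln P$ shifted to zero at the minimum; empty bins are reported
as missing, never as zero or infinity, so barrier measurements stay
explicit.  No multi-temperature reweighting is attempted.

Binding φ-values count only native inter-chain contacts:
$\phi_x = \langle N_x\rangle_{TS} / N_x^{\text{bound}}$ per IDP residue,
with NA (never 0/0) where a residue has no binding contacts.  The
transition-state ensemble is selected by an inclusive window on $Q_b$,
default [0.06, 0.13] — where the barrier top sits depends on the sampling
temperature of the landscape, so the window is an argument.  Per-frame contact counts
are averaged before dividing; thresholding formation per frame first gives
identical bound/unbound limits and differs only at intermediate occupancy,
so the count-averaging reading is used.

Cutoff contact maps deliberately count *non-native* proximity too: mode
"BB" is the probability that two backbone beads are within 8 Å, mode
"SC-charged" restricts to oppositely charged side chains within 6 Å.  Both
cutoffs are arguments (neither has a canonical value), and the map
also returns per-residue mean inter-chain contact numbers.  Collapse
diagnostics are the mass-uniform radius of gyration, centroid distances
between charged blocks, and mean side-chain distance maps.

# Kinetic state machine

Frames are labelled over {U, E, I1, I2, B} in priority order
B > I1/I2 > E > U: bound when $Q_b \ge 0.8$; intermediate I1 when
$Q_N \ge 0.6$ and $Q_C \le 0.2$ (I2 with the roles swapped — the intermediate
basins live on the $(Q_N, Q_C)$ plane but their exact extent varies by
system, so 0.6/0.2 are configurable defaults); encounter when any
inter-chain bead pair is within 8 Å (an encounter criterion has no
canonical numerical definition); unbound otherwise.  A five-frame debounce
suppresses single-frame flickers that would otherwise bias passage-time
estimators.

Each of the six rates (U→E, E→U, E→I1, E→I2, I1→B, I2→B) is reported as
$k = N/T_{\text{origin}}$: the pooled transition count over the pooled time
spent in the origin state, which is the maximum-likelihood estimator when
several exits compete, together with $MPT = T_{\text{origin}}/N$.  Trailing
(censored) episodes contribute exposure time to their origin state; dropping
them measurably biases slow exits upward (+20% on the validation generator).
Pooling over trajectories (rather than averaging per-trajectory rates)
matches the printed $k = N/MPT$ form; uncertainties come from a seeded
bootstrap over trajectories (200 resamples).  The whole machinery is
validated against exact Gillespie simulation of a five-state generator:
with 500 series every recovered rate sits within 3 bootstrap standard
errors of its generator value.  Pathway classification reports the last
intermediate visited before first binding ("direct" if none) and the first
region whose binding coordinate exceeds 0.8.

# Synthetic fixtures — what they emulate and what they do not

`make_toy_complex()` writes minimal all-atom-lite PDBs (N/CA/C/O plus one
CB-like side-chain atom; ideal bond geometry with a small out-of-plane
zigzag and seeded jitter) realizing three arrangements: two antiparallel
strands with facing side chains, a hairpin plus binder (so the "folded"
chain has intra-chain contacts), and a separated pair.  Each fixture ships
its own ground-truth contact manifest computed by direct distance
enumeration, which the builder must reproduce exactly.  These toys exercise
every code path (salt bridges, glycine handling, BB–BB classification) but
have no rotamer realism and do not attempt to mimic any real free-energy
landscape.

`make_bipolar_idp()` is the collapse testbed: a 30-residue flexible coil
(bonds and angles only — no dihedrals, chirality or native contacts, so
nothing but non-native electrostatics can drive compaction) with a −1 block
at residues 5–10 and a +1 block at 20–25.  At 0.02 M the screening length
(≈21 Å) spans the blocks and the coil compacts; at 0.5 M (≈4 Å) it does
not.  The packaged test runs 20 seeds per condition for $4\times10^5$ steps
at the kinetic temperature and requires the high-salt mean $R_g$ to exceed
the low-salt mean at one-sided $p < 0.01$.  Problem sizes throughout
(trajectory lengths, 500 Gillespie series, 50 oracle frames) are chosen so
the full suite runs on a single desktop CPU in minutes; they are desk-scale
choices, and the statistical tolerances quoted above are set accordingly.

`make_markov_series()` provides the exact-stochastic oracle for the rate
estimators; its generator matrix is the ground truth.

# Numerical choices and degenerate inputs

* Force constants vary across this model family; standard magnitudes are
  used ($K_b = 100\,\epsilon_0/\text{Å}^2$,
  $K_a = 20\,\epsilon_0/\text{rad}^2$, $K_d = 1\,\epsilon_0$,
  $K_c = 20\,\epsilon_0$ before balancing) and all are arguments.
* Chains shorter than four residues get no backbone dihedrals (warning);
  terminal residues get no chirality term; poly-glycine systems skip the
  dihedral ratio with a flag in the balance metadata and factors left at 1.
* An empty contact list is a warning, not an error (fully extended toys).
* NMR multi-model files use the first model; altloc A is kept; hydrogens,
  waters and HETATM records are dropped; 1-based PDB residue numbering is
  preserved in the bead table while all term tables use internal indices.
* Energy blow-up ($|E| > 10^8\,\epsilon_0$) aborts a run with the offending
  step index rather than returning NaN frames.
* Overlapping charged beads (r < 0.01 Å) are an error before they can
  produce infinite forces.

# Known limitations

* Plain-histogram free-energy surfaces only; no WHAM/MBAR, replica
  exchange, or committor analysis.
* The contact detector is a single-cutoff stand-in for the original
  structural-units software; it reproduces its inclusive spirit but not its
  exact surface criteria.
* No periodic boundaries or explicit ions; the DH form is valid for dilute
  monovalent salt.
* Kinetic quantities at desk scale rest on far fewer transitions than
  cluster-scale sampling would give; the package reports counts alongside
  every rate so undersampling is visible.
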