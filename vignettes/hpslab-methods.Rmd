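---
title: "Coarse-grained slab simulations of condensates with hpslab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained slab simulations of condensates with hpslab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`hpslab` simulates liquid-liquid phase separation (LLPS) of
intrinsically disordered proteins (IDPs) and single-stranded RNA at
one bead per residue. Three energy terms act between beads:

* **Harmonic bonds** between consecutive beads,
  $U_b = \tfrac{k}{2}(r - r_0)^2$ with $k = 10$ kcal/mol/A^2 and
  $r_0 = 3.8$ A for protein (the C$\alpha$--C$\alpha$ virtual bond) or
  $5.0$ A for RNA. Angles and dihedrals are not modelled: every bead
  is treated as part of a fully flexible disordered chain, which is
  the regime the force field was parameterized for. Folded domains
  are out of scope.
* **Ashbaugh--Hatch hydropathy term** for all non-bonded pairs:
  $\Phi(r) = \Phi_{LJ}(r) + (1-\lambda_{ij})\varepsilon$ for
  $r \le 2^{1/6}\sigma_{ij}$ and $\lambda_{ij}\Phi_{LJ}(r)$ beyond,
  where $\Phi_{LJ} = 4\varepsilon[(\sigma/r)^{12} - (\sigma/r)^6]$.
  The per-residue hydropathy $\lambda_i \in [0,1]$ scales the
  attractive well while the excluded-volume core is kept for every
  pair; $\sigma$ and $\lambda$ mix arithmetically. The packaged scale
  is Urry-style: aromatics high ($\lambda_W = 1.0$,
  $\lambda_Y = 0.90$, $\lambda_F = 0.82$), arginine well above lysine
  (0.56 vs 0.38), glutamate near zero. $\varepsilon = 0.2$ kcal/mol
  globally, configurable.
* **Debye--Hueckel electrostatics**,
  $\Phi(r) = 332.0637\, q_i q_j e^{-\kappa r} / (\epsilon_r r)$
  kcal/mol, with $\kappa$ from the closed form
  $\kappa^2 = 8\pi \ell_B N_A I$ (Bjerrum length $\ell_B$ in the
  implicit solvent, $\epsilon_r = 80$). At the default 0.15 M ionic
  strength and 300 K the screening length is 7.95 A. Charges: D/E
  $-1$, K/R $+1$, each ribonucleotide $-1$; histidine is neutral by
  default with a configurable override, since published HPS variants
  disagree on its protonation.

Units are fixed package-wide: Angstrom, picosecond, amu, kcal/mol,
Kelvin, elementary charge.

Both non-bonded terms are truncated and energy-shifted to zero at
their cutoffs (defaults: 20 A hydropathy, 35 A electrostatic, i.e.
about 4.4 screening lengths). The unshifted Ashbaugh--Hatch form
equals $-\lambda\varepsilon$ exactly at the branch point
$2^{1/6}\sigma$; the shifted form used in dynamics differs from it by
the (small) constant outer-branch value at the cutoff.

Contact radii are *not* the interaction $\sigma$: the contact
criterion of the analysis layer uses radii derived from residue
volumes, $R_i = (3V_i/4\pi)^{1/3}$, and two beads on different chains
are "in potential contact" when their minimum-image distance is
strictly below $R_i + R_j$. At coarse resolution this deliberately
reads as *potential* contact: the model cannot resolve hydrogen bonds
or stacking, only proximity.

# The slab protocol

Direct-coexistence ("slab") simulations measure both phases at once:
chains are replicated on a grid (production scale: $2 \times 2 \times
30$, 120 chains), the periodic box is shrunk to an elongated cell
(180 x 180 x 1800 A, a 3.4 mM chain concentration -- far above
experimental micromolar concentrations, which stands in for the
crowding agents used in vitro), and the production run lets a dense
slab coexist with a dilute phase along $z$.

Numerical choices:

* **Integrator**: BAOAB-split Langevin dynamics, dt = 0.01 ps,
  friction $\gamma$ = 0.01 ps$^{-1}$ in production. The weak friction
  perturbs diffusive dynamics minimally but removes heat slowly, so
  the *compression* phase -- in which the shrinking box does work on
  the system -- runs strongly coupled ($\gamma$ = 1 ps$^{-1}$) and
  velocities are re-thermalized at the target temperature afterwards.
  Without this the compression work survives into production as
  excess kinetic energy.
* **Neighbour search**: Verlet lists (3 A skin) from sorted cell
  grids, one list for the hydropathy term over all beads and a
  separate, longer-ranged list restricted to charged beads.
  Coordinates stay unwrapped between list rebuilds so that each
  pair's cached periodic image remains valid; rebuilds (triggered
  when any bead moves half the skin) rewrap. Forces are exact:
  against an all-pairs reference evaluation the cell-list energies
  agree to better than $10^{-9}$ relative on randomized systems, and
  forces match central-difference gradients to $10^{-5}$ kcal/mol/A.
* **Determinism**: the engine owns its RNG (splitmix64-seeded
  xoshiro256+ with a ziggurat normal sampler); a given seed and
  configuration reproduce a trajectory bit-for-bit on one platform.
* **Writer convention**: frames are written at step multiples of the
  write interval, excluding step 0, so 1e7 steps at interval 1e4
  give exactly 1,000 frames 100 ps apart (100 ns).
* **Divergence**: a non-finite energy aborts the run with an error
  object that retains the last valid frames.

# Analyses

**Contacts.** `contact_map()` applies the strict radius-sum criterion
per frame (inter-chain pairs only, so bonded neighbours can never
appear). `residue_profile()` reports mean contacts per frame per
sequence position, pooled over all chain copies -- the per-residue
profile that identifies sticker residues (tyrosines, in a PARCL-like
sequence). `transience_fraction()` pools over consecutive frame
pairs the fraction of contacts present at $t$ and absent at
$t+\Delta t$; values near 100% at $\Delta t$ = 100 ps indicate a
liquid, not an aggregate. `pair_counts()` aggregates position pairs
over copies, by default counting a position pair at most once per
frame (the alternative, per-copy incidence counting, is a switch:
the convention behind published per-pair thresholds is ambiguous,
and the default is the more conservative reading).
`contact_network()` keeps pairs reaching a count threshold,
*inclusive* ("at least"). `group_contact_matrix()` crosses two chain
groups (e.g. protein x RNA) into a position-by-position mean-contact
matrix whose grand total is the group pair's mean contacts per
frame; for identical groups each unordered contact is counted once
and split symmetrically, so group totals always partition the total
contact count.

**Phases.** `density_profile()` bins beads into 1 A slices along
$z$, recentring each frame on the slab via the circular mean of bead
$z$ positions (the standard way to stop slab drift from smearing the
profile; it makes profiles invariant to rigid $z$ translation).
Slice sums equal the bead count exactly. `phase_concentrations()`
takes the dense density as the mean over a central band (default
centre +/- 50 A) and the dilute density beyond a margin (default 300
A, sized for the 1800 A production box; reduced boxes need
proportionally smaller bands). `slab_maintained()` demands a
dense/dilute contrast of at least 10 (the package's operational
criterion -- no numeric threshold is standard) *and* a contiguous
above-half-maximum band on the periodic axis; profiles that split
into two droplets are flagged rather than averaged, and
`phase_diagram()` carries non-slab temperatures as flagged rows
instead of interpolating them.

**Mutation screening.** `generate_mutant_sets()` enumerates (or
randomly samples, seeded) subsets of a target residue's positions;
`run_screen()` simulates each mutant under per-run seeds derived
from a master seed by a counter-based splitter and summarizes each
run by the mean and sd of the HPS interaction energy
$E_{HPS} = E_{hydropathy} + E_{elec}$ over a tail window (whether
the reported energy should include electrostatics is not settled;
a switch excludes it). `rank_mutants()` orders by mean $E_{HPS}$
descending -- closer to zero means weaker condensation, i.e. more
disruption -- breaking ties toward fewer mutations.

# Synthetic sequences and what the tests show

No PARCL or miR399 sequence is published in a form this package can
ship, so the generator builds seeded stand-ins with the features
that drive the biology: a leading methionine; well-spaced tyrosines
confined to the N-terminal half (the prion-like region); a short
K/R/H-rich patch toward the C-terminus padded with serines (the
RNA-binding region and the serine-mutation site); and a
G/S/Q/N/P-rich, charge-poor background typical of plant IDR
composition. Real sequences are supplied as FASTA when available.

The reduced benchmark (`reduced_slab_run()`) uses 20 copies of a
150-residue, 8-tyrosine chain in a 100 x 100 x 600 A box (5.5 mM)
for 5 ns -- sizes chosen so the whole workflow, including contact
analysis, runs on a single CPU in minutes while still condensing
into liquid clusters. At this scale the package reproduces the
*liquidity* of the condensate (contact transience at or above 99%
over 100 ps frame spacing) and the *signs* of the mutation effects:
replacing the tyrosines with glutamate moves the mean HPS energy
toward zero, and replacing the basic-patch serines with glutamate
cuts protein-RNA contacts without cutting protein-protein contacts.
What the reduced scale cannot reproduce are full-scale magnitudes:
published per-frame contact totals, per-residue peak heights and
phase-diagram densities come from 18,000-24,000-bead, 100-400 ns
trajectories; those remain out of desk reach and are checked instead
through the property suite (force/oracle agreement, microcanonical
energy conservation, equipartition, exact density-profile inversion
on constructed two-phase profiles).

Synthetic stand-ins also mean the absolute contact numbers depend on
the generated composition; only statements that are robust to the
composition (liquidity, mutation signs, conservation laws) are
asserted.

# Worked example

```{r example}
library(hpslab)

ps <- load_params()                      # packaged Urry-style table
chain <- make_parcl_like(length = 150, n_tyr = 8, patch_center = 130,
                         seed = 42)
cfg <- engine_config(n_steps = 5e5, write_interval = 1e4, seed = 42)

traj <- slab_simulation(chain, ps, cfg, grid = c(2, 2, 5),
                        spacing = c(80, 80, 140),
                        target_box = c(100, 100, 600))

cmap <- contact_map(traj, ps)
transience_fraction(cmap)                # near 100%: a liquid
head(residue_profile(cmap))              # per-residue contact profile

prof <- density_profile(traj)            # final-half window
phase_concentrations(prof, dense_halfwidth = 50, dilute_margin = 150,
                     temperature = 300)
```

# Known limitations

* All beads are disordered-chain beads: fusion constructs with
  folded domains (e.g. fluorescent-protein tags) are outside the
  model, mirroring the regime where this force-field family is
  reliable.
* No crowding agent is modelled; high chain concentration stands in.
* RNA is a flexible polyanion here -- no base pairing, stacking or
  secondary structure.
* The packaged RNA bead parameters are representative
  one-bead-per-nucleotide values; users with a specific RNA
  parameterization should supply their own table
  (`load_params(file)`).
* Phase diagrams report per-temperature coexistence densities only;
  critical-temperature fits are not attempted.
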