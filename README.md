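# hpslab

Coarse-grained molecular dynamics of biomolecular condensates in R:
one-bead-per-residue slab simulations of intrinsically disordered
protein (and single-stranded RNA) phase separation under a
hydropathy-scale (HPS) force field, with the contact, phase-diagram
and mutation-screening analyses used to find and validate the
residues that drive liquid-liquid phase separation (LLPS).

The package is aimed at researchers who want to ask, for a disordered
sequence such as the phloem protein PARCL: does it phase separate in
silico, which residues hold the condensate together, and what happens
when you mutate them — before committing to wet-lab mutants.

## The model

Each residue is one bead. Three terms act between beads (units: A,
ps, amu, kcal/mol, K, e):

* bonds: `U = k/2 (r - r0)^2`, `r0` = 3.8 A (protein) / 5.0 A (RNA);
* hydropathy (Ashbaugh–Hatch): `Phi_LJ(r) + (1 - lambda) eps` inside
  the Lennard-Jones minimum, `lambda Phi_LJ(r)` beyond, with
  arithmetic mixing of `sigma` and of the per-residue hydropathy
  `lambda` (Urry-style scale: W 1.0, Y 0.90, F 0.82, R 0.56 > K 0.38,
  E ~0), `eps` = 0.2 kcal/mol;
* screened electrostatics (Debye–Hückel):
  `332.0637 q_i q_j exp(-kappa r) / (eps_r r)`, `kappa` from the
  ionic strength (7.95 A screening length at 0.15 M, 300 K).

Dynamics are BAOAB Langevin (dt = 0.01 ps) in a periodic box that is
first compressed to an elongated "slab" cell (production protocol:
120 chains on a 2 x 2 x 30 grid shrunk to 180 x 180 x 1800 A, i.e.
3.4 mM), so a dense condensed phase coexists with a dilute phase
along z. Contacts between chains use the radius-threshold criterion:
two beads on different chains are in (potential) contact when closer
than the sum of their volume-derived radii `(3V/4pi)^(1/3)`.

## Worked example

A reduced version of the production workflow — 20 copies of a seeded
150-residue PARCL-like sequence, compressed into a 100 x 100 x 600 A
slab box and run for 5 ns:

```r
library(hpslab)

ps  <- load_params()                       # 24 bead types, Urry-style
traj <- reduced_slab_run(seed = 1)         # ~15 min on one CPU
traj
#> hps_trajectory: 50 frames every 100 ps (5 ns total), 3000 beads

round(tail(traj$energies$e_hps, 1))        # sustained negative = condensate
#> [1] -698

cmap <- contact_map(traj, ps)
transience_fraction(cmap)
#> [1] 99.87034
```

The transience statistic is the share of inter-chain residue-pair
contacts present in one frame that are gone 100 ps later; values near
100% mean the dense phase is a liquid (partners constantly exchange),
not an aggregate. The per-frame HPS interaction energy (`e_hps`)
fluctuating around a clearly negative value indicates a condensate;
values near zero indicate no phase separation.

Per-residue drivers and mutation screening:

```r
prof <- residue_profile(cmap)              # mean contacts/frame by position
prof[order(-prof$mean_contacts), ][1:5, ]  # tyrosines lead

chain <- make_parcl_like(length = 150, n_tyr = 8, seed = 1)
sets  <- generate_mutant_sets(chain, "Y", sizes = c(0, 2),
                              sampler = "random", n_random = 3, seed = 1)
cfg   <- engine_config(n_steps = 1e5, write_interval = 2000, seed = 1)
rank_mutants(run_screen(chain, sets, ps, cfg))
# mean_ehps closer to zero = stronger LLPS disruption
```

A thin command-line front end over the same functions is installed at
`inst/cli/hpslab.R` (subcommands `synth`, `build`, `compress`, `run`,
`contacts`, `phases`, `screen`).

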