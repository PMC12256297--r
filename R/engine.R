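#' Ashbaugh-Hatch pair potential
#'
#' Lennard-Jones-derived potential whose attractive well is scaled by
#' the mixed hydropathy `lambda`:
#' `Phi(r) = Phi_LJ(r) + (1 - lambda) eps` for `r <= 2^(1/6) sigma` and
#' `lambda Phi_LJ(r)` beyond, with
#' `Phi_LJ = 4 eps ((sigma/r)^12 - (sigma/r)^6)`. The form is
#' continuous at the branch point, where it equals `-lambda eps`. With
#' a finite `cutoff` the outer-branch value at the cutoff is subtracted
#' everywhere (energy shift), so the potential vanishes at the cutoff;
#' this shifted form is what the engine integrates.
#'
#' @param r distance(s), Angstrom; must be positive.
#' @param sigma mixed pair sigma, Angstrom.
#' @param lambda mixed pair hydropathy.
#' @param eps interaction strength, kcal/mol.
#' @param cutoff truncation distance; `Inf` (default) for the
#'   unshifted potential.
#' @return energy in kcal/mol.
#' @export
ah_potential <- function(r, sigma, lambda, eps = 0.2, cutoff = Inf) {
  if (any(r <= 0)) stop("r must be positive")
  lj <- function(x) 4 * eps * ((sigma / x)^12 - (sigma / x)^6)
  v <- ifelse(r <= 2^(1 / 6) * sigma,
              lj(r) + (1 - lambda) * eps,
              lambda * lj(r))
  if (is.finite(cutoff)) {
    v <- v - lambda * lj(cutoff)
    v[r >= cutoff] <- 0
  }
  v
}

#' Debye-Hueckel screened electrostatic potential
#'
#' `Phi(r) = 332.0637 q_i q_j exp(-kappa r) / (eps_r r)` kcal/mol, the
#' screened-Coulomb interaction between unit charges in an implicit
#' electrolyte. `kappa = 0` gives the unscreened Coulomb limit. With a
#' finite `cutoff` the value at the cutoff is subtracted (energy
#' shift).
#'
#' @param r distance(s), Angstrom; must be positive.
#' @param qi,qj charges, elementary units.
#' @param kappa inverse screening length, 1/Angstrom (see
#'   [debye_kappa()]).
#' @param dielectric relative permittivity.
#' @param cutoff truncation distance; `Inf` for no shift.
#' @return energy in kcal/mol.
#' @export
dh_potential <- function(r, qi, qj, kappa, dielectric = 80, cutoff = Inf) {
  if (any(r <= 0)) stop("r must be positive")
  fac <- .coulomb * qi * qj / dielectric
  v <- fac * exp(-kappa * r) / r
  if (is.finite(cutoff)) {
    v <- v - fac * exp(-kappa * cutoff) / cutoff
    v[r >= cutoff] <- 0
  }
  v
}

# common argument marshalling for the compiled kernels
engine_args <- function(state, ps, cfg) {
  sp <- state_params(state, ps)
  bonds <- state_bonds(state, cfg)
  tabs <- pair_tables(ps, cfg)
  list(sp = sp, bonds = bonds, tabs = tabs)
}

#' Forces and energy decomposition of a configuration
#'
#' Evaluates the full HPS model (harmonic bonds, Ashbaugh-Hatch
#' hydropathy term, Debye-Hueckel electrostatics, both energy-shifted
#' at their cutoffs) under the minimum-image convention using cell-list
#' neighbour search.
#'
#' @param state a `system_state`.
#' @param ps an `hps_params`.
#' @param cfg an `engine_config`.
#' @return list with `forces` (n x 3, kcal/mol/A) and `energy`, an
#'   energy report with `e_bond`, `e_hydropathy`, `e_elec`, `e_hps`.
#' @export
compute_forces <- function(state, ps, cfg) {
  if (max(cfg$cutoff_ah, cfg$cutoff_dh) >= min(state$box) / 2)
    stop("cutoff must be below half the smallest box edge")
  ea <- engine_args(state, ps, cfg)
  out <- cpp_forces(state$coords, ea$sp$mass, ea$sp$type0, state$chain,
                    ea$sp$charge, ea$bonds$i, ea$bonds$j, ea$bonds$r0,
                    cfg$k_bond, state$box, ea$tabs$sig2, ea$tabs$lam,
                    ea$tabs$ahshift, cfg$eps, cfg$cutoff_ah,
                    cfg$cutoff_dh, cfg$kappa, ea$tabs$coulfac, cfg$skin)
  e_hps <- out$e_hydropathy +
    if (cfg$ehps_includes_elec) out$e_elec else 0
  list(forces = out$forces,
       energy = list(e_bond = out$e_bond,
                     e_hydropathy = out$e_hydropathy,
                     e_elec = out$e_elec, e_hps = e_hps))
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Initializes per-bead velocities at the configured temperature,
#' component-wise normal with sd `sqrt(kB T / m)`.
#'
#' @param state a `system_state`.
#' @param ps an `hps_params`.
#' @param temperature K.
#' @param seed optional RNG seed.
#' @return the state with `$vel` set (Angstrom/ps).
#' @export
maxwell_velocities <- function(state, ps, temperature = 300, seed = NULL) {
  m <- state_params(state, ps)$mass
  sdv <- sqrt(.kB * temperature * .kcal2akma / m)
  state$vel <- with_seed(seed,
    matrix(rnorm(3 * length(m)), ncol = 3) * sdv)
  state
}

run_engine <- function(state, ps, cfg, n_steps, box_target,
                       write_interval) {
  if (max(cfg$cutoff_ah, cfg$cutoff_dh) >= min(state$box, box_target) / 2)
    stop("cutoff must be below half the smallest box edge")
  ea <- engine_args(state, ps, cfg)
  vel <- state$vel
  if (is.null(vel)) vel <- matrix(numeric(0), 0, 3)
  cpp_run(state$coords, vel, ea$sp$mass, ea$sp$type0, state$chain,
          ea$sp$charge, ea$bonds$i, ea$bonds$j, ea$bonds$r0, cfg$k_bond,
          state$box, box_target, as.integer(n_steps), cfg$dt,
          cfg$friction, cfg$temperature, as.integer(write_interval),
          as.numeric(cfg$seed), ea$tabs$sig2, ea$tabs$lam,
          ea$tabs$ahshift, cfg$eps, cfg$cutoff_ah, cfg$cutoff_dh,
          cfg$kappa, ea$tabs$coulfac, cfg$skin)
}

traj_from_run <- function(out, state, cfg, write_interval) {
  nf <- out$n_frames
  state$coords <- out$coords
  state$vel <- out$vel
  state$box <- out$box
  el <- out$elog[seq_len(nf), , drop = FALSE]
  energies <- data.frame(step = el[, 1], time = el[, 1] * cfg$dt,
                         e_bond = el[, 2], e_hydropathy = el[, 3],
                         e_elec = el[, 4], e_kinetic = el[, 5])
  energies$e_hps <- energies$e_hydropathy +
    if (cfg$ehps_includes_elec) energies$e_elec else 0
  frames <- out$frames
  if (nf < dim(frames)[3]) frames <- frames[, , seq_len(nf), drop = FALSE]
  traj <- structure(list(
    frames = frames, boxes = out$boxes[seq_len(nf), , drop = FALSE],
    energies = energies, n_frames = nf,
    frame_interval = cfg$dt * write_interval,
    dt = cfg$dt, write_interval = write_interval,
    seed = cfg$seed, config = cfg, system = state),
    class = "hps_trajectory")
  if (isTRUE(out$diverged)) {
    cond <- structure(class = c("hps_divergence", "error", "condition"),
                      list(message = paste0(
                        "simulation diverged (non-finite energy) at step ",
                        out$diverged_step, "; last valid frame retained"),
                        call = sys.call(-1), trajectory = traj))
    stop(cond)
  }
  traj
}

#' @export
print.hps_trajectory <- function(x, ...) {
  cat(sprintf(
    "hps_trajectory: %d frames every %.4g ps (%.4g ns total), %d beads\n",
    x$n_frames, x$frame_interval, x$n_frames * x$frame_interval / 1000,
    n_beads(x$system)))
  invisible(x)
}

#' Compress the box to the slab geometry
#'
#' Runs dynamics while shrinking the box linearly to `target_box` over
#' `n_steps` (the production default target is the
#' 180 x 180 x 1800 A slab cell); coordinates rescale affinely with the
#' box each step, and the final box equals the target exactly.
#'
#' @param state a `system_state` (velocities drawn if absent).
#' @param ps an `hps_params`.
#' @param cfg an `engine_config`.
#' @param target_box length-3 target, Angstrom; must not exceed the
#'   current box on any axis.
#' @param n_steps compression steps.
#' @param friction thermostat friction during compression, 1/ps.
#'   Compression does work on the system, so the box-shrinking phase
#'   couples strongly to the heat bath (default 1/ps) and velocities
#'   are re-thermalized at the target temperature afterwards; the
#'   production friction in `cfg` is typically much weaker.
#' @return the compressed `system_state` (box = target).
#' @export
compress <- function(state, ps, cfg, target_box = c(180, 180, 1800),
                     n_steps = 10000, friction = 1.0) {
  target_box <- rep_len(as.numeric(target_box), 3)
  if (any(target_box > state$box + 1e-9))
    stop("target box exceeds current box on at least one axis")
  if (is.null(state$vel))
    state <- maxwell_velocities(state, ps, cfg$temperature, cfg$seed)
  cfgc <- cfg
  cfgc$friction <- friction
  out <- run_engine(state, ps, cfgc, n_steps, target_box,
                    write_interval = 0)
  state$coords <- out$coords
  state$vel <- out$vel
  state$box <- out$box
  if (isTRUE(out$diverged)) stop("simulation diverged during compression")
  maxwell_velocities(state, ps, cfg$temperature,
                     derive_seed(cfg$seed, 104729L))
}

#' Run a slab production simulation
#'
#' Langevin (BAOAB) dynamics at constant volume and temperature.
#' Frames and the per-frame energy decomposition are recorded every
#' `write_interval` steps (the state at step 0 is not a frame), so
#' `n_steps / write_interval` frames result; the production protocol
#' (1e7 steps, interval 1e4, dt 0.01 ps) yields a 1,000-frame, 100 ns
#' trajectory with frames 100 ps apart. Runs are reproducible: the
#' same seed and configuration give bit-identical trajectories on one
#' platform.
#'
#' @param state a `system_state` (velocities drawn at `cfg$temperature`
#'   from `cfg$seed` if absent).
#' @param ps an `hps_params`.
#' @param cfg an `engine_config`.
#' @param n_steps,write_interval override the configured values.
#' @return an `hps_trajectory`: `$frames` (beads x 3 x frames),
#'   `$energies` (per-frame `e_bond`, `e_hydropathy`, `e_elec`,
#'   `e_kinetic`, `e_hps`), `$system` (final state), box and provenance
#'   metadata. On divergence an error of class `hps_divergence` is
#'   raised carrying the partial trajectory.
#' @export
run_simulation <- function(state, ps, cfg, n_steps = cfg$n_steps,
                           write_interval = cfg$write_interval) {
  if (is.null(state$vel))
    state <- maxwell_velocities(state, ps, cfg$temperature, cfg$seed)
  out <- run_engine(state, ps, cfg, n_steps, state$box, write_interval)
  traj_from_run(out, state, cfg, write_interval)
}

#' Single Langevin step
#'
#' One BAOAB update of positions and velocities (forces recomputed
#' internally), mainly useful for stepwise inspection.
#'
#' @inheritParams run_simulation
#' @return the updated `system_state`.
#' @export
langevin_step <- function(state, ps, cfg) {
  if (is.null(state$vel))
    state <- maxwell_velocities(state, ps, cfg$temperature, cfg$seed)
  out <- run_engine(state, ps, cfg, 1L, state$box, 0L)
  state$coords <- out$coords
  state$vel <- out$vel
  state
}

#' Molar chain concentration of a box
#'
#' `c = n / (V N_A)` with the box volume in litres. The production
#' slab (120 chains in 180 x 180 x 1800 A) corresponds to 3.4 mM.
#'
#' @param n_chains number of chains.
#' @param box length-3 box, Angstrom.
#' @return concentration in mol/L.
#' @export
concentration <- function(n_chains, box) {
  v_l <- prod(as.numeric(box)) * 1e-27
  if (v_l <= 0) stop("box volume must be positive")
  n_chains / (v_l * .avogadro)
}

#' Windowed energy-convergence check
#'
#' Splits the tail of an energy trace into two consecutive windows and
#' declares convergence when the relative change in window means is at
#' most `tol`:
#' `|mean(last) - mean(previous)| <= tol |mean(last)|`.
#'
#' @param trace numeric energy series (e.g. `e_hps` per frame).
#' @param window window length in samples.
#' @param tol relative tolerance.
#' @return logical.
#' @export
check_convergence <- function(trace, window, tol = 0.05) {
  if (length(trace) < 2 * window)
    stop("trace must cover at least two windows")
  last <- mean(tail(trace, window))
  prev <- mean(tail(trace, 2 * window)[seq_len(window)])
  abs(last - prev) <= tol * abs(last)
}
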