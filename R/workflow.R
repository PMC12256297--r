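#' End-to-end slab simulation protocol
#'
#' The standard direct-coexistence workflow in one call: seed a
#' self-avoiding-walk conformation, replicate it into a grid, draw
#' velocities, shrink the box to the slab cell (strongly thermostated,
#' see [compress()]), then run production dynamics. The production
#' protocol replicates 2 x 2 x 30 copies and compresses to
#' 180 x 180 x 1800 Angstrom; reduced systems scale the grid and box
#' down.
#'
#' @param chain a `chain_topology` (one species; assemble mixed
#'   systems manually with [assemble_system()]).
#' @param ps an `hps_params`.
#' @param cfg an `engine_config`; `cfg$seed` drives every random
#'   stage.
#' @param grid integer `c(nx, ny, nz)` replication.
#' @param spacing grid spacing, Angstrom (scalar or per axis); default
#'   is the chain extent plus 10 Angstrom clearance.
#' @param target_box slab box after compression, Angstrom.
#' @param compress_steps box-shrinking steps.
#' @return an `hps_trajectory` (production phase).
#' @export
slab_simulation <- function(chain, ps, cfg, grid = c(2, 2, 30),
                            spacing = NULL,
                            target_box = c(180, 180, 1800),
                            compress_steps = 10000) {
  coords <- random_walk_coords(chain, seed = cfg$seed)
  if (is.null(spacing)) spacing <- max(chain_extent(coords)) + 10
  st <- replicate_grid(chain, coords, grid, spacing)
  st <- maxwell_velocities(st, ps, cfg$temperature, cfg$seed)
  st <- compress(st, ps, cfg, target_box, n_steps = compress_steps)
  run_simulation(st, ps, cfg)
}

#' Reduced PARCL-like slab benchmark system
#'
#' The desk-scale analogue of the production slab: a seeded
#' 150-residue tyrosine-rich disordered chain (8 tyrosines in the
#' N-terminal half, K/R/H basic patch near residue 130), 20 copies on
#' a 2 x 2 x 5 grid compressed into a 100 x 100 x 600 Angstrom slab
#' box (5.5 mM). The default 500,000 production steps at dt 0.01 ps
#' with frames every 10,000 steps give a 5 ns, 50-frame trajectory
#' with the production frame spacing of 100 ps.
#'
#' @param seed master seed for sequence, conformation and dynamics.
#' @param n_steps production steps.
#' @param ps an `hps_params`.
#' @param ... further [engine_config()] overrides.
#' @return an `hps_trajectory`.
#' @export
reduced_slab_run <- function(seed = 1, n_steps = 5e5, ps = load_params(),
                             ...) {
  cfg <- engine_config(n_steps = n_steps, write_interval = 1e4,
                       seed = seed, ...)
  chain <- make_parcl_like(length = 150, n_tyr = 8, patch_center = 130,
                           seed = seed)
  slab_simulation(chain, ps, cfg, grid = c(2, 2, 5),
                  spacing = c(80, 80, 140),
                  target_box = c(100, 100, 600),
                  compress_steps = 10000)
}
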