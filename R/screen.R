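#' Generate combinatorial mutation sets
#'
#' Enumerates subsets of the positions at which `residue` occurs in
#' the wild type, for each requested set size: exhaustively (all
#' `choose(k, s)` subsets) or as `n_random` distinct seeded draws per
#' size. Size 0 yields the single empty set (the wild type).
#'
#' @param wildtype a `chain_topology`.
#' @param residue one-letter code of the target residue (e.g. `"Y"`).
#' @param sizes integer vector of subset sizes.
#' @param sampler `"exhaustive"` or `"random"`.
#' @param n_random draws per size when sampling.
#' @param seed RNG seed for the random sampler.
#' @return list of integer position vectors (sorted, duplicate-free).
#' @export
generate_mutant_sets <- function(wildtype, residue, sizes,
                                 sampler = c("exhaustive", "random"),
                                 n_random = 10, seed = NULL) {
  sampler <- match.arg(sampler)
  stopifnot(inherits(wildtype, "chain_topology"))
  occ <- which(bead_to_letter(wildtype$sequence) == toupper(residue))
  if (!length(occ)) stop("residue ", residue, " absent from wild type")
  sets <- list()
  for (s in sizes) {
    if (s > length(occ))
      stop("set size ", s, " exceeds the ", length(occ),
           " occurrences of ", residue)
    if (s == 0) { sets <- c(sets, list(integer(0))); next }
    if (sampler == "exhaustive") {
      cmb <- utils::combn(occ, s)
      sets <- c(sets, lapply(seq_len(ncol(cmb)), function(k)
        as.integer(cmb[, k])))
    } else {
      new <- with_seed(seed, {
        got <- list(); tries <- 0
        while (length(got) < min(n_random, choose(length(occ), s))) {
          cand <- sort(sample(occ, s))
          key <- paste(cand, collapse = ",")
          if (!key %in% names(got)) got[[key]] <- as.integer(cand)
          tries <- tries + 1
          if (tries > 1000 * n_random) break
        }
        unname(got)
      })
      sets <- c(sets, new)
      if (!is.null(seed)) seed <- seed + 1
    }
  }
  sets
}

#' Derive a per-run seed from a master seed
#'
#' Counter-based splitting: mixes the master seed with the run index
#' through an integer hash and reduces below 2^31, so independent runs
#' get decorrelated, reproducible streams.
#'
#' @param master integer master seed.
#' @param index run counter (1-based).
#' @return integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(master, index) {
  x <- (as.numeric(master) * 2654435761 + as.numeric(index) * 40503) %%
    2147483647
  as.integer(x) + 1L
}

#' Run a mutation screen
#'
#' For each mutation set: substitutes `to` for `from` at the given
#' positions, builds a reduced slab system (grid replication of a
#' self-avoiding-walk conformation, box compression, production run)
#' and summarizes the run by its mean HPS interaction energy over the
#' tail window. Each run draws its own seed from the master seed via
#' [derive_seed()]; divergent runs are recorded with `NA` energy
#' rather than aborting the screen.
#'
#' @param wildtype a `chain_topology`.
#' @param sets list of position vectors (see
#'   [generate_mutant_sets()]).
#' @param ps an `hps_params`.
#' @param cfg an `engine_config`; `cfg$seed` is the master seed and
#'   `cfg$n_steps` / `cfg$write_interval` set the per-run length.
#' @param from,to substitution, one-letter codes (default Y -> E, the
#'   tyrosine screen).
#' @param grid,spacing,target_box system geometry per run.
#' @param compress_steps box-compression steps before production.
#' @param window frame window for [mean_hps_energy()] (default final
#'   half).
#' @return a `screen_result` data.frame: `mutant`, `n_mut`,
#'   `positions`, `mean_ehps`, `sd_ehps`, `seed`, `config_hash`.
#' @export
run_screen <- function(wildtype, sets, ps, cfg, from = "Y", to = "E",
                       grid = c(2, 2, 5), spacing = c(60, 60, 120),
                       target_box = NULL, compress_steps = 2000,
                       window = NULL) {
  stopifnot(inherits(wildtype, "chain_topology"))
  if (is.null(target_box)) target_box <- as.integer(grid) * rep_len(spacing, 3)
  cfg_hash <- config_hash(cfg)
  rows <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    pos <- sets[[k]]
    seed_k <- derive_seed(cfg$seed, k)
    cfg_k <- cfg
    cfg_k$seed <- seed_k
    mut <- if (length(pos))
      apply_mutations(wildtype, pos, from, to) else wildtype
    res <- tryCatch({
      coords <- random_walk_coords(mut, seed = seed_k)
      st <- replicate_grid(mut, coords, grid, spacing)
      st <- maxwell_velocities(st, ps, cfg$temperature, seed_k)
      st <- compress(st, ps, cfg_k, target_box, n_steps = compress_steps)
      traj <- run_simulation(st, ps, cfg_k)
      wnd <- if (is.null(window)) NULL else window
      eh <- mean_hps_energy(traj$energies, wnd)
      c(eh$mean, eh$sd)
    }, hps_divergence = function(e) c(NA_real_, NA_real_),
       error = function(e) {
         if (inherits(e, "hps_divergence")) c(NA_real_, NA_real_) else stop(e)
       })
    rows[[k]] <- data.frame(
      mutant = if (length(pos)) paste0(from, paste(pos, collapse = "+"),
                                       to) else "WT",
      n_mut = length(pos),
      positions = paste(pos, collapse = ","),
      mean_ehps = res[1], sd_ehps = res[2],
      seed = seed_k, config_hash = cfg_hash,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    out <- data.frame(mutant = character(0), n_mut = integer(0),
                      positions = character(0), mean_ehps = numeric(0),
                      sd_ehps = numeric(0), seed = integer(0),
                      config_hash = character(0))
  else out <- do.call(rbind, rows)
  class(out) <- c("screen_result", "data.frame")
  out
}

# short deterministic hash of the configuration for rerun provenance
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    collapse = ";")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Rank screened mutants by LLPS disruption
#'
#' Sorts screen results by mean HPS energy, descending: energies
#' closer to zero mean weaker condensation, so the most disruptive
#' mutant ranks first. Ties break toward fewer mutations, then
#' lexicographically by positions. `NA` energies (divergent runs) sink
#' to the bottom.
#'
#' @param results a `screen_result` data.frame.
#' @return the same rows, ordered, with a `rank` column.
#' @export
rank_mutants <- function(results) {
  if (nrow(results) < 1) stop("no screen results to rank")
  ord <- order(-xtfrm(results$mean_ehps), results$n_mut,
               results$positions, na.last = TRUE)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
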