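# shared fixtures: all built in code, seeded

default_ps <- load_params()

# a small two-chain protein system in a roomy box (cutoffs < L/2)
small_system <- function(n_res = 40, n_chains = 2, seed = 1,
                         box_spacing = 80,
                         n_tyr = if (n_res >= 40) 3 else 2) {
  ch <- make_parcl_like(length = n_res, n_tyr = n_tyr, min_spacing = 4,
                        patch_center = round(0.85 * n_res),
                        patch_length = max(4, round(n_res / 8)),
                        seed = seed)
  co <- random_walk_coords(ch, seed = seed)
  replicate_grid(ch, co, c(n_chains, 1, 1), box_spacing)
}

# random unstructured configuration: n beads of random types thrown
# uniformly into a box, each bead its own chain unless chain_len given
random_system <- function(n = 50, box = c(80, 80, 80), seed = 1,
                          chain_len = 1, ps = default_ps,
                          protein_only = TRUE) {
  hpslab:::with_seed(seed, {
    codes <- ps$table$name
    if (protein_only) codes <- setdiff(codes, c("rA", "rC", "rG", "rU"))
    n <- as.integer(n / chain_len) * chain_len
    topo <- lapply(seq_len(n / chain_len), function(k) {
      ch <- raw_chain(sample(codes, chain_len, replace = TRUE))
      ch$chain_id <- k
      ch
    })
    coords <- matrix(runif(3 * n), ncol = 3) %*% diag(box)
    st <- hpslab:::new_system_state(topo, coords, box,
                                    rep("protein", length(topo)))
    st
  })
}

# a chain_topology over arbitrary bead codes (incl. mixed aa/rna)
raw_chain <- function(beads, molecule_class = "protein") {
  n <- length(beads)
  structure(list(chain_id = 1L, molecule_class = molecule_class,
                 sequence = beads, length = n,
                 bonds = if (n > 1) cbind(seq_len(n - 1), 2:n)
                         else matrix(integer(0), 0, 2),
                 disorder = rep(TRUE, n)), class = "chain_topology")
}

# quick engine config for tests
test_config <- function(n_steps = 1000, write_interval = 100,
                        seed = 99, ...) {
  engine_config(n_steps = n_steps, write_interval = write_interval,
                seed = seed, cutoff_ah = 20, cutoff_dh = 35, ...)
}

# build a toy contact_map object directly from hand-placed frames
toy_contact_map <- function(frame_pairs, n_beads, meta,
                            frame_interval = 100) {
  structure(list(
    frames = lapply(frame_pairs, function(m)
      matrix(as.integer(m), ncol = 2,
             dimnames = list(NULL, c("i", "j")))),
    n_frames = length(frame_pairs),
    frame_ids = seq_along(frame_pairs),
    meta = meta, frame_interval = frame_interval, n_beads = n_beads),
    class = "contact_map")
}
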