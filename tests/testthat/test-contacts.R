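# place single-bead chains at given coordinates to control contacts
point_system <- function(coords, types, box = c(100, 100, 100),
                         chain = seq_len(nrow(coords))) {
  topo <- list()
  for (cid in unique(chain)) {
    b <- types[chain == cid]
    topo[[length(topo) + 1]] <- build_chain(paste(b, collapse = ""),
                                            "protein",
                                            chain_id = length(topo) + 1)
  }
  # renumber chains contiguously as given
  st <- hpslab:::new_system_state(topo, coords, box,
                                  rep("protein", length(topo)))
  st
}

test_that("contact criterion is strict and excludes intra-chain pairs", {
  ps <- load_params()
  rG <- ps$table["G", "radius"]
  d <- 2 * rG
  # exactly at the radius sum: no contact; just inside: contact
  st <- point_system(matrix(c(10, 10, 10, 10 + d, 10, 10), 2, 3,
                            byrow = TRUE), c("G", "G"))
  expect_equal(nrow(find_contacts(st, ps)), 0)
  st$coords[2, 1] <- 10 + d - 1e-9
  expect_equal(nrow(find_contacts(st, ps)), 1)
  # bonded neighbours and any same-chain pair are never reported
  ch <- build_chain("GGGG", "protein")
  co <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0, 11.4, 0, 0), 4, 3,
               byrow = TRUE)
  st1 <- replicate_grid(ch, co, c(1, 1, 1), 100)
  expect_equal(nrow(find_contacts(st1, ps)), 0)
})

test_that("contacts respect the minimum image across the boundary", {
  ps <- load_params()
  rY <- ps$table["Y", "radius"]
  st <- point_system(matrix(c(0.5, 50, 50, 99.5, 50, 50), 2, 3,
                            byrow = TRUE), c("Y", "Y"))
  ct <- find_contacts(st, ps)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$dist, 1.0, tolerance = 1e-12)
  expect_lt(ct$dist, 2 * rY)
})

test_that("contact sets match the all-pairs oracle on random frames", {
  cfg <- test_config()
  for (seed in c(3, 17, 202)) {
    st <- random_system(n = 200, box = c(60, 60, 120), seed = seed,
                        chain_len = 20)
    eng <- find_contacts(st, default_ps)
    ora <- brute_force_oracle(st, default_ps, cfg)$contacts
    key <- function(df) sort(paste(pmin(df$i, df$j), pmax(df$i, df$j)))
    expect_identical(key(eng), key(ora))
  }
})

test_that("residue profile matches hand-enumerated toy counts", {
  ps <- load_params()
  rG <- ps$table["G", "radius"]
  # two 3-residue chains; frame 1: chain1 res2 touches chain2 res1;
  # frame 2: no contacts (chains pulled apart)
  ch <- build_chain("GGG", "protein")
  near <- 2 * rG - 0.5
  f1 <- rbind(c(10, 10, 10), c(14, 10, 10), c(18, 10, 10),
              c(14, 10 + near, 10), c(18 + 4, 10 + near + 20, 10),
              c(22 + 4, 10 + near + 20, 10))
  f2 <- f1; f2[4:6, 2] <- f2[4:6, 2] + 40
  topo <- list(ch, ch)
  st <- hpslab:::new_system_state(topo, f1, c(100, 100, 100),
                                  c("protein", "protein"))
  traj <- structure(list(
    frames = array(c(f1, f2), c(6, 3, 2)),
    boxes = matrix(100, 2, 3), n_frames = 2, frame_interval = 100,
    system = st), class = "hps_trajectory")
  cmap <- contact_map(traj, ps)
  prof <- residue_profile(cmap)
  expect_equal(nrow(prof), 3)  # profile length = chain length
  # one contact incidence at position 2 (chain 1) and position 1
  # (chain 2) in frame 1 only => mean 0.5 each
  expect_equal(prof$mean_contacts, c(0.5, 0.5, 0))
  # trajectory with zero contacts: all-zero profile
  traj2 <- traj; traj2$frames <- array(c(f2, f2), c(6, 3, 2))
  expect_equal(residue_profile(contact_map(traj2, ps))$mean_contacts,
               c(0, 0, 0))
})

test_that("profile sums count every contact incidence twice", {
  cfg <- test_config()
  st <- random_system(n = 120, box = c(50, 50, 80), seed = 7,
                      chain_len = 30)
  traj <- structure(list(
    frames = array(st$coords, c(120, 3, 1)),
    boxes = matrix(c(50, 50, 80), 1, 3), n_frames = 1,
    frame_interval = 100, system = st), class = "hps_trajectory")
  cmap <- contact_map(traj, default_ps)
  prof <- residue_profile(cmap)
  total <- sum(vapply(cmap$frames, nrow, integer(1)))
  expect_equal(sum(prof$mean_contacts) * cmap$n_frames, 2 * total)
})

test_that("transience follows the pooled make/break definition", {
  meta <- list(chain = c(1, 1, 2, 2), pos = c(1, 2, 1, 2),
               type = rep("G", 4), chain_class = c("protein", "protein"),
               n_per = c(2L, 2L))
  # frames {A}, {B}, {B} with A = (1,3), B = (2,4):
  # transition 1: broken 1/1; transition 2: broken 0/1 => pooled 50%
  cmap <- toy_contact_map(list(rbind(c(1, 3)), rbind(c(2, 4)),
                               rbind(c(2, 4))), 4, meta)
  expect_equal(transience_fraction(cmap), 50)
  # identical consecutive frames: 0%
  cmap2 <- toy_contact_map(list(rbind(c(1, 3)), rbind(c(1, 3))), 4, meta)
  expect_equal(transience_fraction(cmap2), 0)
  cmap3 <- toy_contact_map(list(rbind(c(1, 3))), 4, meta)
  expect_error(transience_fraction(cmap3), "2 frames")
})

test_that("contact network threshold is inclusive at the boundary", {
  counts <- data.frame(pos_i = c(3, 3, 5), pos_j = c(7, 9, 8),
                       count = c(400, 100, 350))
  net <- contact_network(counts, min_count = 350, frame_count = 1000)
  expect_equal(nrow(net), 2)           # 350 kept ("at least"), 100 out
  expect_true(all(net$count >= 350))
  net349 <- contact_network(data.frame(pos_i = 1, pos_j = 2, count = 349),
                            min_count = 350, frame_count = 1000)
  expect_equal(nrow(net349), 0)        # 349 at threshold 350: excluded
  # min_count 1 keeps every observed pair
  expect_equal(nrow(contact_network(counts, 1, 1000)), 3)
  expect_warning(contact_network(counts, 1001, 1000), "empty")
})

test_that("pair counting aggregates copies once per frame by default", {
  meta <- list(chain = c(1, 1, 2, 2, 3, 3), pos = rep(c(1, 2), 3),
               type = rep("G", 6),
               chain_class = rep("protein", 3), n_per = rep(2L, 3))
  # frame: copies (1,2) and (2,3) both realize position pair (1,2):
  # chain1 pos1 - chain2 pos2, chain2 pos1 - chain3 pos2
  fr <- rbind(c(1, 4), c(3, 6))
  cmap <- toy_contact_map(list(fr, fr), 6, meta)
  pc_frame <- pair_counts(cmap, mode = "frame")
  expect_equal(pc_frame$count, 2)        # once per frame, two frames
  pc_inc <- pair_counts(cmap, mode = "incidence")
  expect_equal(pc_inc$count, 4)          # two copy pairs, two frames
})

test_that("group contact matrices match hand counts and conservation", {
  ps <- load_params()
  rG <- ps$table["G", "radius"]
  rA <- ps$table["rA", "radius"]
  # 2 protein chains (2 res) + 1 RNA chain (2 nt)
  prot <- build_chain("GG", "protein")
  rna <- build_chain("AA", "rna")
  topo <- list(prot, prot, rna)
  co <- rbind(c(10, 10, 10), c(14, 10, 10),          # protein 1
              c(10, 13, 10), c(14, 13, 10),          # protein 2 (close)
              c(10, 4, 10), c(15, 40, 40))           # rna nt1 near p1r1
  st <- hpslab:::new_system_state(topo, co, c(80, 80, 80),
                                  c("protein", "protein", "rna"))
  traj <- structure(list(frames = array(co, c(6, 3, 1)),
                         boxes = matrix(80, 1, 3), n_frames = 1,
                         frame_interval = 100, system = st),
                    class = "hps_trajectory")
  cmap <- contact_map(traj, ps)
  # hand enumeration: 2rG = 4.86, rG + rA = 6.65
  # p1r1-p2r1 = 3: contact; p1r2-p2r2 = 3: contact
  # p1r1-p2r2 = 5: no; p1r2-p2r1 = 5: no
  # p1r1-rna1 = 6.0: contact; every other RNA distance > 7
  pp <- group_contact_matrix(cmap, 1:2, 1:2)
  expect_equal(pp$total, 2)
  expect_equal(pp$matrix, matrix(c(1, 0, 0, 1), 2))
  pr <- group_contact_matrix(cmap, 1:2, 3)
  expect_equal(pr$total, 1)
  expect_equal(pr$matrix, matrix(c(1, 0, 0, 0), 2))
  # scalar decomposition: group totals partition all contacts
  cs <- contact_summary(cmap)
  expect_equal(sum(cs$contacts_per_frame),
               sum(vapply(cmap$frames, nrow, integer(1))) / cmap$n_frames)
  expect_equal(cs$contacts_per_frame[cs$class_a == "protein" &
                                       cs$class_b == "protein"], 2)
  expect_equal(cs$contacts_per_frame[cs$class_a == "protein" &
                                       cs$class_b == "rna"], 1)
  expect_equal(cs$contacts_per_frame[cs$class_a == "rna" &
                                       cs$class_b == "rna"], 0)
  expect_error(group_contact_matrix(cmap, integer(0), 1:2), "empty")
  expect_error(group_contact_matrix(cmap, 1:2, 2:3), "disjoint")
})

test_that("contact statistics are invariant under rigid translation", {
  st <- random_system(n = 100, box = c(60, 60, 60), seed = 12,
                      chain_len = 25)
  f1 <- st$coords
  st2 <- translate_state(st, c(17, -23, 41))
  traj <- function(s) structure(list(
    frames = array(s$coords, c(100, 3, 1)), boxes = matrix(60, 1, 3),
    n_frames = 1, frame_interval = 100, system = s),
    class = "hps_trajectory")
  p1 <- residue_profile(contact_map(traj(st), default_ps))
  p2 <- residue_profile(contact_map(traj(st2), default_ps))
  expect_equal(p1$mean_contacts, p2$mean_contacts)
})
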