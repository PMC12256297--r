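# helper: wrap raw coordinates into a minimal trajectory object
coords_traj <- function(frames_list, box) {
  n <- nrow(frames_list[[1]])
  structure(list(
    frames = array(unlist(frames_list), c(n, 3, length(frames_list))),
    boxes = matrix(box, length(frames_list), 3, byrow = TRUE),
    n_frames = length(frames_list), frame_interval = 100,
    system = NULL), class = "hps_trajectory")
}

test_that("density profiles conserve bead counts exactly", {
  set.seed(5)
  box <- c(50, 50, 200)
  frames <- lapply(1:3, function(k)
    cbind(runif(400) * 50, runif(400) * 50, runif(400) * 200))
  prof <- density_profile(coords_traj(frames, box), window = 1:3)
  expect_equal(attr(prof, "bin_width"), 1)
  expect_equal(nrow(prof), 200)
  expect_equal(sum(prof$density), 400, tolerance = 1e-12)
  # roughly flat: no slice wildly above the mean
  expect_lt(max(prof$density), 5 * mean(prof$density) + 5)
})

test_that("a delta configuration lands in a single slice", {
  box <- c(20, 20, 100)
  co <- cbind(runif(50) * 20, runif(50) * 20, rep(30.4, 50))
  prof <- density_profile(coords_traj(list(co), box), window = 1,
                          recenter = FALSE)
  expect_equal(sum(prof$density > 0), 1)
  expect_equal(max(prof$density), 50)
  expect_equal(prof$z[which.max(prof$density)], 30.5)
})

test_that("default window is the final half of the trajectory", {
  box <- c(20, 20, 50)
  # frame 1 puts beads at z 10, frames 2-4 at z 40
  mk <- function(z) cbind(rep(10, 20), rep(10, 20), rep(z, 20))
  prof <- density_profile(coords_traj(list(mk(10), mk(40), mk(40),
                                           mk(40)), box),
                          recenter = FALSE)
  expect_equal(attr(prof, "window"), 3:4)
  expect_equal(sum(prof$density), 20)
})

test_that("recentering makes profiles translation invariant", {
  set.seed(9)
  box <- c(30, 30, 120)
  slab <- cbind(runif(300) * 30, runif(300) * 30,
                60 + rnorm(300, sd = 8) %% 120)
  shifted <- slab
  shifted[, 3] <- (slab[, 3] + 47.3) %% 120
  p1 <- density_profile(coords_traj(list(slab), box), window = 1)
  p2 <- density_profile(coords_traj(list(shifted), box), window = 1)
  # identical up to one bin of circular shift
  err <- vapply(-1:1, function(s)
    sum(abs(p1$density - c(tail(p2$density, -s %% 120),
                           head(p2$density, s %% 120)))), numeric(1))
  expect_lt(min(err), 1e-9 + 0.05 * sum(p1$density))
})

test_that("phase concentrations invert constructed top-hat profiles", {
  # plateau d = 12 within +-40 A of centre, background b = 0.3
  dens <- rep(0.3, 400)
  dens[161:240] <- 12
  prof <- hpslab:::as_density_profile(dens)
  pt <- phase_concentrations(prof, dense_halfwidth = 30,
                             dilute_margin = 100, temperature = 300)
  expect_equal(pt$dense, 12)
  expect_equal(pt$dilute, 0.3)
  expect_true(pt$slab_maintained)
  # noisy top-hat: plateau recovered within 2%
  set.seed(11)
  noisy <- dens + abs(rnorm(400, sd = 0.05))
  pt2 <- phase_concentrations(hpslab:::as_density_profile(noisy),
                              dense_halfwidth = 30, dilute_margin = 100)
  expect_equal(pt2$dense, 12, tolerance = 0.02)
  # flat profile: dense == dilute, no slab
  flat <- hpslab:::as_density_profile(rep(2, 400))
  ptf <- phase_concentrations(flat, dense_halfwidth = 30,
                              dilute_margin = 100)
  expect_equal(ptf$dense, ptf$dilute)
  expect_false(ptf$slab_maintained)
  expect_error(phase_concentrations(hpslab:::as_density_profile(
    rep(0, 100)), dilute_margin = 20), "degenerate")
})

test_that("slab maintenance flags contrast, splits and flatness", {
  dens <- rep(0.1, 400); dens[180:220] <- 10
  expect_true(as.vector(slab_maintained(hpslab:::as_density_profile(dens),
                                        dilute_margin = 100)))
  flat <- hpslab:::as_density_profile(rep(1, 300))
  expect_false(as.vector(slab_maintained(flat, dilute_margin = 100)))
  # two separated plateaus: split slab diagnostic
  split <- rep(0.05, 400); split[50:90] <- 8; split[260:300] <- 8
  res <- slab_maintained(hpslab:::as_density_profile(split),
                         dilute_margin = 150)
  expect_false(as.vector(res))
  expect_equal(attr(res, "reason"), "split slab")
  # a slab wrapping the periodic boundary is still contiguous
  wrap <- rep(0.05, 400); wrap[c(1:30, 371:400)] <- 9
  expect_true(as.vector(slab_maintained(hpslab:::as_density_profile(wrap),
                                        dilute_margin = 120)))
})

test_that("phase diagrams order points and flag non-slab temperatures", {
  mk <- function(T, d, b, slab) structure(
    list(temperature = T, dense = d, dilute = b, slab_maintained = slab),
    class = "coexistence_point")
  pd <- phase_diagram(list(mk(320, 8, 0.4, TRUE), mk(300, 10, 0.2, TRUE),
                           mk(340, 2, 1.8, FALSE)))
  expect_equal(pd$temperature, c(300, 320, 340))
  expect_equal(pd$dense, c(10, 8, 2))
  expect_equal(pd$slab_maintained, c(TRUE, TRUE, FALSE))
  expect_true(all(pd$dense[pd$slab_maintained] >=
                    pd$dilute[pd$slab_maintained]))
  # single point and duplicate temperature handling
  expect_equal(nrow(phase_diagram(mk(300, 5, 1, TRUE))), 1)
  expect_error(phase_diagram(list(mk(300, 5, 1, TRUE),
                                  mk(300, 6, 1, TRUE))), "duplicate")
})

test_that("mean HPS energy summarizes inclusive frame windows", {
  en <- data.frame(e_hps = c(-10, -20, -30))
  out <- mean_hps_energy(en, c(1, 3))
  expect_equal(out$mean, -20)
  expect_equal(out$sd, 10)       # closed form sd of {-10,-20,-30}
  expect_equal(out$n, 3)
  const <- data.frame(e_hps = rep(-7.5, 10))
  expect_equal(mean_hps_energy(const, c(3, 8)),
               list(mean = -7.5, sd = 0, n = 6))
  expect_error(mean_hps_energy(en, c(1, 5)), "window")
  # default window: final half
  expect_equal(mean_hps_energy(en)$mean, mean(c(-20, -30)))
})

test_that("slice densities convert to molar concentration", {
  # one bead per slice of a 100 x 100 A cross-section
  ref <- 1 / (100 * 100 * 1 * 1e-27 * 6.02214076e23)
  expect_equal(slice_to_molar(1, c(100, 100)), ref, tolerance = 1e-12)
  expect_equal(slice_to_molar(150, c(180, 180), beads_per_chain = 150),
               1 / (180 * 180 * 1e-27 * 6.02214076e23), tolerance = 1e-12)
})
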