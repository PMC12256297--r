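# circular mean of z positions on a periodic axis of length L
circular_center <- function(z, L) {
  th <- z / L * 2 * pi
  m <- atan2(mean(sin(th)), mean(cos(th)))
  (m %% (2 * pi)) / (2 * pi) * L
}

#' z-density profile of a slab trajectory
#'
#' Bins beads into 1 Angstrom slices along the long (z) axis,
#' recentering each frame so the slab centre -- the circular mean of
#' the bead z coordinates on the periodic axis -- sits at `Lz/2`, then
#' averages over the frame window. Densities are in beads per 1 A
#' slice; summed over slices each frame contributes exactly the bead
#' count.
#'
#' @param traj an `hps_trajectory`.
#' @param window frame indices to average (default: the final half of
#'   the trajectory).
#' @param bin_width slice thickness, Angstrom (1 A convention).
#' @param recenter recentre each frame on its slab before binning?
#' @param beads optional bead subset (e.g. only the RNA beads of a
#'   mixed system).
#' @return a `density_profile`: data.frame `z` (bin centres) and
#'   `density`, with the window, box and per-frame offsets attached.
#' @export
density_profile <- function(traj, window = NULL, bin_width = 1,
                            recenter = TRUE, beads = NULL) {
  stopifnot(inherits(traj, "hps_trajectory"))
  if (traj$n_frames < 1) stop("trajectory has no frames")
  if (is.null(window))
    window <- seq.int(floor(traj$n_frames / 2) + 1, traj$n_frames)
  if (!length(window) || any(window < 1 | window > traj$n_frames))
    stop("window must be a non-empty set of frame indices")
  Lz <- traj$boxes[window[1], 3]
  nbin <- max(1L, round(Lz / bin_width))
  edges <- seq(0, Lz, length.out = nbin + 1)
  dens <- numeric(nbin)
  offsets <- numeric(length(window))
  if (is.null(beads)) beads <- seq_len(dim(traj$frames)[1])
  for (k in seq_along(window)) {
    f <- window[k]
    z <- traj$frames[beads, 3, f]
    allz <- traj$frames[, 3, f]
    if (recenter) {
      ctr <- circular_center(allz, Lz)
      offsets[k] <- Lz / 2 - ctr
      z <- (z + offsets[k]) %% Lz
    }
    idx <- pmin(pmax(floor(z / bin_width), 0), nbin - 1) + 1
    dens <- dens + tabulate(idx, nbins = nbin)
  }
  out <- data.frame(z = (edges[-1] + edges[-(nbin + 1)]) / 2,
                    density = dens / length(window))
  structure(out, class = c("density_profile", "data.frame"),
            window = window, box_z = Lz, bin_width = bin_width,
            offsets = offsets, n_beads_binned = length(beads))
}

# construct a density_profile from raw bins (used by tests and by the
# constructed-profile analyses)
as_density_profile <- function(density, bin_width = 1) {
  n <- length(density)
  structure(data.frame(z = (seq_len(n) - 0.5) * bin_width,
                       density = as.numeric(density)),
            class = c("density_profile", "data.frame"),
            window = NA, box_z = n * bin_width, bin_width = bin_width,
            offsets = numeric(0), n_beads_binned = NA)
}

#' Coexistence concentrations from a density profile
#'
#' The dense-phase density is the mean over a central band around the
#' profile maximum (the slab centre); the dilute-phase density is the
#' mean over the slices beyond a margin on either side. The slab-
#' maintenance flag applies [slab_maintained()].
#'
#' @param profile a `density_profile`.
#' @param dense_halfwidth half-width of the central dense band,
#'   Angstrom.
#' @param dilute_margin distance from the slab centre beyond which
#'   slices count as dilute, Angstrom.
#' @param temperature optional temperature label, K.
#' @param ratio contrast threshold passed to [slab_maintained()].
#' @return a `coexistence_point`: list with `temperature`, `dense`,
#'   `dilute` (beads per slice) and `slab_maintained`.
#' @export
phase_concentrations <- function(profile, dense_halfwidth = 50,
                                 dilute_margin = 300,
                                 temperature = NA_real_, ratio = 10) {
  stopifnot(inherits(profile, "density_profile"))
  if (all(profile$density == 0)) stop("degenerate profile: all zero")
  Lz <- attr(profile, "box_z")
  if (2 * dilute_margin >= Lz)
    stop("dilute margin leaves no dilute band for this box")
  ctr <- profile_center(profile)
  d <- circ_dist(profile$z, ctr, Lz)
  dense_band <- d <= dense_halfwidth
  dilute_band <- d > dilute_margin
  if (!any(dilute_band)) stop("dilute band is empty; reduce dilute_margin")
  structure(list(temperature = temperature,
                 dense = mean(profile$density[dense_band]),
                 dilute = mean(profile$density[dilute_band]),
                 slab_maintained = isTRUE(slab_maintained(profile,
                   ratio = ratio, dense_halfwidth = dense_halfwidth,
                   dilute_margin = dilute_margin))),
            class = "coexistence_point")
}

#' @export
print.coexistence_point <- function(x, ...) {
  cat(sprintf(
    "coexistence_point: T %.4g K, dense %.4g, dilute %.4g beads/slice, slab %s\n",
    x$temperature, x$dense, x$dilute,
    if (x$slab_maintained) "maintained" else "NOT maintained"))
  invisible(x)
}

circ_dist <- function(z, ctr, L) {
  d <- abs(z - ctr)
  pmin(d, L - d)
}

# density-weighted circular centre of a profile; robust against
# flat-topped slabs where the maximum bin sits at a plateau edge
profile_center <- function(profile) {
  L <- attr(profile, "box_z")
  th <- profile$z / L * 2 * pi
  m <- atan2(sum(profile$density * sin(th)),
             sum(profile$density * cos(th)))
  (m %% (2 * pi)) / (2 * pi) * L
}

#' Does the profile show a maintained slab?
#'
#' True when (i) the dense/dilute contrast reaches `ratio` and (ii)
#' the dense region -- the slices above half the peak density -- forms
#' one contiguous band on the periodic axis. Profiles whose
#' high-density slices split into two separated bands (slabs split
#' into droplets) fail with a `"split slab"` diagnostic attribute.
#'
#' @param profile a `density_profile`.
#' @param ratio minimum dense/dilute contrast.
#' @param dense_halfwidth,dilute_margin band geometry as in
#'   [phase_concentrations()].
#' @return logical with attribute `reason` when false.
#' @export
slab_maintained <- function(profile, ratio = 10, dense_halfwidth = 50,
                            dilute_margin = 300) {
  stopifnot(inherits(profile, "density_profile"))
  Lz <- attr(profile, "box_z")
  if (max(profile$density) <= 0)
    return(structure(FALSE, reason = "no dense phase"))
  # contiguity first: slabs split into droplets are flagged as such
  # (above-half-max slices must form one band on the circular axis)
  hi <- profile$density > max(profile$density) / 2
  runs <- rle(hi)
  nblocks <- sum(runs$values)
  if (nblocks > 1 && runs$values[1] && runs$values[length(runs$values)])
    nblocks <- nblocks - 1  # wraps around the periodic boundary
  if (nblocks > 1) return(structure(FALSE, reason = "split slab"))
  ctr <- profile_center(profile)
  d <- circ_dist(profile$z, ctr, Lz)
  dense <- mean(profile$density[d <= dense_halfwidth])
  dil_band <- d > dilute_margin
  dilute <- if (any(dil_band)) mean(profile$density[dil_band]) else 0
  if (dense <= 0) return(structure(FALSE, reason = "no dense phase"))
  if (dilute > 0 && dense / dilute < ratio)
    return(structure(FALSE, reason = "insufficient contrast"))
  TRUE
}

#' Assemble a phase diagram from coexistence points
#'
#' Orders per-temperature dense/dilute coexistence densities into the
#' temperature-concentration diagram. Temperatures where the slab was
#' not maintained are flagged (phase separation deemed not to have
#' occurred) rather than interpolated.
#'
#' @param points list of `coexistence_point` objects, one per
#'   temperature.
#' @return a `phase_diagram` data.frame: `temperature`, `dense`,
#'   `dilute`, `slab_maintained`, ordered by temperature.
#' @export
phase_diagram <- function(points) {
  if (inherits(points, "coexistence_point")) points <- list(points)
  if (!length(points)) stop("need at least one coexistence point")
  tt <- vapply(points, function(p) p$temperature, numeric(1))
  if (anyDuplicated(tt[!is.na(tt)]))
    stop("duplicate temperatures in phase diagram")
  df <- data.frame(temperature = tt,
                   dense = vapply(points, function(p) p$dense, numeric(1)),
                   dilute = vapply(points, function(p) p$dilute, numeric(1)),
                   slab_maintained = vapply(points, function(p)
                     isTRUE(p$slab_maintained), logical(1)))
  df <- df[order(df$temperature), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("phase_diagram", "data.frame")
  df
}

#' Convert beads-per-slice density to molar concentration
#'
#' A slice holds `density` beads in `Lx * Ly * bin_width` Angstrom^3;
#' dividing by residues per chain gives the chain molarity of the
#' phase.
#'
#' @param density beads per slice.
#' @param box_xy cross-section `c(Lx, Ly)`, Angstrom.
#' @param bin_width slice thickness, Angstrom.
#' @param beads_per_chain divide to obtain chain (not bead) molarity.
#' @return concentration, mol/L.
#' @export
slice_to_molar <- function(density, box_xy, bin_width = 1,
                           beads_per_chain = 1) {
  v_l <- box_xy[1] * box_xy[2] * bin_width * 1e-27
  density / beads_per_chain / (v_l * .avogadro)
}

#' Mean HPS interaction energy over a frame window
#'
#' The screening metric of the mutation studies: mean and standard
#' deviation of the per-frame HPS interaction energy (`e_hps`,
#' hydropathy + electrostatics by default) over an inclusive frame
#' window, conventionally the tail of the trajectory. Sustained
#' negative values indicate a condensate; values near zero indicate no
#' phase separation.
#'
#' @param energies data.frame with an `e_hps` column (e.g.
#'   `traj$energies`), one row per frame.
#' @param window inclusive frame-index bounds `c(first, last)`;
#'   default the final half.
#' @return list `mean`, `sd`, `n`.
#' @export
mean_hps_energy <- function(energies, window = NULL) {
  if (inherits(energies, "hps_trajectory")) energies <- energies$energies
  nf <- nrow(energies)
  if (nf < 1) stop("empty energy log")
  if (is.null(window)) window <- c(floor(nf / 2) + 1, nf)
  if (window[1] < 1 || window[2] > nf || window[1] > window[2])
    stop("window outside the energy log")
  e <- energies$e_hps[window[1]:window[2]]
  list(mean = mean(e), sd = if (length(e) > 1) stats::sd(e) else 0,
       n = length(e))
}

#' @export
plot.density_profile <- function(x, ...) {
  plot(x$z, x$density, type = "l", xlab = "z (A)",
       ylab = "density (beads / slice)", ...)
  invisible(x)
}

#' @export
plot.phase_diagram <- function(x, ...) {
  keep <- x$slab_maintained
  rng <- range(c(x$dense, x$dilute))
  plot(x$dense[keep], x$temperature[keep], xlim = rng,
       xlab = "density (beads / slice)", ylab = "temperature (K)",
       type = "b", pch = 16, ...)
  points(x$dilute[keep], x$temperature[keep], type = "b", pch = 1)
  invisible(x)
}
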