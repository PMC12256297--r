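# background composition of generated disordered sequences:
# G/S/Q/N/P-rich with sparse charges, no tyrosine (tyrosines are
# placed explicitly)
.idr_background <- c(G = 0.18, S = 0.18, Q = 0.12, N = 0.12, P = 0.10,
                     A = 0.08, T = 0.06, E = 0.04, D = 0.03, K = 0.03,
                     R = 0.02, L = 0.02, V = 0.02)

#' Generate a PARCL-like disordered sequence
#'
#' Seeded synthetic stand-in for a tyrosine-driven phase-separating
#' IDP: a leading methionine, `n_tyr` well-spaced tyrosines confined
#' to the N-terminal half (the prion-like region), a short K/R/H-rich
#' basic patch toward the C-terminus (the RNA-binding region, padded
#' with serines), a serine-rich stretch between the patch and the
#' terminus (the phospho-site region targeted by serine mutations),
#' and a G/S/Q/N/P-rich low-charge background elsewhere. The same
#' spec and seed always give the same sequence.
#'
#' @param length total residues (default 178).
#' @param n_tyr number of tyrosines, all in the N-terminal half.
#' @param min_spacing minimum separation between tyrosines, residues.
#' @param patch_center centre index of the basic patch (default
#'   `round(0.85 * length)`).
#' @param patch_length patch length, residues.
#' @param patch_basic_frac fraction of patch residues drawn from
#'   K/R/H; the remainder are serines.
#' @param tail_serine_frac serine fraction of the C-terminal stretch
#'   after the patch.
#' @param seed RNG seed.
#' @return a protein `chain_topology`.
#' @export
make_parcl_like <- function(length = 178, n_tyr = 10, min_spacing = 5,
                            patch_center = NULL, patch_length = 12,
                            patch_basic_frac = 0.6,
                            tail_serine_frac = 0.6, seed = 1) {
  if (length < 12) stop("sequence too short for the layout")
  if (is.null(patch_center)) patch_center <- round(0.85 * length)
  half <- floor(length / 2)
  if (n_tyr > 0 && 2 + (n_tyr - 1) * min_spacing > half)
    stop("cannot place ", n_tyr, " tyrosines with spacing ", min_spacing,
         " in the N-terminal half")
  p0 <- patch_center - floor(patch_length / 2)
  p1 <- p0 + patch_length - 1
  if (p0 <= half || p1 > length)
    stop("basic patch does not fit between the N-terminal half and the terminus")
  with_seed(seed, {
    seqv <- sample(names(.idr_background), length, replace = TRUE,
                   prob = .idr_background)
    seqv[1] <- "M"
    if (n_tyr > 0) {
      # rejection-sample spaced tyrosine positions in [2, half]
      repeat {
        pos <- sort(sample(2:half, n_tyr))
        if (n_tyr == 1 || min(diff(pos)) >= min_spacing) break
      }
      seqv[pos] <- "Y"
    }
    patch <- p0:p1
    n_basic <- round(patch_basic_frac * patch_length)
    basics <- sample(c("K", "R", "H"), n_basic, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
    fill <- rep("S", patch_length)
    fill[sample(patch_length, n_basic)] <- basics
    seqv[patch] <- fill
    # serine-rich stretch between the patch and the terminus
    tail_len <- max(10L, round(0.08 * length))
    t0 <- max(p1 + 1, length - tail_len + 1)
    if (t0 <= length) {
      tail_pos <- t0:length
      is_s <- runif(length(tail_pos)) < tail_serine_frac
      seqv[tail_pos[is_s]] <- "S"
    }
    build_chain(seqv, "protein")
  })
}

#' Generate a single-stranded RNA sequence
#'
#' Seeded uniform sequence over A/C/G/U; the default length 21 matches
#' a mature miRNA.
#'
#' @param length nucleotides.
#' @param seed RNG seed.
#' @return an RNA `chain_topology`.
#' @export
make_rna <- function(length = 21, seed = 1) {
  if (length < 1) stop("length must be >= 1")
  with_seed(seed,
    build_chain(sample(c("A", "C", "G", "U"), length, replace = TRUE),
                "rna"))
}

#' All-pairs reference evaluation of the HPS model
#'
#' Independent O(N^2) minimum-image evaluation of every energy term,
#' the analytic forces and the radius-threshold contact set, with no
#' neighbour lists. Used as the test oracle against the cell-list
#' engine; refuses systems above 1,000 beads.
#'
#' @param state a `system_state`.
#' @param ps an `hps_params`.
#' @param cfg an `engine_config`.
#' @return list `e_bond`, `e_hydropathy`, `e_elec`, `e_hps`, `forces`
#'   (n x 3), `contacts` (data.frame `i`, `j`, `dist`).
#' @export
brute_force_oracle <- function(state, ps, cfg) {
  n <- n_beads(state)
  if (n > 1000) stop("brute-force oracle refuses systems above 1,000 beads")
  box <- state$box
  xyz <- sweep(state$coords, 2, box, function(a, b) a %% b)
  sp <- state_params(state, ps)
  sig <- param_lookup(ps, state$types, "sigma")
  lam <- param_lookup(ps, state$types, "lambda")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  r2 <- rowSums(d^2)
  r <- sqrt(r2)
  bonded <- state$chain[i] == state$chain[j] & abs(i - j) == 1
  forces <- matrix(0, n, 3)
  add_force <- function(fr, ii, jj, dd) {
    fv <- dd * fr
    forces <<- forces + rowsum_into(fv, ii, n) - rowsum_into(fv, jj, n)
  }
  # Ashbaugh-Hatch, energy-shifted at the cutoff
  eps <- cfg$eps
  sij <- (sig[i] + sig[j]) / 2
  lij <- (lam[i] + lam[j]) / 2
  nb <- !bonded & r < cfg$cutoff_ah
  e_ah <- 0
  if (any(nb)) {
    s6 <- (sij[nb] / r[nb])^6; s12 <- s6^2
    phi <- 4 * eps * (s12 - s6)
    frlj <- 24 * eps * (2 * s12 - s6) / r2[nb]
    inner <- s6 > 0.5
    sh6 <- (sij[nb] / cfg$cutoff_ah)^6
    shift <- lij[nb] * 4 * eps * (sh6^2 - sh6)
    e <- ifelse(inner, phi + (1 - lij[nb]) * eps, lij[nb] * phi) - shift
    fr <- ifelse(inner, frlj, lij[nb] * frlj)
    e_ah <- sum(e)
    add_force(fr, i[nb], j[nb], d[nb, , drop = FALSE])
  }
  # Debye-Hueckel, energy-shifted at the cutoff
  qq <- .coulomb / cfg$dielectric * sp$charge[i] * sp$charge[j]
  el <- !bonded & qq != 0 & r < cfg$cutoff_dh
  e_dh <- 0
  if (any(el)) {
    ex <- exp(-cfg$kappa * r[el])
    shift <- exp(-cfg$kappa * cfg$cutoff_dh) / cfg$cutoff_dh
    e_dh <- sum(qq[el] * (ex / r[el] - shift))
    fr <- qq[el] * ex * (cfg$kappa * r[el] + 1) / (r2[el] * r[el])
    add_force(fr, i[el], j[el], d[el, , drop = FALSE])
  }
  # harmonic bonds
  bonds <- state_bonds(state, cfg)
  e_bond <- 0
  if (length(bonds$i)) {
    bi <- bonds$i + 1L; bj <- bonds$j + 1L
    db <- xyz[bi, , drop = FALSE] - xyz[bj, , drop = FALSE]
    db <- db - sweep(round(sweep(db, 2, box, "/")), 2, box, "*")
    rb <- sqrt(rowSums(db^2))
    dev <- rb - bonds$r0
    e_bond <- sum(0.5 * cfg$k_bond * dev^2)
    add_force(-cfg$k_bond * dev / rb, bi, bj, db)
  }
  # contact criterion (strict <, inter-chain only)
  rad <- sp$radius
  inter <- state$chain[i] != state$chain[j]
  hit <- inter & r < rad[i] + rad[j]
  contacts <- data.frame(i = i[hit], j = j[hit], dist = r[hit])
  e_hps <- e_ah + if (cfg$ehps_includes_elec) e_dh else 0
  list(e_bond = e_bond, e_hydropathy = e_ah, e_elec = e_dh,
       e_hps = e_hps, forces = forces, contacts = contacts)
}

# scatter-add rows of `v` (m x 3) into an n x 3 matrix at indices `ii`
rowsum_into <- function(v, ii, n) {
  out <- matrix(0, n, 3)
  s <- rowsum(v, ii)
  out[as.integer(rownames(s)), ] <- s
  out
}
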