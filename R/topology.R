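.aa_codes <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
               "P","S","T","W","Y","V")
.rna_codes <- c("A", "C", "G", "U")

# map a sequence string/vector of one-letter codes to bead codes
seq_to_beads <- function(sequence, molecule_class) {
  if (length(sequence) == 1 && nchar(sequence) == 0)
    stop("sequence must be non-empty")
  if (length(sequence) == 1 && nchar(sequence) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(as.character(sequence))
  if (length(sequence) == 0) stop("sequence must be non-empty")
  valid <- if (molecule_class == "protein") .aa_codes else .rna_codes
  bad <- which(!sequence %in% valid)
  if (length(bad))
    stop("invalid ", molecule_class, " residue code '", sequence[bad[1]],
         "' at position ", bad[1])
  if (molecule_class == "rna") paste0("r", sequence) else sequence
}

bead_to_letter <- function(beads) sub("^r", "", beads)

#' Build a coarse-grained chain topology from a sequence
#'
#' One bead per residue (or nucleotide), bonded consecutively. All
#' beads are treated as disordered by default; disorder flags from a
#' predictor can be attached but the engine applies the IDR model to
#' every bead (folded-domain force fields are out of scope).
#'
#' @param sequence character: the sequence as a single string or a
#'   vector of one-letter codes (`ACGU` for RNA).
#' @param molecule_class `"protein"` or `"rna"`.
#' @param disorder optional logical vector, one flag per residue.
#' @param chain_id integer id.
#' @return a `chain_topology`: bead codes (`$sequence`), `$bonds`
#'   (length-1 x 2 matrix of consecutive local indices, 1-based),
#'   `$disorder`, `$molecule_class`, `$chain_id`.
#' @export
build_chain <- function(sequence, molecule_class = c("protein", "rna"),
                        disorder = NULL, chain_id = 1L) {
  molecule_class <- match.arg(molecule_class)
  beads <- seq_to_beads(sequence, molecule_class)
  n <- length(beads)
  if (is.null(disorder)) disorder <- rep(TRUE, n)
  if (length(disorder) != n)
    stop("disorder flags must have one entry per residue")
  bonds <- if (n > 1) cbind(seq_len(n - 1), 2:n) else
    matrix(integer(0), 0, 2)
  structure(list(chain_id = as.integer(chain_id),
                 molecule_class = molecule_class,
                 sequence = beads, length = n, bonds = bonds,
                 disorder = as.logical(disorder)),
            class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf("chain_topology: %s, %d beads, %d bonds\n",
              x$molecule_class, x$length, nrow(x$bonds)))
  cat("  ", paste(bead_to_letter(x$sequence), collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Apply point mutations to a chain
#'
#' Substitutes residues at 1-based positions, verifying the expected
#' wild-type residue at each position first (guarding against
#' off-by-one index conventions). The input topology is not modified.
#'
#' @param chain a `chain_topology`.
#' @param positions integer vector of 1-based residue indices.
#' @param from expected current one-letter code(s), recycled.
#' @param to replacement one-letter code(s), recycled.
#' @return a new `chain_topology` differing only at `positions`.
#' @export
apply_mutations <- function(chain, positions, from, to) {
  stopifnot(inherits(chain, "chain_topology"))
  if (length(positions) == 0) return(chain)
  positions <- as.integer(positions)
  from <- rep_len(toupper(from), length(positions))
  to <- rep_len(toupper(to), length(positions))
  if (anyDuplicated(positions)) stop("duplicate mutation positions")
  out <- which(positions < 1 | positions > chain$length)
  if (length(out))
    stop("mutation index out of range: ", positions[out[1]],
         " (chain length ", chain$length, ")")
  cur <- bead_to_letter(chain$sequence[positions])
  bad <- which(cur != from)
  if (length(bad))
    stop(sprintf("expected %s at position %d but found %s",
                 from[bad[1]], positions[bad[1]], cur[bad[1]]))
  valid <- if (chain$molecule_class == "protein") .aa_codes else .rna_codes
  if (!all(to %in% valid)) stop("invalid replacement code")
  new <- chain
  new$sequence[positions] <-
    if (chain$molecule_class == "rna") paste0("r", to) else to
  new
}

#' Self-avoiding random-walk conformation for a single chain
#'
#' Seeds an initial conformation as a fixed-step random walk whose
#' beads never come closer than `min_dist`, with backtracking when the
#' walk traps itself. Step length defaults to the bond length of the
#' molecule class (3.8 A protein, 5.0 A RNA).
#'
#' @param chain a `chain_topology`.
#' @param step step (bond) length, Angstrom.
#' @param min_dist minimum non-bonded bead separation, Angstrom.
#' @param seed optional RNG seed (caller's RNG state is preserved).
#' @return n x 3 coordinate matrix centred at the origin.
#' @export
random_walk_coords <- function(chain, step = NULL, min_dist = 4.0,
                               seed = NULL) {
  stopifnot(inherits(chain, "chain_topology"))
  if (is.null(step))
    step <- if (chain$molecule_class == "rna") 5.0 else 3.8
  n <- chain$length
  with_seed(seed, {
    xyz <- matrix(0, n, 3)
    i <- 2L
    tries <- integer(n)
    while (i <= n) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- xyz[i - 1L, ] + step * u
      prev <- xyz[seq_len(max(i - 2L, 0L)), , drop = FALSE]
      ok <- nrow(prev) == 0 ||
        min(sqrt(rowSums((prev - matrix(cand, nrow(prev), 3,
                                        byrow = TRUE))^2))) >= min_dist
      if (ok) {
        xyz[i, ] <- cand
        tries[i] <- 0L
        i <- i + 1L
      } else {
        tries[i] <- tries[i] + 1L
        if (tries[i] > 50L) { # trapped: back up one bead
          tries[i] <- 0L
          i <- max(i - 1L, 2L)
        }
      }
    }
    sweep(xyz, 2, colMeans(xyz))
  })
}

# span of a conformation along each axis
chain_extent <- function(coords) apply(coords, 2, function(v) diff(range(v)))

new_system_state <- function(topologies, coords, box, mol_class) {
  n_per <- vapply(topologies, function(tp) tp$length, integer(1))
  chain <- rep(seq_along(topologies), n_per)
  types <- unlist(lapply(topologies, function(tp) tp$sequence),
                  use.names = FALSE)
  structure(list(topologies = topologies, coords = coords, vel = NULL,
                 box = as.numeric(box), chain = chain, types = types,
                 mol_class = mol_class),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("system_state: %d chains (%s), %d beads, box %.5g x %.5g x %.5g A\n",
              n_chains(x), paste(names(table(x$mol_class)),
                                 table(x$mol_class), collapse = ", "),
              n_beads(x), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Number of beads / chains in a system
#' @param state a `system_state`.
#' @export
n_beads <- function(state) nrow(state$coords)

#' @rdname n_beads
#' @export
n_chains <- function(state) length(state$topologies)

#' Replicate a chain into a periodic grid
#'
#' Places identical copies of one conformation on an
#' `nx x ny x nz` lattice (copy `(i,j,k)` translated by
#' `(i,j,k) * spacing`), the initial condition that the compression
#' step then shrinks into the slab box. The production protocol uses a
#' 2 x 2 x 30 grid (120 chains).
#'
#' @param chain a `chain_topology`.
#' @param coords single-chain conformation (n x 3), e.g. from
#'   [random_walk_coords()].
#' @param grid integer vector `c(nx, ny, nz)`.
#' @param spacing lattice spacing, Angstrom (scalar or per-axis); must
#'   exceed the chain extent to avoid initial overlap.
#' @return a `system_state` with box `grid * spacing`.
#' @export
replicate_grid <- function(chain, coords, grid, spacing) {
  stopifnot(inherits(chain, "chain_topology"))
  grid <- as.integer(grid)
  if (length(grid) != 3 || any(grid < 1))
    stop("grid must be three positive integers")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  ext <- chain_extent(coords)
  if (any(ext >= spacing))
    warning(sprintf(
      "chain extent (%.1f A) reaches the grid spacing; initial copies may overlap",
      max(ext)))
  # centre the conformation inside its lattice cell
  cell0 <- sweep(coords, 2, apply(coords, 2, min)) +
    matrix((spacing - ext) / 2, nrow(coords), 3, byrow = TRUE)
  ncopy <- prod(grid)
  offs <- as.matrix(expand.grid(x = seq_len(grid[1]) - 1,
                                y = seq_len(grid[2]) - 1,
                                z = seq_len(grid[3]) - 1))
  topologies <- vector("list", ncopy)
  all <- matrix(0, ncopy * chain$length, 3)
  for (c in seq_len(ncopy)) {
    tp <- chain
    tp$chain_id <- c
    topologies[[c]] <- tp
    rows <- (c - 1) * chain$length + seq_len(chain$length)
    all[rows, ] <- sweep(cell0, 2, offs[c, ] * spacing, "+")
  }
  new_system_state(topologies, all, grid * spacing,
                   rep(chain$molecule_class, ncopy))
}

#' Scatter copies of a chain at random positions in a box
#'
#' Places `n` randomly rotated copies of a conformation at uniform
#' random positions, rejecting placements whose beads fall within
#' `min_clearance` of already placed beads. Used to add a second
#' species (e.g. RNA) to a protein grid.
#'
#' @param chain a `chain_topology`.
#' @param coords single-chain conformation (n x 3).
#' @param n number of copies.
#' @param box box dimensions, Angstrom.
#' @param min_clearance minimum distance to previously placed beads.
#' @param avoid optional coordinate matrix (e.g. an existing system's
#'   beads) that placements must also keep `min_clearance` from.
#' @param seed optional RNG seed.
#' @return a `system_state`.
#' @export
scatter_chains <- function(chain, coords, n, box, min_clearance = 5,
                           avoid = NULL, seed = NULL) {
  stopifnot(inherits(chain, "chain_topology"))
  box <- rep_len(as.numeric(box), 3)
  with_seed(seed, {
    placed <- if (is.null(avoid)) matrix(numeric(0), 0, 3)
              else sweep(as.matrix(avoid), 2, box,
                         function(a, b) a %% b)
    topologies <- vector("list", n)
    cc <- sweep(coords, 2, colMeans(coords))
    for (c in seq_len(n)) {
      for (attempt in seq_len(200)) {
        # random rotation from a normalized quaternion
        q <- rnorm(4); q <- q / sqrt(sum(q^2))
        R <- quat_to_rot(q)
        pos <- runif(3) * box
        cand <- sweep(cc %*% t(R), 2, pos, "+")
        cand <- sweep(cand, 2, box, function(a, b) a %% b)
        if (nrow(placed) == 0 ||
            min_image_mindist(cand, placed, box) >= min_clearance) break
        if (attempt == 200) stop("could not place chain ", c,
                                 " without overlap")
      }
      tp <- chain
      tp$chain_id <- c
      topologies[[c]] <- tp
      placed <- rbind(placed, cand)
    }
    own <- tail(seq_len(nrow(placed)), n * chain$length)
    new_system_state(topologies, placed[own, , drop = FALSE], box,
                     rep(chain$molecule_class, n))
  })
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# minimum over minimum-image distances between two coordinate sets
min_image_mindist <- function(a, b, box) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- sweep(b, 2, a[i, ])
    d <- sweep(d, 2, box, function(x, L) x - L * round(x / L))
    best <- min(best, sqrt(min(rowSums(d^2))))
  }
  best
}

#' Assemble a multi-species system
#'
#' Concatenates the chains of several `system_state` objects (all
#' interpreted in the common `box`), renumbering chain ids globally and
#' preserving per-chain molecule class. Close inter-species bead
#' overlaps produce a warning, not an error.
#'
#' @param species list of `system_state` objects.
#' @param box common box dimensions, Angstrom (default: box of the
#'   first species).
#' @param overlap_tol warn when beads from different input states are
#'   closer than this, Angstrom.
#' @return a merged `system_state`.
#' @export
assemble_system <- function(species, box = NULL, overlap_tol = 2.0) {
  stopifnot(length(species) >= 1,
            all(vapply(species, inherits, logical(1), "system_state")))
  if (is.null(box)) box <- species[[1]]$box
  box <- rep_len(as.numeric(box), 3)
  topologies <- list(); coords <- NULL; mol_class <- character(0)
  for (sp in species) {
    topologies <- c(topologies, sp$topologies)
    coords <- rbind(coords, sp$coords)
    mol_class <- c(mol_class, sp$mol_class)
  }
  for (i in seq_along(topologies)) topologies[[i]]$chain_id <- i
  coords <- sweep(coords, 2, box, function(a, b) a %% b)
  st <- new_system_state(topologies, coords, box, mol_class)
  if (length(species) > 1) {
    off <- 0; group <- integer(0)
    for (k in seq_along(species))
      group <- c(group, rep(k, n_beads(species[[k]])))
    ct <- cpp_find_contacts(coords, box, rep(overlap_tol / 2, nrow(coords)),
                            group)
    if (length(ct$i) > 0)
      warning(length(ct$i), " inter-species bead pair(s) closer than ",
              overlap_tol, " A in the initial placement")
  }
  st
}

#' Rigidly translate a system
#' @param state a `system_state`.
#' @param offset length-3 translation, Angstrom; coordinates re-wrap.
#' @export
translate_state <- function(state, offset) {
  state$coords <- sweep(state$coords, 2, as.numeric(offset), "+")
  state$coords <- sweep(state$coords, 2, state$box,
                        function(a, b) a %% b)
  state
}

# per-bead parameter vectors for a state (errors on missing codes)
state_params <- function(state, ps) {
  list(mass = param_lookup(ps, state$types, "mass"),
       charge = param_lookup(ps, state$types, "charge"),
       radius = param_lookup(ps, state$types, "radius"),
       type0 = match(state$types, ps$table$name) - 1L)
}

# global bond arrays (0-based for the kernels) and per-bond r0
state_bonds <- function(state, cfg) {
  bi <- integer(0); bj <- integer(0); r0 <- numeric(0)
  off <- 0L
  for (k in seq_along(state$topologies)) {
    tp <- state$topologies[[k]]
    if (nrow(tp$bonds) > 0) {
      bi <- c(bi, off + tp$bonds[, 1] - 1L)
      bj <- c(bj, off + tp$bonds[, 2] - 1L)
      r0 <- c(r0, rep(if (tp$molecule_class == "rna") cfg$r0_rna
                      else cfg$r0_protein, nrow(tp$bonds)))
    }
    off <- off + tp$length
  }
  list(i = bi, j = bj, r0 = r0)
}
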