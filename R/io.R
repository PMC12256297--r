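#' Read sequences from a FASTA file
#'
#' @param file FASTA path.
#' @param molecule_class `"protein"` or `"rna"`.
#' @return named list of `chain_topology` objects, one per record.
#' @export
read_fasta <- function(file, molecule_class = c("protein", "rna")) {
  molecule_class <- match.arg(molecule_class)
  set <- Biostrings::readBStringSet(file)
  if (length(set) == 0) stop("no sequences in ", file)
  out <- lapply(seq_along(set), function(k) {
    s <- as.character(set[[k]])
    if (molecule_class == "rna") s <- gsub("T", "U", toupper(s))
    build_chain(s, molecule_class, chain_id = k)
  })
  stats::setNames(out, names(set))
}

#' Write chains to a FASTA file
#' @param chains a `chain_topology` or list of them.
#' @param file output path.
#' @export
write_fasta <- function(chains, file) {
  if (inherits(chains, "chain_topology")) chains <- list(chains)
  seqs <- vapply(chains, function(ch)
    paste(bead_to_letter(ch$sequence), collapse = ""), character(1))
  nm <- names(chains)
  if (is.null(nm)) nm <- paste0("chain_", seq_along(chains))
  set <- Biostrings::BStringSet(stats::setNames(seqs, nm))
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}

#' Read per-residue disorder flags
#'
#' Two-column TSV `index flag` (1-based index, 0/1 or TRUE/FALSE), the
#' consumption format for external disorder-predictor output.
#'
#' @param file TSV path.
#' @param length expected chain length (flags default to TRUE where
#'   the file has no row).
#' @return logical vector of length `length`.
#' @export
read_disorder <- function(file, length) {
  tab <- utils::read.delim(file, comment.char = "#", header = TRUE)
  if (ncol(tab) < 2) stop("disorder file needs columns: index, flag")
  idx <- as.integer(tab[[1]])
  if (any(idx < 1 | idx > length)) stop("disorder index out of range")
  flags <- rep(TRUE, length)
  flags[idx] <- as.logical(as.numeric(tab[[2]]))
  flags
}

#' @rdname read_disorder
#' @param flags logical vector to write.
#' @export
write_disorder <- function(flags, file) {
  utils::write.table(
    data.frame(index = seq_along(flags), flag = as.integer(flags)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a system as a coarse-grained PDB topology
#'
#' One `ATOM` record per bead (atom name `CA`, residue = bead code,
#' chain letters cycling A-Z, residue numbers restarting per chain),
#' the topology companion of a DCD trajectory.
#'
#' @param state a `system_state`.
#' @param file output path.
#' @export
write_pdb <- function(state, file) {
  meta <- bead_meta(state)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
    state$box[1], state$box[2], state$box[3]), con)
  chain_letters <- rep(LETTERS, length.out = length(meta$n_per))
  res3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
            rA = "A", rC = "C", rG = "G", rU = "U")
  lines <- character(n_beads(state))
  for (b in seq_len(n_beads(state))) {
    rn <- res3[state$types[b]]
    if (is.na(rn)) rn <- state$types[b]
    lines[b] <- sprintf(
      "ATOM  %5d  CA  %-4s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      b %% 100000, rn, chain_letters[meta$chain[b]],
      meta$pos[b] %% 10000, state$coords[b, 1], state$coords[b, 2],
      state$coords[b, 3])
  }
  writeLines(lines, con)
  writeLines("END", con)
  invisible(file)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Minimal single-precision DCD writer (CORD format, unit-cell records
#' per frame), readable by standard MD tooling.
#'
#' @param traj an `hps_trajectory`.
#' @param file output path.
#' @export
write_dcd <- function(traj, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  nf <- traj$n_frames
  natom <- dim(traj$frames)[1]
  blk <- function(payload_writer, size) {
    writeBin(as.integer(size), con, size = 4)
    payload_writer()
    writeBin(as.integer(size), con, size = 4)
  }
  # header block: 'CORD' + 20 int control array (icntrl)
  blk(function() {
    writeChar("CORD", con, 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf                      # frames
    icntrl[2] <- as.integer(traj$write_interval)  # first step
    icntrl[3] <- as.integer(traj$write_interval)  # step interval
    icntrl[4] <- as.integer(nf * traj$write_interval)
    icntrl[11] <- 1L                     # unit cell present
    icntrl[20] <- 24L                    # CHARMM version flag
    writeBin(icntrl, con, size = 4)
  }, 84)
  blk(function() {
    writeBin(1L, con, size = 4)
    writeChar(formatC("generated by hpslab", width = -80), con, 80,
              eos = NULL)
  }, 84)
  blk(function() writeBin(as.integer(natom), con, size = 4), 4)
  for (f in seq_len(nf)) {
    b <- traj$boxes[f, ]
    blk(function() writeBin(as.numeric(c(b[1], 90, b[2], 90, 90, b[3])),
                            con, size = 8), 48)
    for (d in 1:3)
      blk(function() writeBin(as.numeric(traj$frames[, d, f]), con,
                              size = 4), 4 * natom)
  }
  invisible(file)
}

#' Read a CHARMM-format DCD file
#'
#' Counterpart of [write_dcd()]; returns the coordinate frames and
#' per-frame unit cells.
#'
#' @param file DCD path.
#' @return list with `frames` (natom x 3 x nframes) and `boxes`
#'   (nframes x 3).
#' @export
read_dcd <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  rdint <- function(n = 1) readBin(con, "integer", n, size = 4)
  expect <- function(sz) {
    got <- rdint()
    if (!identical(got, as.integer(sz)))
      stop("malformed DCD record (", got, " != ", sz, ")")
  }
  expect(84)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (magic != "CORD") stop("not a CORD DCD file")
  icntrl <- rdint(20)
  expect(84)
  sz <- rdint()
  ntitle <- rdint()
  readChar(con, 80 * ntitle, useBytes = TRUE)
  expect(sz)
  expect(4)
  natom <- rdint()
  expect(4)
  nf <- icntrl[1]
  frames <- array(0, c(natom, 3, nf))
  boxes <- matrix(0, nf, 3)
  for (f in seq_len(nf)) {
    expect(48)
    cell <- readBin(con, "numeric", 6, size = 8)
    boxes[f, ] <- cell[c(1, 3, 6)]
    expect(48)
    for (d in 1:3) {
      expect(4 * natom)
      frames[, d, f] <- readBin(con, "numeric", natom, size = 4)
      expect(4 * natom)
    }
  }
  list(frames = frames, boxes = boxes)
}

#' Write the per-frame energy log as TSV
#' @param traj an `hps_trajectory` (or its `$energies`).
#' @param file output path.
#' @export
write_energy_log <- function(traj, file) {
  en <- if (inherits(traj, "hps_trajectory")) traj$energies else traj
  utils::write.table(en[, c("step", "e_bond", "e_hydropathy", "e_elec",
                            "e_kinetic", "e_hps")],
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read / write an engine configuration as YAML
#'
#' Keys mirror the [engine_config()] fields; `kappa` is re-derived on
#' read.
#'
#' @param file YAML path.
#' @export
read_engine_config <- function(file) {
  vals <- yaml::read_yaml(file)
  vals <- vals[setdiff(names(vals), "kappa")]
  keep <- intersect(names(vals), names(formals(engine_config)))
  do.call(engine_config, vals[keep])
}

#' @rdname read_engine_config
#' @param cfg an `engine_config`.
#' @export
write_engine_config <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' Write a density profile or contact outputs as TSV
#' @param x a `density_profile`, [pair_counts()] table or
#'   [residue_profile()] table.
#' @param file output path.
#' @export
write_tsv <- function(x, file) {
  utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
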