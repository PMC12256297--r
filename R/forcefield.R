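#' Load an HPS bead-parameter table
#'
#' Reads a tab-separated force-field table with one row per bead type
#' (columns `name mass charge sigma lambda volume`; `#` comments) and
#' derives the per-bead contact radius `R = (3V / 4 pi)^(1/3)` used by
#' the radius-threshold contact criterion.
#'
#' The packaged table (`file = NULL`) covers the 20 amino acids
#' (one-letter codes) plus the 4 ribonucleotides (`rA`, `rC`, `rG`,
#' `rU`, one bead per nucleotide, charge -1) with an Urry-style
#' hydropathy scale. Alternative hydropathy models can be supplied as
#' files with the same schema.
#'
#' @param file path to a TSV parameter table, or `NULL` for the
#'   packaged Urry-style table.
#' @param eps global pair interaction strength epsilon, kcal/mol.
#' @param his_charge charge assigned to histidine beads (the default 0
#'   is the convention used here; published HPS variants differ).
#' @return an object of class `hps_params`: the parameter table
#'   (`$table`, with derived `radius` column) plus `$eps`.
#' @export
load_params <- function(file = NULL, eps = 0.2, his_charge = 0) {
  if (is.null(file))
    file <- system.file("extdata", "hps_urry.tsv", package = "hpslab")
  if (!file.exists(file)) stop("parameter table not found: ", file)
  tab <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("name", "mass", "charge", "sigma", "lambda", "volume")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("parameter table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(tab) == 0) stop("parameter table is empty")
  if (anyDuplicated(tab$name))
    stop("duplicate bead code(s) in parameter table: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  num <- c("mass", "charge", "sigma", "lambda", "volume")
  for (cl in num) {
    tab[[cl]] <- as.numeric(tab[[cl]])
    if (anyNA(tab[[cl]])) stop("non-numeric values in column '", cl, "'")
  }
  if (any(tab$sigma <= 0)) stop("sigma must be positive for every bead type")
  if (any(tab$volume <= 0)) stop("volume must be positive for every bead type")
  if (any(tab$mass <= 0)) stop("mass must be positive for every bead type")
  if ("H" %in% tab$name && !is.null(his_charge))
    tab$charge[tab$name == "H"] <- his_charge
  tab$radius <- contact_radius(tab$volume)
  rownames(tab) <- tab$name
  structure(list(table = tab, eps = eps), class = "hps_params")
}

#' @export
print.hps_params <- function(x, ...) {
  cat("HPS bead parameters:", nrow(x$table), "bead types, eps =",
      x$eps, "kcal/mol\n")
  print(x$table, digits = 4)
  invisible(x)
}

# bead codes present in a ParamSet
param_codes <- function(ps) ps$table$name

# named lookup of one column, errors on unknown codes
param_lookup <- function(ps, codes, column) {
  idx <- match(codes, ps$table$name)
  if (anyNA(idx))
    stop("unknown bead code(s): ", paste(unique(codes[is.na(idx)]), collapse = ", "))
  ps$table[[column]][idx]
}

#' Write an HPS parameter table
#'
#' Inverse of [load_params()]: writes the six schema columns to TSV so
#' that a write-then-load round trip reproduces the ParamSet.
#'
#' @param ps an `hps_params` object.
#' @param file output path.
#' @export
write_params <- function(ps, file) {
  stopifnot(inherits(ps, "hps_params"))
  cols <- c("name", "mass", "charge", "sigma", "lambda", "volume")
  utils::write.table(ps$table[, cols], file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Contact radius of a residue from its volume
#'
#' Radius of the sphere with the given volume,
#' `R = (3 V / 4 pi)^(1/3)`. Residue-pair contact distances are sums of
#' these radii.
#'
#' @param volume residue volume(s), Angstrom^3; must be positive.
#' @return radius in Angstrom.
#' @export
contact_radius <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volume must be positive and finite")
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Pairwise interaction parameters for two bead types
#'
#' Arithmetic-mean (Lorentz-style) mixing for both the size and the
#' hydropathy: `sigma_ij = (sigma_i + sigma_j)/2`,
#' `lambda_ij = (lambda_i + lambda_j)/2`. The contact distance is the
#' sum of the volume-derived radii, `d_ij = R_i + R_j`.
#'
#' @param a,b bead codes present in `ps`.
#' @param ps an `hps_params` object.
#' @param eps interaction strength override, kcal/mol (defaults to
#'   `ps$eps`).
#' @return list with `sigma`, `lambda`, `eps`, `contact_dist`,
#'   `charge_product`.
#' @export
pair_params <- function(a, b, ps, eps = ps$eps) {
  sa <- param_lookup(ps, a, "sigma"); sb <- param_lookup(ps, b, "sigma")
  la <- param_lookup(ps, a, "lambda"); lb <- param_lookup(ps, b, "lambda")
  ra <- param_lookup(ps, a, "radius"); rb <- param_lookup(ps, b, "radius")
  qa <- param_lookup(ps, a, "charge"); qb <- param_lookup(ps, b, "charge")
  list(sigma = (sa + sb) / 2, lambda = (la + lb) / 2, eps = eps,
       contact_dist = ra + rb, charge_product = qa * qb)
}

#' Inverse Debye screening length
#'
#' Closed form for a 1:1 electrolyte:
#' `kappa = sqrt(8 pi l_B n)` with Bjerrum length
#' `l_B = e^2 / (4 pi eps0 eps_r kB T)` and ion number density `n`
#' from the molar ionic strength. In package units
#' `l_B = 332.0637 / (eps_r kB T)` Angstrom.
#'
#' @param ionic_strength mol/L.
#' @param temperature K.
#' @param dielectric relative permittivity of the implicit solvent.
#' @return kappa in 1/Angstrom.
#' @export
debye_kappa <- function(ionic_strength, temperature = 300, dielectric = 80) {
  if (ionic_strength < 0) stop("ionic strength must be >= 0")
  lB <- .coulomb / (dielectric * .kB * temperature)
  n <- ionic_strength * .avogadro * 1e-27  # ions per A^3 per species
  sqrt(8 * pi * lB * n)
}

#' Engine configuration
#'
#' Collects the run parameters of the Langevin slab engine. The
#' screening constant `kappa` is derived from the ionic strength,
#' temperature and dielectric via [debye_kappa()]. Defaults follow the
#' production protocol: 0.01 ps timestep, 1e7 steps written every 1e4
#' steps (a 1,000-frame, 100 ns trajectory), 300 K, 0.15 M ionic
#' strength.
#'
#' @param dt timestep, ps.
#' @param n_steps number of integration steps.
#' @param write_interval steps between trajectory writes.
#' @param temperature K.
#' @param ionic_strength mol/L.
#' @param dielectric relative permittivity.
#' @param friction Langevin friction gamma, 1/ps.
#' @param k_bond harmonic bond constant, kcal/mol/A^2
#'   (`U = k/2 (r - r0)^2`).
#' @param r0_protein,r0_rna equilibrium bond lengths, Angstrom.
#' @param cutoff_ah,cutoff_dh truncation distances for the
#'   hydropathy (Ashbaugh-Hatch) and electrostatic (Debye-Hueckel)
#'   terms, Angstrom; both energy-shifted to zero at the cutoff.
#' @param eps global pair interaction strength, kcal/mol.
#' @param skin Verlet-list skin, Angstrom.
#' @param ehps_includes_elec should the reported HPS interaction energy
#'   `e_hps` include the electrostatic term (default yes)?
#' @param seed integer seed for the engine's random number stream.
#' @param ps optional `hps_params`; when given, cutoffs shorter than
#'   3 x the largest mixed sigma trigger a warning.
#' @return an `engine_config` list with derived `kappa`.
#' @export
engine_config <- function(dt = 0.01, n_steps = 1e7, write_interval = 1e4,
                          temperature = 300, ionic_strength = 0.15,
                          dielectric = 80, friction = 0.01, k_bond = 10,
                          r0_protein = 3.8, r0_rna = 5.0,
                          cutoff_ah = 20, cutoff_dh = 35, eps = 0.2,
                          skin = 3.0, ehps_includes_elec = TRUE,
                          seed = 1L, ps = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (write_interval < 0) stop("write_interval must be >= 0")
  if (temperature < 0) stop("temperature must be >= 0")
  if (friction < 0) stop("friction must be >= 0")
  if (cutoff_ah <= 0 || cutoff_dh <= 0) stop("cutoffs must be positive")
  if (!is.null(ps)) {
    smax <- max(ps$table$sigma)
    if (min(cutoff_ah, cutoff_dh) < 3 * smax)
      warning(sprintf(
        "cutoff %.1f A is below 3 x max sigma_ij = %.1f A for this parameter set",
        min(cutoff_ah, cutoff_dh), 3 * smax))
  }
  cfg <- list(dt = dt, n_steps = as.numeric(n_steps),
              write_interval = as.numeric(write_interval),
              temperature = temperature, ionic_strength = ionic_strength,
              dielectric = dielectric,
              kappa = debye_kappa(ionic_strength, temperature, dielectric),
              friction = friction, k_bond = k_bond,
              r0_protein = r0_protein, r0_rna = r0_rna,
              cutoff_ah = cutoff_ah, cutoff_dh = cutoff_dh, eps = eps,
              skin = skin, ehps_includes_elec = ehps_includes_elec,
              seed = as.integer(seed))
  class(cfg) <- "engine_config"
  cfg
}

#' @export
print.engine_config <- function(x, ...) {
  cat(sprintf(
    "engine_config: dt %.3g ps, %g steps (write every %g), T %.4g K, I %.3g M\n",
    x$dt, x$n_steps, x$write_interval, x$temperature, x$ionic_strength))
  cat(sprintf("  kappa %.5f 1/A, gamma %.3g 1/ps, cutoffs AH %.4g / DH %.4g A, eps %.3g\n",
              x$kappa, x$friction, x$cutoff_ah, x$cutoff_dh, x$eps))
  invisible(x)
}

# flattened nt x nt pair tables for the compiled kernels: sigma_ij^2,
# lambda_ij and the energy shift that zeroes the AH term at its cutoff
pair_tables <- function(ps, cfg) {
  sig <- ps$table$sigma
  lam <- ps$table$lambda
  nt <- length(sig)
  sij <- outer(sig, sig, function(a, b) (a + b) / 2)
  lij <- outer(lam, lam, function(a, b) (a + b) / 2)
  rc <- cfg$cutoff_ah
  sr6 <- (sij / rc)^6
  shift <- lij * 4 * cfg$eps * (sr6^2 - sr6)  # outer branch value at rc
  list(nt = nt, codes = ps$table$name,
       sig2 = as.numeric(sij^2), lam = as.numeric(lij),
       ahshift = as.numeric(shift),
       coulfac = .coulomb / cfg$dielectric)
}
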