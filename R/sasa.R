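#' Quasi-uniform points on the unit sphere
#'
#' Deterministic golden-spiral (Fibonacci) construction used as the
#' quadrature grid for Shrake-Rupley surface integration.
#'
#' @param n Number of points (>= 1).
#' @return An `n` x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive integer")
  }
  n <- as.integer(n)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = cos(theta) * sin(phi),
        y = sin(theta) * sin(phi),
        z = cos(phi))
}

#' Default van der Waals radii (Angstrom)
#'
#' Chothia-style protein radii keyed by element, used when no explicit
#' per-atom radius is supplied.
#' @return Named numeric vector.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over each atom: each atom is expanded to radius
#' r_vdw + probe, `n_points` quadrature points are placed on that sphere, and
#' the accessible fraction is the share of points not buried inside any
#' neighbouring expanded sphere. Per-atom SASA is the accessible fraction
#' times the expanded-sphere area; per-residue SASA sums over the residue's
#' atoms.
#'
#' @param atoms Atom table (data frame with `x`, `y`, `z`, `element`, and
#'   residue identifiers `chain`, `resno`, `icode`, `resname`).
#' @param probe_radius Probe (solvent) radius in Angstrom; water is 1.4.
#' @param n_points Quadrature points per atom (>= 60).
#' @param radii Named vector of van der Waals radii by element; atoms whose
#'   element is absent raise an error.
#' @return List with `atom_sasa` (numeric, one per atom row) and
#'   `residue_sasa` (data frame `chain`, `resno`, `icode`, `resname`, `sasa`).
#' @export
compute_sasa <- function(atoms, probe_radius = 1.4, n_points = 960,
                         radii = default_vdw_radii()) {
  stopifnot(probe_radius > 0)
  if (n_points < 60) stop("n_points must be at least 60")
  n <- nrow(atoms)
  if (n == 0L) stop("no atoms supplied")
  el <- toupper(atoms$element)
  miss <- setdiff(unique(el), names(radii))
  if (length(miss)) {
    stop(sprintf("no van der Waals radius for element(s): %s",
                 paste(miss, collapse = ", ")))
  }
  r <- unname(radii[el]) + probe_radius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  grid <- sphere_points(n_points)

  # pairwise distances once; neighbour lists from the overlap condition
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  atom_sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2)
    nb <- nb[nb != i]
    pts <- grid * r[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- (pts[free, 1] - xyz[j, 1])^2 + (pts[free, 2] - xyz[j, 2])^2 +
        (pts[free, 3] - xyz[j, 3])^2
      free[free] <- dj >= r[j]^2
    }
    atom_sasa[i] <- sum(free) / n_points * 4 * pi * r[i]^2
  }

  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  key <- factor(key, levels = unique(key))
  res <- atoms[!duplicated(key), c("chain", "resno", "icode", "resname")]
  res$sasa <- as.numeric(tapply(atom_sasa, key, sum))
  rownames(res) <- NULL
  list(atom_sasa = atom_sasa, residue_sasa = res)
}

#' Gly-Xaa-Gly reference accessibilities
#'
#' Theoretical maximum per-residue solvent accessibility of residue X in an
#' extended Gly-X-Gly tripeptide (Tien et al. 2013, theoretical column),
#' the standard denominator for relative/fractional SASA.
#'
#' @return Named numeric vector (Angstrom^2) keyed by 3-letter residue code.
#' @export
gxg_reference_sasa <- function() {
  c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLU = 223.0, GLN = 225.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)
}

#' Fractional solvent-accessible surface area of a chain
#'
#' fSASA = SASA(native) / SASA(reference), where the native value is the
#' whole-residue SASA of the isolated chain (extracted from the complex) and
#' the reference models the denatured state as an extended Gly-Xaa-Gly
#' tripeptide. Values near 1 indicate full exposure; small values indicate
#' burial in the fold.
#'
#' @param model A `pdb_structure`.
#' @param chain_id Chain to analyse (its atoms alone enter the calculation).
#' @param probe_radius,n_points,radii Passed to [compute_sasa()].
#' @param reference Named vector of reference areas per residue type;
#'   defaults to [gxg_reference_sasa()].
#' @return Data frame of class `fsasa_profile` with columns `resno`, `icode`,
#'   `resname`, `sasa_native`, `sasa_reference`, `fsasa`.
#' @export
compute_fsasa <- function(model, chain_id, probe_radius = 1.4, n_points = 960,
                          radii = default_vdw_radii(),
                          reference = gxg_reference_sasa()) {
  at <- chain_atoms(model, chain_id)
  miss <- setdiff(unique(at$resname), names(reference))
  if (length(miss)) {
    stop(sprintf("no reference SASA for residue type(s): %s",
                 paste(miss, collapse = ", ")))
  }
  rs <- compute_sasa(at, probe_radius = probe_radius, n_points = n_points,
                     radii = radii)$residue_sasa
  out <- data.frame(resno = rs$resno, icode = rs$icode, resname = rs$resname,
                    sasa_native = rs$sasa,
                    sasa_reference = unname(reference[rs$resname]),
                    stringsAsFactors = FALSE)
  out$fsasa <- out$sasa_native / out$sasa_reference
  class(out) <- c("fsasa_profile", class(out))
  out
}

#' @export
print.fsasa_profile <- function(x, ...) {
  y <- as.data.frame(x)
  y$sasa_native <- round(y$sasa_native, 1)
  y$fsasa_pct <- round(100 * y$fsasa)  # integer percent, display only
  y$fsasa <- NULL
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write an fSASA profile as TSV
#' @param profile An `fsasa_profile`.
#' @param path Output file path.
#' @export
write_fsasa_profile <- function(profile, path) {
  y <- as.data.frame(profile)
  y <- data.frame(residue_number = y$resno, res_name = y$resname,
                  sasa_A2 = round(y$sasa_native, 2),
                  ref_A2 = y$sasa_reference,
                  fsasa_pct = round(100 * y$fsasa))
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
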