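## Solvent accessibility, burial classification and residue depth.
## SASA uses Shrake-Rupley sphere sampling with a deterministic
## golden-section spiral point set; depth reuses the retained (solvent
## exposed) sample points as a discrete model of the solvent-accessible
## surface and measures the nearest distance from each atom to it.

## van der Waals radii (A) by element; unknown elements fall back to
## carbon.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90,
               P = 1.80, H = 1.20)
VDW_DEFAULT <- 1.70

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

## Maximum per-residue SASA (A^2) in an extended Gly-X-Gly reference
## tripeptide (theoretical values); used as the denominator of relative
## accessibility.  Recorded here so an alternative (empirical) table can
## be swapped in.
MAX_SASA_REF <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0, Q = 225.0,
  E = 223.0, G = 104.0, H = 224.0, I = 197.0, L = 201.0, K = 236.0,
  M = 224.0, F = 240.0, P = 159.0, S = 155.0, T = 172.0, W = 285.0,
  Y = 263.0, V = 174.0
)

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples `n_sphere_points` quasi-uniform points on each atom's solvent
#' sphere (radius = van der Waals radius + probe) and retains those not
#' occluded by any neighbouring atom's solvent sphere.  Computed on the
#' chain in isolation (other chains and ligands do not occlude).
#'
#' @param struct a [chain_structure()].
#' @param probe_radius solvent probe radius, A (default 1.4).
#' @param n_sphere_points sample points per atom.
#' @return List with `atom_area` (A^2 per atom, in atom-table order),
#'   `residue_sasa` (A^2 per residue), and `surface_points` (matrix of
#'   retained sample points, the discrete solvent-accessible surface).
#' @export
compute_sasa <- function(struct, probe_radius = 1.4, n_sphere_points = 480) {
  stopifnot(probe_radius > 0, n_sphere_points >= 12)
  a <- struct$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n_atoms <- nrow(xyz)
  rad <- vdw_radius(a$element) + probe_radius
  pts0 <- sphere_points(n_sphere_points)
  area <- numeric(n_atoms)
  surface <- vector("list", n_atoms)
  d2 <- cross_dist2(xyz, xyz)
  for (i in seq_len(n_atoms)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n_atoms) != i)
    pts <- sweep(pts0 * rad[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      pd2 <- cross_dist2(pts, xyz[nb, , drop = FALSE])
      keep <- rowSums(pd2 < matrix(rad[nb]^2, nrow(pts), length(nb),
                                   byrow = TRUE)) == 0L
    } else {
      keep <- rep(TRUE, nrow(pts))
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(keep) / n_sphere_points
    surface[[i]] <- pts[keep, , drop = FALSE]
  }
  residue_sasa <- as.numeric(tapply(area, a$res_idx, sum))
  list(
    atom_area = area,
    residue_sasa = residue_sasa,
    surface_points = do.call(rbind, surface)
  )
}

#' Classify residue burial from its solvent accessibility
#'
#' Relative accessibility is the residue SASA as a percentage of its
#' maximum reference value in an extended Gly-X-Gly tripeptide; residues
#' strictly below the threshold (default 7%) are buried.
#'
#' @param residue_sasa residue SASA, A^2 (vectorized).
#' @param residue_name one- or three-letter residue code(s).
#' @param threshold_pct burial threshold as a percentage (default 7).
#' @return data.frame with columns `rel_sasa` (%) and `buried`; unknown
#'   residue types get `rel_sasa = NA` and `buried = FALSE`.
#' @export
#' @examples
#' classify_burial(8, "A")        # 6.2% of 129 -> buried
classify_burial <- function(residue_sasa, residue_name, threshold_pct = 7) {
  code <- ifelse(nchar(residue_name) == 3,
                 unname(AA3_TO_1[toupper(residue_name)]),
                 toupper(residue_name))
  ref <- MAX_SASA_REF[code]
  rel <- 100 * residue_sasa / unname(ref)
  buried <- !is.na(rel) & rel < threshold_pct
  data.frame(rel_sasa = unname(rel), buried = buried)
}

#' Residue depth below the solvent-accessible surface
#'
#' The discrete surface is the set of solvent-exposed sample points kept
#' by [compute_sasa()]; each atom's depth is its nearest distance to that
#' set and a residue's depth is the mean over its heavy atoms.  A fully
#' exposed atom therefore has depth ~ (vdW radius + probe).
#'
#' @param struct a [chain_structure()].
#' @param probe_radius solvent probe radius, A.
#' @param sasa optional precomputed result of [compute_sasa()] (reused
#'   for its surface points).
#' @param n_sphere_points sampling density if `sasa` is not supplied.
#' @return Numeric vector of per-residue depths (A).
#' @export
compute_residue_depth <- function(struct, probe_radius = 1.4, sasa = NULL,
                                  n_sphere_points = 480) {
  if (is.null(sasa)) {
    sasa <- compute_sasa(struct, probe_radius, n_sphere_points)
  }
  surf <- sasa$surface_points
  if (is.null(surf) || nrow(surf) == 0L) {
    stop("no exposed surface points; cannot define depth")
  }
  xyz <- as.matrix(struct$atoms[, c("x", "y", "z")])
  atom_depth <- sqrt(pmax(0, apply(cross_dist2(xyz, surf), 1, min)))
  as.numeric(tapply(atom_depth, struct$atoms$res_idx, mean))
}
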