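# Shared geometric primitives: vector algebra, internal-coordinate atom
# placement, van der Waals radii and the soft-sphere overlap kernel used by
# both clash relief and mutation clash scoring.

unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# signed dihedral a-b-c-d in degrees (IUPAC convention)
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# NeRF placement: coordinates of atom D given positions of A, B, C, the bond
# length C-D, the angle B-C-D (degrees) and the torsion A-B-C-D (degrees)
nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), -bond * sin(th) * sin(ph))
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.numeric(m %*% d2 + c)
}

# van der Waals radii (angstrom), Bondi-type values for elements found in
# protein heavy atoms plus common ions; SASA and clash kernels error on
# anything absent from this table
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31, MN = 2.05, "NA" = 2.27, K = 2.75
)

#' Van der Waals radii used by the package
#' @param elements character vector of element symbols.
#' @return numeric vector of radii in angstroms.
#' @export
vdw_radius <- function(elements) {
  el <- toupper(elements)
  unknown <- setdiff(unique(el), names(VDW_RADII))
  if (length(unknown) > 0) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  }
  unname(VDW_RADII[el])
}

# Soft-sphere squared overlap between two atom sets:
#   sum over pairs of max(0, r_i + r_j - d_ij)^2   [angstrom^2]
# Zero exactly when no pair is closer than the sum of vdW radii.
overlap_score_xyz <- function(xyz_a, rad_a, xyz_b, rad_b) {
  if (nrow(xyz_a) == 0 || nrow(xyz_b) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(xyz_a))) {
    dx <- xyz_b[, 1] - xyz_a[i, 1]
    dy <- xyz_b[, 2] - xyz_a[i, 2]
    dz <- xyz_b[, 3] - xyz_a[i, 3]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    pen <- rad_a[i] + rad_b - d
    pen <- pen[pen > 0]
    total <- total + sum(pen^2)
  }
  total
}

# overlap between two chains of a structure (heavy atoms)
chain_overlap_score <- function(structure, chain_a_ids, chain_b_ids) {
  a <- structure$atoms[structure$atoms$chain %in% chain_a_ids, , drop = FALSE]
  b <- structure$atoms[structure$atoms$chain %in% chain_b_ids, , drop = FALSE]
  overlap_score_xyz(as.matrix(a[, c("x", "y", "z")]), vdw_radius(a$elem),
                    as.matrix(b[, c("x", "y", "z")]), vdw_radius(b$elem))
}

# minimum heavy-atom distance from one residue to every atom of a chain
min_dist_residue_to_chain <- function(structure, chain_id, resno, ins = "",
                                      partner_chain_id) {
  a <- structure$atoms
  res <- a[a$chain == chain_id & a$resno == resno & a$ins == ins, , drop = FALSE]
  par <- a[a$chain == partner_chain_id, , drop = FALSE]
  if (nrow(res) == 0 || nrow(par) == 0) return(Inf)
  rx <- as.matrix(res[, c("x", "y", "z")])
  px <- as.matrix(par[, c("x", "y", "z")])
  mind <- Inf
  for (i in seq_len(nrow(rx))) {
    d2 <- (px[, 1] - rx[i, 1])^2 + (px[, 2] - rx[i, 2])^2 +
      (px[, 3] - rx[i, 3])^2
    mind <- min(mind, min(d2))
  }
  sqrt(mind)
}
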