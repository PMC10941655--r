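# Rigid-body superposition (Kabsch) and clash-relieving rigid shifts.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation and translation minimising the RMSD between paired
#' coordinates, by singular value decomposition of the covariance matrix with
#' the usual determinant correction so the result is a proper rotation
#' (det +1, never a reflection).
#'
#' @param mobile,reference n x 3 coordinate matrices, rows paired.
#' @return object of class `sw_superposition`: `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (angstrom, after transform), `n_pairs`.
#'   The transform maps a mobile point x to `rotation %*% x + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3) {
    stop("coordinate matrices must have 3 columns")
  }
  if (nrow(mobile) != nrow(reference)) {
    stop("mobile and reference must have the same number of points")
  }
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 paired points, got ", n)

  cm <- colMeans(mobile); cr <- colMeans(reference)
  x <- sweep(mobile, 2, cm)
  y <- sweep(reference, 2, cr)
  # degenerate (collinear or coincident) point sets leave the rotation
  # under-determined
  if (svd(x)$d[2] < 1e-8 * max(1, svd(x)$d[1])) {
    stop("degenerate point set: points are collinear or coincident")
  }
  h <- crossprod(x, y)               # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(cr - rot %*% cm)
  moved <- t(rot %*% t(mobile)) + matrix(trans, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd,
                 n_pairs = n),
            class = "sw_superposition")
}

#' @export
print.sw_superposition <- function(x, ...) {
  cat(sprintf("<sw_superposition> %d pairs, rmsd %.4f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to a structure or chain
#' @param x an `sw_structure` or `sw_chain`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector.
#' @return object of the same class with transformed coordinates.
#' @export
apply_transform <- function(x, rotation, translation) {
  xyz <- atom_xyz(x)
  moved <- t(rotation %*% t(xyz)) +
    matrix(translation, nrow(xyz), 3, byrow = TRUE)
  x$atoms$x <- moved[, 1]
  x$atoms$y <- moved[, 2]
  x$atoms$z <- moved[, 3]
  x
}

# coordinates of one named atom per residue, indexed by residue order;
# returns matrix with NA rows where the atom is absent
anchor_coords <- function(chain, atom_name) {
  rt <- residue_table(chain)
  a <- chain$atoms[chain$atoms$atom == atom_name, , drop = FALSE]
  key <- paste(a$resno, a$ins, sep = "\r")
  idx <- match(paste(rt$resno, rt$ins, sep = "\r"), key)
  out <- matrix(NA_real_, nrow(rt), 3)
  ok <- !is.na(idx)
  out[ok, ] <- as.matrix(a[idx[ok], c("x", "y", "z")])
  out
}

#' Superpose a chain onto a reference via a sequence alignment
#'
#' Builds anchor-atom pairs (CA by default) from the aligned positions present
#' in both chains, computes the Kabsch transform on those anchors, and applies
#' it to every atom of the mobile chain. CA-only anchoring keeps the fit
#' robust to side-chain differences between a model and its template.
#'
#' @param mobile_chain,ref_chain `sw_chain` objects.
#' @param alignment `sw_alignment` mapping mobile (a) to reference (b)
#'   sequence positions, 1-based over the residues present in each chain.
#' @param atom anchor atom name (default `"CA"`).
#' @return list with `superposition` (`sw_superposition`) and `chain` (the
#'   transformed mobile chain).
#' @export
superpose_by_alignment <- function(mobile_chain, ref_chain, alignment,
                                   atom = "CA") {
  am <- anchor_coords(mobile_chain, atom)
  ar <- anchor_coords(ref_chain, atom)
  pairs <- alignment$aligned_pairs
  keep <- pairs[, 1] <= nrow(am) & pairs[, 2] <= nrow(ar)
  pairs <- pairs[keep, , drop = FALSE]
  ok <- !is.na(am[pairs[, 1], 1]) & !is.na(ar[pairs[, 2], 1])
  if (sum(ok) < 3) {
    stop("only ", sum(ok), " aligned positions have '", atom,
         "' in both chains; need at least 3 (missing at mobile positions: ",
         paste(utils::head(pairs[!ok, 1], 10), collapse = ", "), ")")
  }
  sp <- kabsch_superpose(am[pairs[ok, 1], , drop = FALSE],
                         ar[pairs[ok, 2], , drop = FALSE])
  list(superposition = sp,
       chain = apply_transform(mobile_chain, sp$rotation, sp$translation))
}

#' Relieve inter-chain clashes by a small rigid shift
#'
#' Translates one chain away from the rest of the complex along the axis from
#' the fixed chains' interface centroid toward the movable chain's interface
#' centroid, in fixed increments, until the heavy-atom soft-sphere overlap
#' score drops to the threshold or the shift budget is exhausted. This is the
#' rigid-body "shift the components slightly apart" step of template-based
#' complex assembly; a step is only accepted if it does not increase the
#' overlap score.
#'
#' @param complex an `sw_structure` with at least two chains.
#' @param movable_chain_id chain to shift.
#' @param step shift increment (angstrom).
#' @param max_shift maximum total shift (angstrom).
#' @param overlap_threshold target overlap score (angstrom^2); 0 means no
#'   van der Waals interpenetration at all.
#' @param interface_cutoff distance (angstrom) defining which atoms form the
#'   interface centroids that set the shift direction.
#' @return list with `structure` (shifted complex) and `report` (list:
#'   `shift`, `initial_overlap`, `residual_overlap`, `direction`, `moved`).
#' @export
relieve_clashes <- function(complex, movable_chain_id, step = 0.25,
                            max_shift = 5, overlap_threshold = 0,
                            interface_cutoff = 5) {
  cids <- chain_ids(complex)
  if (!movable_chain_id %in% cids) {
    stop("movable chain '", movable_chain_id, "' not in complex")
  }
  fixed_ids <- setdiff(cids, movable_chain_id)
  if (length(fixed_ids) == 0) stop("complex has no other chain to fix")

  a <- complex$atoms
  mob <- a$chain == movable_chain_id
  xyz_m <- as.matrix(a[mob, c("x", "y", "z")])
  xyz_f <- as.matrix(a[!mob, c("x", "y", "z")])
  rad_m <- vdw_radius(a$elem[mob])
  rad_f <- vdw_radius(a$elem[!mob])

  # interface atoms: within interface_cutoff of the other side
  near_m <- rep(FALSE, nrow(xyz_m)); near_f <- rep(FALSE, nrow(xyz_f))
  cut2 <- interface_cutoff^2
  for (i in seq_len(nrow(xyz_m))) {
    d2 <- (xyz_f[, 1] - xyz_m[i, 1])^2 + (xyz_f[, 2] - xyz_m[i, 2])^2 +
      (xyz_f[, 3] - xyz_m[i, 3])^2
    hit <- d2 <= cut2
    if (any(hit)) { near_m[i] <- TRUE; near_f[hit] <- TRUE }
  }
  report <- list(shift = 0, initial_overlap = NA_real_,
                 residual_overlap = NA_real_, direction = c(NA, NA, NA),
                 moved = FALSE)
  if (!any(near_m)) {
    warning("chains are not in contact (no atoms within ", interface_cutoff,
            " A); structure left unchanged")
    ov <- overlap_score_xyz(xyz_m, rad_m, xyz_f, rad_f)
    report$initial_overlap <- report$residual_overlap <- ov
    return(list(structure = complex, report = report))
  }
  centroid_m <- colMeans(xyz_m[near_m, , drop = FALSE])
  centroid_f <- colMeans(xyz_f[near_f, , drop = FALSE])
  dirv <- centroid_m - centroid_f
  if (sqrt(sum(dirv^2)) < 1e-9) {
    # coincident centroids: fall back to the whole-chain centroid axis
    dirv <- colMeans(xyz_m) - colMeans(xyz_f)
  }
  dirv <- unitv(dirv)

  ov <- overlap_score_xyz(xyz_m, rad_m, xyz_f, rad_f)
  report$initial_overlap <- ov
  shift <- 0
  while (ov > overlap_threshold && shift + step <= max_shift + 1e-9) {
    trial <- sweep(xyz_m, 2, -step * dirv)
    ov_trial <- overlap_score_xyz(trial, rad_m, xyz_f, rad_f)
    if (ov_trial > ov + 1e-12) break   # moving apart must not make it worse
    xyz_m <- trial
    shift <- shift + step
    ov <- ov_trial
  }
  if (shift > 0) {
    complex$atoms[mob, c("x", "y", "z")] <- xyz_m
    report$moved <- TRUE
  }
  report$shift <- shift
  report$residual_overlap <- ov
  report$direction <- dirv
  list(structure = complex, report = report)
}
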