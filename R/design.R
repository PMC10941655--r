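# Mutation design: residue classification, substitution rules, rotamer-based
# side-chain growth, soft-sphere clash scoring against the partner to be
# displaced, surface-exposure checks, grouping of targets and enumeration of
# mutant combinations.

# fixed physicochemical classes; H is 'special' because its charge is
# pH-dependent, G/P for backbone geometry, C for disulphide risk
RESIDUE_CLASSES <- list(
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "Y"),
  positive = c("K", "R"),
  negative = c("D", "E"),
  polar_uncharged = c("S", "T", "N", "Q"),
  special = c("G", "P", "C", "H")
)

# maximum residue SASA (A^2) in an extended Gly-X-Gly tripeptide
# (theoretical values of Tien et al. 2013), used to normalise relative SASA
MAX_SASA_GXG <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174
)

#' Physicochemical class of an amino acid
#'
#' @param aa one-letter code of a standard amino acid.
#' @return one of `"hydrophobic"`, `"positive"`, `"negative"`,
#'   `"polar_uncharged"`, `"special"`.
#' @export
classify_residue <- function(aa) {
  aa <- toupper(aa)
  if (length(aa) != 1 || !aa %in% unlist(RESIDUE_CLASSES)) {
    stop("not a standard amino acid: '", aa, "'")
  }
  for (cls in names(RESIDUE_CLASSES)) {
    if (aa %in% RESIDUE_CLASSES[[cls]]) return(cls)
  }
}

#' Propose a specificity-breaking substitution for one residue
#'
#' Applies the design rules: hydrophobic residues become glutamine (larger
#' and hydrophilic but uncharged, so the newly exposed surface stays
#' soluble); charged residues become the larger residue of the same charge
#' (Lys to Arg, Asp to Glu). Arg and Glu have no larger same-charge standard
#' option and are flagged for manual attention, as are polar-uncharged and
#' special residues, for which the rules make no prescription.
#'
#' @param position author residue number.
#' @param wt_aa wild-type one-letter code.
#' @return one-row data frame: `position`, `wt_aa`, `mutant_aa`, `rule`
#'   (`hydrophobic_to_gln`, `charge_size_up` or `flagged_manual`), `notes`.
#' @export
propose_mutation <- function(position, wt_aa) {
  wt_aa <- toupper(wt_aa)
  cls <- classify_residue(wt_aa)
  mutant <- wt_aa
  rule <- "flagged_manual"
  notes <- ""
  if (cls == "hydrophobic") {
    mutant <- "Q"
    rule <- "hydrophobic_to_gln"
    if (wt_aa %in% c("W", "Y")) {
      notes <- "aromatic wild type: Gln substitution is aggressive"
    }
  } else if (cls == "positive") {
    if (wt_aa == "K") {
      mutant <- "R"; rule <- "charge_size_up"
    } else {
      notes <- "no larger positively charged standard residue than Arg"
    }
  } else if (cls == "negative") {
    if (wt_aa == "D") {
      mutant <- "E"; rule <- "charge_size_up"
    } else {
      notes <- "no larger negatively charged standard residue than Glu"
    }
  } else if (cls == "polar_uncharged") {
    notes <- "polar uncharged wild type: no rule prescribed"
  } else {
    notes <- "special residue (G/P/C/H): no rule prescribed"
  }
  data.frame(position = as.integer(position), wt_aa = wt_aa,
             mutant_aa = mutant, rule = rule, notes = notes,
             stringsAsFactors = FALSE)
}

# side-chain topology beyond CB: each atom is placed by NeRF from three
# previously placed atoms with the given bond length, bond angle and a
# torsion that is either a chi angle (+ offset) or fixed
sc_atom <- function(name, a, b, c, bond, angle, chi = NA, offset = 0,
                    fixed = NA) {
  list(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
       chi = chi, offset = offset, fixed = fixed)
}

SIDECHAIN_TOPO <- list(
  G = list(), A = list(),
  S = list(sc_atom("OG", "N", "CA", "CB", 1.417, 110.8, chi = 1)),
  C = list(sc_atom("SG", "N", "CA", "CB", 1.808, 114.4, chi = 1)),
  T = list(sc_atom("OG1", "N", "CA", "CB", 1.433, 109.6, chi = 1),
           sc_atom("CG2", "N", "CA", "CB", 1.521, 110.5, chi = 1,
                   offset = -120)),
  V = list(sc_atom("CG1", "N", "CA", "CB", 1.527, 110.5, chi = 1),
           sc_atom("CG2", "N", "CA", "CB", 1.527, 110.5, chi = 1,
                   offset = 122)),
  L = list(sc_atom("CG", "N", "CA", "CB", 1.530, 116.3, chi = 1),
           sc_atom("CD1", "CA", "CB", "CG", 1.524, 110.7, chi = 2),
           sc_atom("CD2", "CA", "CB", "CG", 1.524, 110.7, chi = 2,
                   offset = 122)),
  I = list(sc_atom("CG1", "N", "CA", "CB", 1.530, 110.4, chi = 1),
           sc_atom("CG2", "N", "CA", "CB", 1.521, 110.5, chi = 1,
                   offset = -122),
           sc_atom("CD1", "CA", "CB", "CG1", 1.513, 113.8, chi = 2)),
  M = list(sc_atom("CG", "N", "CA", "CB", 1.520, 114.1, chi = 1),
           sc_atom("SD", "CA", "CB", "CG", 1.803, 112.7, chi = 2),
           sc_atom("CE", "CB", "CG", "SD", 1.791, 100.9, chi = 3)),
  F = list(sc_atom("CG", "N", "CA", "CB", 1.500, 113.8, chi = 1),
           sc_atom("CD1", "CA", "CB", "CG", 1.390, 120.8, chi = 2),
           sc_atom("CD2", "CA", "CB", "CG", 1.390, 120.8, chi = 2,
                   offset = 180),
           sc_atom("CE1", "CB", "CG", "CD1", 1.390, 120.3, fixed = 180),
           sc_atom("CE2", "CB", "CG", "CD2", 1.390, 120.3, fixed = 180),
           sc_atom("CZ", "CG", "CD1", "CE1", 1.390, 120.0, fixed = 0)),
  W = list(sc_atom("CG", "N", "CA", "CB", 1.500, 113.6, chi = 1),
           sc_atom("CD1", "CA", "CB", "CG", 1.370, 126.9, chi = 2),
           sc_atom("CD2", "CA", "CB", "CG", 1.430, 126.7, chi = 2,
                   offset = 180),
           sc_atom("NE1", "CB", "CG", "CD1", 1.380, 110.2, fixed = 180),
           sc_atom("CE2", "CB", "CG", "CD2", 1.410, 107.2, fixed = 180),
           sc_atom("CE3", "CB", "CG", "CD2", 1.400, 133.9, fixed = 0),
           sc_atom("CZ2", "CG", "CD2", "CE2", 1.400, 122.4, fixed = 180),
           sc_atom("CZ3", "CG", "CD2", "CE3", 1.390, 118.6, fixed = 180),
           sc_atom("CH2", "CD2", "CE3", "CZ3", 1.370, 121.1, fixed = 0)),
  Y = list(sc_atom("CG", "N", "CA", "CB", 1.500, 113.8, chi = 1),
           sc_atom("CD1", "CA", "CB", "CG", 1.390, 120.8, chi = 2),
           sc_atom("CD2", "CA", "CB", "CG", 1.390, 120.8, chi = 2,
                   offset = 180),
           sc_atom("CE1", "CB", "CG", "CD1", 1.390, 120.3, fixed = 180),
           sc_atom("CE2", "CB", "CG", "CD2", 1.390, 120.3, fixed = 180),
           sc_atom("CZ", "CG", "CD1", "CE1", 1.390, 120.0, fixed = 0),
           sc_atom("OH", "CD1", "CE1", "CZ", 1.380, 119.9, fixed = 180)),
  H = list(sc_atom("CG", "N", "CA", "CB", 1.490, 113.8, chi = 1),
           sc_atom("ND1", "CA", "CB", "CG", 1.380, 122.7, chi = 2),
           sc_atom("CD2", "CA", "CB", "CG", 1.350, 131.2, chi = 2,
                   offset = 180),
           sc_atom("CE1", "CB", "CG", "ND1", 1.320, 109.2, fixed = 180),
           sc_atom("NE2", "CB", "CG", "CD2", 1.370, 107.2, fixed = 180)),
  N = list(sc_atom("CG", "N", "CA", "CB", 1.516, 112.6, chi = 1),
           sc_atom("OD1", "CA", "CB", "CG", 1.231, 120.8, chi = 2),
           sc_atom("ND2", "CA", "CB", "CG", 1.328, 116.4, chi = 2,
                   offset = 180)),
  D = list(sc_atom("CG", "N", "CA", "CB", 1.516, 112.6, chi = 1),
           sc_atom("OD1", "CA", "CB", "CG", 1.249, 118.5, chi = 2),
           sc_atom("OD2", "CA", "CB", "CG", 1.249, 118.5, chi = 2,
                   offset = 180)),
  Q = list(sc_atom("CG", "N", "CA", "CB", 1.520, 114.1, chi = 1),
           sc_atom("CD", "CA", "CB", "CG", 1.516, 112.6, chi = 2),
           sc_atom("OE1", "CB", "CG", "CD", 1.231, 120.8, chi = 3),
           sc_atom("NE2", "CB", "CG", "CD", 1.328, 116.4, chi = 3,
                   offset = 180)),
  E = list(sc_atom("CG", "N", "CA", "CB", 1.520, 114.1, chi = 1),
           sc_atom("CD", "CA", "CB", "CG", 1.516, 112.6, chi = 2),
           sc_atom("OE1", "CB", "CG", "CD", 1.249, 118.5, chi = 3),
           sc_atom("OE2", "CB", "CG", "CD", 1.249, 118.5, chi = 3,
                   offset = 180)),
  K = list(sc_atom("CG", "N", "CA", "CB", 1.520, 114.1, chi = 1),
           sc_atom("CD", "CA", "CB", "CG", 1.520, 111.3, chi = 2),
           sc_atom("CE", "CB", "CG", "CD", 1.520, 111.3, chi = 3),
           sc_atom("NZ", "CG", "CD", "CE", 1.489, 111.7, chi = 4)),
  R = list(sc_atom("CG", "N", "CA", "CB", 1.520, 114.1, chi = 1),
           sc_atom("CD", "CA", "CB", "CG", 1.520, 111.3, chi = 2),
           sc_atom("NE", "CB", "CG", "CD", 1.461, 112.0, chi = 3),
           sc_atom("CZ", "CG", "CD", "NE", 1.329, 124.2, chi = 4),
           sc_atom("NH1", "CD", "NE", "CZ", 1.326, 120.0, fixed = 0),
           sc_atom("NH2", "CD", "NE", "CZ", 1.326, 120.0, fixed = 180)),
  P = list(sc_atom("CG", "N", "CA", "CB", 1.492, 104.5, chi = 1),
           sc_atom("CD", "CA", "CB", "CG", 1.503, 106.1, chi = 2))
)

n_chi <- function(aa) {
  topo <- SIDECHAIN_TOPO[[aa]]
  if (length(topo) == 0) return(0L)
  max(c(0L, vapply(topo, function(x) if (is.na(x$chi)) 0L else as.integer(x$chi),
                   integer(1))))
}

#' Build mutant side-chain rotamers on an existing backbone
#'
#' Places the mutant side chain at ideal bond geometry for each rotamer of a
#' small fixed chi library (every combination of the supplied chi values for
#' chi1..chi3; chi angles beyond the third are held at 180 degrees, capping
#' the library at `length(chi_values)^3` rotamers). The CB is always rebuilt
#' at ideal tetrahedral geometry from N, CA, C. The library is meant for
#' clash coverage, not energy ranking.
#'
#' @param model an `sw_complex_model` or `sw_structure`.
#' @param position author residue number (on `chain_id`).
#' @param mutant_aa one-letter code of the residue to build.
#' @param chain_id chain to build on; defaults to the model's shared subunit.
#' @param chi_values chi angle set per rotatable bond (degrees); default
#'   `c(-60, 60, 180)`.
#' @return list of rotamers; each is a data frame (`atom`, `elem`, `x`, `y`,
#'   `z`) of side-chain atoms including CB (empty for glycine), with the chi
#'   vector attached as attribute `"chi"`.
#' @export
grow_sidechain <- function(model, position, mutant_aa, chain_id = NULL,
                           chi_values = c(-60, 60, 180)) {
  st <- if (inherits(model, "sw_complex_model")) model$structure else model
  if (is.null(chain_id)) {
    chain_id <- if (inherits(model, "sw_complex_model")) {
      shared_chain_id(model)
    } else chain_ids(st)[1]
  }
  mutant_aa <- toupper(mutant_aa)
  if (!mutant_aa %in% names(SIDECHAIN_TOPO)) {
    stop("unknown residue type '", mutant_aa, "'")
  }
  a <- st$atoms
  res <- a[a$chain == chain_id & a$resno == position, , drop = FALSE]
  missing_bb <- setdiff(c("N", "CA", "C"), res$atom)
  if (length(missing_bb) > 0) {
    stop("backbone atom(s) ", paste(missing_bb, collapse = ", "),
         " missing at position ", position, " of chain ", chain_id)
  }
  p <- function(nm) unlist(res[res$atom == nm, c("x", "y", "z")][1, ])
  base <- list(N = p("N"), CA = p("CA"), C = p("C"))

  if (mutant_aa == "G") {
    out <- data.frame(atom = character(0), elem = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "chi") <- numeric(0)
    return(list(out))
  }
  cb <- ideal_cb(base$N, base$CA, base$C)
  topo <- SIDECHAIN_TOPO[[mutant_aa]]
  nchi <- n_chi(mutant_aa)
  free <- min(nchi, 3L)
  grid <- if (free == 0) {
    matrix(numeric(0), nrow = 1, ncol = 0)
  } else {
    as.matrix(expand.grid(rep(list(chi_values), free)))
  }
  rotamers <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    chis <- c(grid[r, ], rep(180, max(0, nchi - free)))
    coords <- c(base, list(CB = cb))
    names_out <- "CB"
    for (at in topo) {
      tors <- if (!is.na(at$fixed)) at$fixed else chis[at$chi] + at$offset
      coords[[at$name]] <- nerf_place(coords[[at$a]], coords[[at$b]],
                                      coords[[at$c]], at$bond, at$angle, tors)
      names_out <- c(names_out, at$name)
    }
    xyz <- do.call(rbind, coords[names_out])
    out <- data.frame(atom = names_out,
                      elem = substr(names_out, 1, 1),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "chi") <- unname(chis)
    rotamers[[r]] <- out
  }
  rotamers
}

#' Steric clash score of a proposed mutation against a partner chain
#'
#' Grows the mutant side chain in every rotamer and scores the soft-sphere
#' squared overlap (sum over atom pairs of `max(0, r_i + r_j - d)^2`,
#' angstrom^2) against the heavy atoms of the partner chain. The
#' max-over-rotamers view asks "can this mutation clash however the side
#' chain turns is best for the designer"; a designed clash requires max > 0.
#' The min-over-rotamers view is the partner-optimistic bound: only min = 0
#' certifies that some rotamer avoids the partner entirely.
#'
#' @param model an `sw_complex_model`.
#' @param proposal one-row data frame from [propose_mutation()].
#' @param partner_chain_id chain the mutation is meant to displace.
#' @param chain_id chain carrying the mutation; defaults to the shared
#'   subunit.
#' @param chi_values chi library (see [grow_sidechain()]).
#' @return object of class `sw_clash_report`: `per_rotamer` (numeric),
#'   `min_overlap`, `max_overlap`, `designed_clash` (max > 0), `no_clash`
#'   (min == 0), `partner_atoms` (data frame of partner atoms overlapping in
#'   the max-scoring rotamer).
#' @export
clash_score <- function(model, proposal, partner_chain_id, chain_id = NULL,
                        chi_values = c(-60, 60, 180)) {
  st <- model$structure
  if (!partner_chain_id %in% chain_ids(st)) {
    stop("partner chain '", partner_chain_id, "' not in model")
  }
  if (is.null(chain_id)) chain_id <- shared_chain_id(model)
  rot <- grow_sidechain(model, proposal$position, proposal$mutant_aa,
                        chain_id = chain_id, chi_values = chi_values)
  par <- st$atoms[st$atoms$chain == partner_chain_id, , drop = FALSE]
  pxyz <- as.matrix(par[, c("x", "y", "z")])
  prad <- vdw_radius(par$elem)

  per_rot <- numeric(length(rot))
  involved <- vector("list", length(rot))
  for (r in seq_along(rot)) {
    m <- rot[[r]]
    if (nrow(m) == 0) { involved[[r]] <- integer(0); next }
    mxyz <- as.matrix(m[, c("x", "y", "z")])
    mrad <- vdw_radius(m$elem)
    tot <- 0; hit <- logical(nrow(par))
    for (i in seq_len(nrow(m))) {
      d <- sqrt((pxyz[, 1] - mxyz[i, 1])^2 + (pxyz[, 2] - mxyz[i, 2])^2 +
                  (pxyz[, 3] - mxyz[i, 3])^2)
      pen <- mrad[i] + prad - d
      pos <- pen > 0
      if (any(pos)) { tot <- tot + sum(pen[pos]^2); hit <- hit | pos }
    }
    per_rot[r] <- tot
    involved[[r]] <- which(hit)
  }
  best <- which.max(per_rot)
  structure(list(per_rotamer = per_rot,
                 min_overlap = min(per_rot),
                 max_overlap = max(per_rot),
                 designed_clash = max(per_rot) > 0,
                 no_clash = min(per_rot) == 0,
                 partner_atoms = par[involved[[best]], , drop = FALSE]),
            class = "sw_clash_report")
}

#' @export
print.sw_clash_report <- function(x, ...) {
  cat(sprintf(
    "<sw_clash_report> %d rotamers, overlap min %.3f / max %.3f A^2%s\n",
    length(x$per_rotamer), x$min_overlap, x$max_overlap,
    if (x$designed_clash) " (designed clash)" else ""))
  invisible(x)
}

#' Is a residue solvent-exposed in the shared subunit alone?
#'
#' Computes the residue's SASA with all partner chains removed (the state the
#' mutant surface would face if the targeted complex no longer forms) and
#' compares its relative SASA - residue SASA divided by the residue type's
#' Gly-X-Gly maximum - against a threshold. The wild-type residue as present
#' in the model is measured; the reference maximum is taken for that same
#' residue type.
#'
#' @param model an `sw_complex_model`.
#' @param position author residue number on the shared subunit.
#' @param threshold minimum relative SASA to call the residue exposed;
#'   default 0.2.
#' @param probe_radius,n_points passed to [sasa()].
#' @return logical, with the relative SASA attached as attribute
#'   `"relative_sasa"`.
#' @export
exposure_check <- function(model, position, threshold = 0.2,
                           probe_radius = 1.4, n_points = 960) {
  if (threshold <= 0) {
    return(structure(TRUE, relative_sasa = NA_real_))
  }
  chain <- get_chain(model$structure, shared_chain_id(model))
  prof <- sasa(chain, probe_radius = probe_radius, n_points = n_points)
  row <- prof$residue_sasa[prof$residue_sasa$resno == position, , drop = FALSE]
  if (nrow(row) == 0) stop("position ", position, " not in shared subunit")
  one <- if (row$resna[1] %in% names(AA_321)) AA_321[[row$resna[1]]] else NA
  if (is.na(one) || !one %in% names(MAX_SASA_GXG)) {
    stop("no reference maximum SASA for residue ", row$resna[1])
  }
  rel <- row$sasa[1] / MAX_SASA_GXG[[one]]
  structure(rel >= threshold, relative_sasa = rel)
}

# relative SASA of every residue of a chain (chain in isolation), one SASA
# evaluation for the whole chain
relative_sasa_profile <- function(chain, probe_radius = 1.4, n_points = 960) {
  prof <- sasa(chain, probe_radius = probe_radius, n_points = n_points)
  rs <- prof$residue_sasa
  one <- ifelse(rs$resna %in% names(AA_321), AA_321[rs$resna], NA)
  rs$relative_sasa <- rs$sasa / MAX_SASA_GXG[one]
  rs
}

#' Group mutation targets
#'
#' @param proposals data frame with a `position` column (one row per
#'   proposal).
#' @param method `"sequence_window"` merges positions closer than
#'   `window_len` along the sequence; `"spatial"` single-linkage clusters CA
#'   positions at `dist_cutoff` (requires `model`); `"explicit"` takes a
#'   user partition.
#' @param window_len sequence gap (residues) that separates groups;
#'   default 10.
#' @param partition for `"explicit"`: list of position vectors that must
#'   cover all proposals disjointly.
#' @param model,dist_cutoff for `"spatial"`.
#' @return named list (`G1`, `G2`, ...) of sorted position vectors.
#' @export
group_targets <- function(proposals,
                          method = c("sequence_window", "spatial", "explicit"),
                          window_len = 10, partition = NULL,
                          model = NULL, dist_cutoff = 8) {
  method <- match.arg(method)
  pos <- sort(unique(proposals$position))
  if (length(pos) == 0) stop("no proposals to group")
  if (method == "sequence_window") {
    brk <- c(0, which(diff(pos) > window_len), length(pos))
    groups <- lapply(seq_len(length(brk) - 1), function(i) {
      pos[(brk[i] + 1):brk[i + 1]]
    })
  } else if (method == "explicit") {
    if (is.null(partition)) stop("explicit grouping needs 'partition'")
    flat <- unlist(partition)
    if (anyDuplicated(flat)) stop("explicit partition has duplicated positions")
    not_covered <- setdiff(pos, flat)
    if (length(not_covered) > 0) {
      stop("explicit partition does not cover position(s): ",
           paste(not_covered, collapse = ", "))
    }
    groups <- lapply(partition, function(g) sort(intersect(g, pos)))
    groups <- groups[vapply(groups, length, integer(1)) > 0]
  } else {
    if (is.null(model)) stop("spatial grouping needs 'model'")
    chain <- get_chain(model$structure, shared_chain_id(model))
    ca <- chain$atoms[chain$atoms$atom == "CA" &
                        chain$atoms$resno %in% pos, , drop = FALSE]
    ca <- ca[match(pos, ca$resno), ]
    if (length(pos) == 1) {
      groups <- list(pos)
    } else {
      hc <- stats::hclust(stats::dist(ca[, c("x", "y", "z")]),
                          method = "single")
      cl <- stats::cutree(hc, h = dist_cutoff)
      groups <- unname(split(pos, cl))
      groups <- groups[order(vapply(groups, min, numeric(1)))]
    }
  }
  setNames(groups, paste0("G", seq_along(groups)))
}

#' Enumerate all non-empty combinations of mutation groups
#'
#' @param groups named list of position vectors (see [group_targets()]).
#' @return named list of `2^g - 1` position vectors; names are `K` followed
#'   by the sorted indices of the included groups (`K1`, `K2`, `K12`, ...),
#'   ordered by combination size then index.
#' @export
enumerate_combinations <- function(groups) {
  g <- length(groups)
  if (g < 1) stop("need at least one group")
  combos <- list()
  for (size in seq_len(g)) {
    idx_sets <- utils::combn(g, size, simplify = FALSE)
    for (idx in idx_sets) {
      nm <- paste0("K", paste(idx, collapse = ""))
      combos[[nm]] <- sort(unique(unlist(groups[idx])))
    }
  }
  combos
}
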