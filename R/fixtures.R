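# Synthetic toy complexes with known ground-truth interfaces. Fixtures are
# ideal helices, not folded domains: analytic placement makes the truth sets
# exact by construction rather than re-measured.

# ideal backbone geometry (angstrom / degrees)
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.53,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5, dih_cb = 122.6,
  phi = -57, psi = -47, omega = 180
)

#' Build an ideal alpha-helix chain
#'
#' Backbone (N, CA, C, O) generated from ideal bond geometry with
#' phi = -57 deg, psi = -47 deg, plus an ideal CB on every non-glycine
#' residue. Deterministic: the same arguments always give the same
#' coordinates. The CA(i)-CA(i+1) spacing of such a helix is ~3.8 A.
#'
#' @param n_res number of residues.
#' @param sequence one-letter sequence of length `n_res` (default poly-Ala).
#' @param chain_id chain identifier.
#' @param start_resno author number of the first residue.
#' @return an [sw_structure()] with one chain.
#' @export
make_helix <- function(n_res, sequence = strrep("A", n_res), chain_id = "A",
                       start_resno = 1L) {
  if (nchar(sequence) != n_res) {
    stop("sequence length ", nchar(sequence), " != n_res ", n_res)
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(AA_123))
  if (length(bad) > 0) stop("non-standard letters in sequence: ",
                            paste(unique(bad), collapse = ", "))
  g <- BB_GEOM
  n_xyz <- matrix(NA_real_, n_res, 3)
  ca_xyz <- matrix(NA_real_, n_res, 3)
  c_xyz <- matrix(NA_real_, n_res, 3)
  n_xyz[1, ] <- c(0, 0, 0)
  ca_xyz[1, ] <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  c_xyz[1, ] <- ca_xyz[1, ] + g$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_res)[-1]) {
    n_xyz[i, ] <- nerf_place(n_xyz[i - 1, ], ca_xyz[i - 1, ], c_xyz[i - 1, ],
                             g$c_n, g$ang_ca_c_n, g$psi)
    ca_xyz[i, ] <- nerf_place(ca_xyz[i - 1, ], c_xyz[i - 1, ], n_xyz[i, ],
                              g$n_ca, g$ang_c_n_ca, g$omega)
    c_xyz[i, ] <- nerf_place(c_xyz[i - 1, ], n_xyz[i, ], ca_xyz[i, ],
                             g$ca_c, g$ang_n_ca_c, g$phi)
  }
  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    o <- nerf_place(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ],
                    g$c_o, g$ang_ca_c_o, g$psi + 180)
    names_i <- c("N", "CA", "C", "O")
    elem_i <- c("N", "C", "C", "O")
    xyz_i <- rbind(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ], o)
    if (aa[i] != "G") {
      cb <- nerf_place(c_xyz[i, ], n_xyz[i, ], ca_xyz[i, ],
                       g$ca_cb, g$ang_n_ca_cb, g$dih_cb)
      names_i <- c(names_i, "CB")
      elem_i <- c(elem_i, "C")
      xyz_i <- rbind(xyz_i, cb)
    }
    rows[[i]] <- data.frame(
      chain = chain_id, resno = start_resno + i - 1L, ins = "",
      resna = unname(AA_123[aa[i]]), atom = names_i, elem = elem_i,
      x = unname(xyz_i[, 1]), y = unname(xyz_i[, 2]), z = unname(xyz_i[, 3]),
      occ = 1, row.names = NULL, stringsAsFactors = FALSE
    )
  }
  sw_structure(do.call(rbind, rows), id = paste0("helix_", chain_id),
               source_format = "generated")
}

#' Specification of a synthetic two-partner fixture
#'
#' Describes a focal helix and two partner chains whose contact footprints on
#' the focal chain are known half-open residue intervals. `approach_distance`
#' is the planted minimum heavy-atom distance between each interval residue
#' and its partner; the default 3.8 A is a typical heavy-atom contact
#' distance, comfortably inside the default 4.5 A contact cutoff while
#' non-interval residues sit > 8 A from any partner atom.
#'
#' @param seed integer seed recorded in outputs and used by [perturb()].
#' @param n_res_focal focal helix length.
#' @param partner_specs list of two lists, each with `partner_id` (chain id),
#'   `contact_interval` (half-open `c(start, end)` on focal author numbering)
#'   and optionally `approach_distance` (angstrom).
#' @param noise_sigma per-atom Gaussian noise (angstrom) applied to both
#'   complexes via [perturb()]; 0 disables.
#' @param sequence focal chain sequence (default poly-Ala).
#' @return object of class `sw_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_res_focal = 60L,
                         partner_specs = list(
                           list(partner_id = "B",
                                contact_interval = c(10L, 25L),
                                approach_distance = 3.8),
                           list(partner_id = "C",
                                contact_interval = c(20L, 40L),
                                approach_distance = 3.8)),
                         noise_sigma = 0, sequence = NULL) {
  stopifnot(length(partner_specs) == 2, noise_sigma >= 0)
  for (ps in partner_specs) {
    iv <- ps$contact_interval
    if (length(iv) != 2 || iv[1] >= iv[2]) {
      stop("contact_interval must be half-open c(start, end) with start < end")
    }
    if (iv[1] < 1 || iv[2] > n_res_focal + 1) {
      stop("contact_interval [", iv[1], ",", iv[2],
           ") outside focal chain 1..", n_res_focal)
    }
    if (!is.null(ps$approach_distance) && ps$approach_distance <= 0) {
      stop("approach_distance must be positive")
    }
  }
  if (is.null(sequence)) sequence <- strrep("A", n_res_focal)
  structure(list(seed = as.integer(seed), n_res_focal = as.integer(n_res_focal),
                 partner_specs = partner_specs, noise_sigma = noise_sigma,
                 sequence = sequence),
            class = "sw_fixture_spec")
}

# partner atoms for one focal interval: three pseudo-atoms per interval
# residue, planted on the radial through the focal CB (outward from the
# fitted helix axis) at the approach distance, flanked along the axis.
# Radial placement keeps every non-interval residue > 6.4 A from any partner
# atom, so interface truth is exact at the default cutoff and margin.
partner_atoms_for_interval <- function(focal, interval, approach,
                                       partner_id) {
  a <- focal$atoms
  ca_all <- as.matrix(a[a$atom == "CA", c("x", "y", "z")])
  centre_all <- colMeans(ca_all)
  axis <- stats::prcomp(ca_all)$rotation[, 1]
  res <- seq.int(interval[1], interval[2] - 1L)
  rows <- vector("list", length(res))
  for (k in seq_along(res)) {
    i <- res[k]
    cb <- unlist(a[a$resno == i & a$atom == "CB", c("x", "y", "z")])
    if (length(cb) == 0) stop("focal residue ", i, " lacks CB")
    v <- cb - centre_all
    u <- unitv(v - sum(v * axis) * axis)   # radial, away from helix axis
    # two axial flankers sit slightly inside the approach distance so the
    # planted contact is redundant (robust to small coordinate noise)
    centre <- cb + approach * u
    xyz <- rbind(centre,
                 centre + 0.7 * axis - 0.25 * u,
                 centre - 0.7 * axis - 0.25 * u)
    rows[[k]] <- data.frame(
      chain = partner_id, resno = k, ins = "", resna = "UNK",
      atom = c("CB", "CG", "CD"), elem = "C",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Generate a two-partner fixture with ground-truth interfaces
#'
#' Builds a focal helix plus two alternative complexes: partner 1 contacts
#' exactly `contact_interval_1` in complex 1, partner 2 contacts exactly
#' `contact_interval_2` in complex 2. Truth sets are derived from the
#' construction, not re-measured, so they are exact targets for the contact,
#' interface and differential-interface machinery.
#'
#' @param spec an [fixture_spec()].
#' @return list with `complex_1`, `complex_2` ([sw_structure()]s sharing the
#'   focal chain "A"), and `truth` (per-partner interface residue sets,
#'   differential sets in both directions, planted clash pairs, the spec).
#' @export
make_two_partner_fixture <- function(spec) {
  stopifnot(inherits(spec, "sw_fixture_spec"))
  focal <- make_helix(spec$n_res_focal, spec$sequence, chain_id = "A")
  p1 <- spec$partner_specs[[1]]
  p2 <- spec$partner_specs[[2]]
  ap1 <- if (is.null(p1$approach_distance)) 3.8 else p1$approach_distance
  ap2 <- if (is.null(p2$approach_distance)) 3.8 else p2$approach_distance

  atoms1 <- partner_atoms_for_interval(focal, p1$contact_interval, ap1,
                                       p1$partner_id)
  atoms2 <- partner_atoms_for_interval(focal, p2$contact_interval, ap2,
                                       p2$partner_id)
  complex_1 <- sw_structure(rbind(focal$atoms, atoms1), id = "fixture_complex_1")
  complex_2 <- sw_structure(rbind(focal$atoms, atoms2), id = "fixture_complex_2")
  if (spec$noise_sigma > 0) {
    complex_1 <- perturb(complex_1, spec$seed, spec$noise_sigma)
    complex_2 <- perturb(complex_2, spec$seed + 1L, spec$noise_sigma)
  }
  iv1 <- seq.int(p1$contact_interval[1], p1$contact_interval[2] - 1L)
  iv2 <- seq.int(p2$contact_interval[1], p2$contact_interval[2] - 1L)
  clash_radius <- 2 * VDW_RADII[["C"]]
  truth <- list(
    interfaces = setNames(list(iv1, iv2), c(p1$partner_id, p2$partner_id)),
    differential = setNames(list(setdiff(iv1, iv2), setdiff(iv2, iv1)),
                            c(paste0(p1$partner_id, "_not_", p2$partner_id),
                              paste0(p2$partner_id, "_not_", p1$partner_id))),
    clash_pairs = setNames(list(if (ap1 < clash_radius) iv1 else integer(0),
                                if (ap2 < clash_radius) iv2 else integer(0)),
                           c(p1$partner_id, p2$partner_id)),
    spec = spec
  )
  list(complex_1 = complex_1, complex_2 = complex_2, truth = truth)
}

#' Add seeded Gaussian coordinate noise
#'
#' I.i.d. N(0, sigma^2) displacement per atom and coordinate, behind a local
#' RNG so the caller's random state is untouched. Reproducible: the same
#' seed always gives the same output.
#'
#' @param structure an [sw_structure()].
#' @param seed integer seed.
#' @param sigma standard deviation (angstrom); 0 returns the input unchanged.
#' @return perturbed `sw_structure`.
#' @export
perturb <- function(structure, seed, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(structure)
  n <- nrow(structure$atoms)
  noise <- local_rng(seed, stats::rnorm(3L * n, 0, sigma))
  structure$atoms$x <- structure$atoms$x + noise[seq_len(n)]
  structure$atoms$y <- structure$atoms$y + noise[n + seq_len(n)]
  structure$atoms$z <- structure$atoms$z + noise[2L * n + seq_len(n)]
  structure
}

# evaluate expr under a temporary RNG seeded with `seed`
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
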