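# Independent oracles used across the suite. These deliberately share no
# code with the package: plain-R dynamic programming, all-pairs distance
# scans and closed-form geometry.

# Gotoh affine-gap global alignment score (gap of length L costs
# open + L * extend, end gaps included), brute-force O(nm) matrices.
oracle_align_score <- function(a, b, submat, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1)
  X <- matrix(neg, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(neg, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * extend)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend,
                             Y[i, j + 1] - open - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend,
                             X[i + 1, j] - open - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# all-pairs residue contact list between two chains of a structure:
# returns sorted "labA|labB" keys of residue pairs with min heavy-atom
# distance <= cutoff
oracle_contact_keys <- function(structure, chain_a, chain_b, cutoff) {
  at <- structure$atoms
  a <- at[at$chain == chain_a, ]
  b <- at[at$chain == chain_b, ]
  lab_a <- paste0(a$resno, a$ins)
  lab_b <- paste0(b$resno, b$ins)
  keys <- character(0)
  for (ra in unique(lab_a)) {
    pa <- as.matrix(a[lab_a == ra, c("x", "y", "z")])
    for (rb in unique(lab_b)) {
      pb <- as.matrix(b[lab_b == rb, c("x", "y", "z")])
      dmin <- Inf
      for (i in seq_len(nrow(pa))) {
        dmin <- min(dmin, sqrt(min((pb[, 1] - pa[i, 1])^2 +
                                     (pb[, 2] - pa[i, 2])^2 +
                                     (pb[, 3] - pa[i, 3])^2)))
      }
      if (dmin <= cutoff) keys <- c(keys, paste(ra, rb, sep = "|"))
    }
  }
  sort(keys)
}

# random two-chain point cloud for oracle-equivalence tests
random_two_chain_structure <- function(seed, n_a = 60, n_b = 60,
                                       box = 20) {
  set.seed(seed)
  mk <- function(chain, n) {
    data.frame(chain = chain,
               resno = rep(seq_len(ceiling(n / 3)), each = 3)[seq_len(n)],
               ins = "", resna = "UNK",
               atom = rep(c("C1", "C2", "C3"), length.out = n),
               elem = "C",
               x = runif(n, 0, box), y = runif(n, 0, box),
               z = runif(n, 0, box), occ = 1,
               stringsAsFactors = FALSE)
  }
  sw_structure(rbind(mk("A", n_a), mk("B", n_b)), id = paste0("rand", seed))
}

# random rotation matrix from a seeded quaternion
random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# soft-sphere overlap by direct double loop
oracle_overlap <- function(xyz_a, rad_a, xyz_b, rad_b) {
  tot <- 0
  for (i in seq_len(nrow(xyz_a))) {
    for (j in seq_len(nrow(xyz_b))) {
      d <- sqrt(sum((xyz_a[i, ] - xyz_b[j, ])^2))
      pen <- rad_a[i] + rad_b[j] - d
      if (pen > 0) tot <- tot + pen^2
    }
  }
  tot
}

# minimal hand-written two-residue PDB text
minimal_pdb_text <- c(
  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
  "END"
)

# wrap a single-helix structure as a complex model (with a distant dummy
# partner so the role invariants hold)
complex_model_from_helix <- function(h) {
  cid <- unique(h$atoms$chain)[1]
  dummy <- data.frame(chain = "Z", resno = 1L, ins = "", resna = "UNK",
                      atom = "C1", elem = "C", x = 500, y = 500, z = 500,
                      occ = 1, stringsAsFactors = FALSE)
  complex_model(sw_structure(rbind(h$atoms, dummy)), "helix_model",
                setNames(c("shared_subunit", "partner_specific"),
                         c(cid, "Z")))
}
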