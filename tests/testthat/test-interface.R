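two_cb_structure <- function(d) {
  sw_structure(data.frame(
    chain = c("A", "B"), resno = c(1L, 1L), ins = "",
    resna = "ALA", atom = "CB", elem = "C",
    x = c(0, d), y = 0, z = 0, occ = 1, stringsAsFactors = FALSE))
}

test_that("contact map applies the heavy-atom min-distance cutoff exactly", {
  st <- two_cb_structure(4.0)
  cm <- contact_map(st, "A", "B", cutoff = 4.5)
  expect_equal(nrow(cm$contacts), 1)
  expect_equal(cm$contacts$dist, 4.0)
  expect_equal(nrow(contact_map(st, "A", "B", cutoff = 3.5)$contacts), 0)
  expect_error(contact_map(st, "A", "A"), "differ")
})

test_that("grid contacts equal the brute-force oracle on random fixtures", {
  for (seed in 1:25) {
    st <- random_two_chain_structure(seed, n_a = 100, n_b = 100)
    cutoff <- runif(1, 3, 6)
    cm <- contact_map(st, "A", "B", cutoff = cutoff)
    got <- sort(paste(cm$contacts$label_a, cm$contacts$label_b, sep = "|"))
    expect_equal(got, oracle_contact_keys(st, "A", "B", cutoff),
                 info = paste("seed", seed))
    # and the package's own brute method agrees with the grid
    cm2 <- contact_map(st, "A", "B", cutoff = cutoff, method = "brute")
    expect_equal(cm$contacts, cm2$contacts, info = paste("seed", seed))
  }
})

test_that("contact maps are symmetric under swapping the chain pair", {
  st <- random_two_chain_structure(99)
  ab <- contact_map(st, "A", "B", 4.5)
  ba <- contact_map(st, "B", "A", 4.5)
  expect_equal(sort(paste(ab$contacts$label_a, ab$contacts$label_b)),
               sort(paste(ba$contacts$label_b, ba$contacts$label_a)))
  expect_equal(sort(ab$contacts$dist), sort(ba$contacts$dist))
})

test_that("interface projection collects focal residues from contacts", {
  st <- two_cb_structure(4.0)
  cm <- contact_map(st, "A", "B", 4.5)
  iface <- interface_residues(cm, "A")
  expect_equal(iface$residues$resno, 1L)
  empty <- interface_residues(contact_map(st, "A", "B", 3.0), "A")
  expect_equal(nrow(empty$residues), 0)
  expect_error(interface_residues(cm, "Z"), "not a side")

  fx <- make_two_partner_fixture(fixture_spec())
  cm_fx <- contact_map(fx$complex_1, "A", "B", 4.5)
  got <- interface_residues(cm_fx, "A")$residues$resno
  expect_equal(got, fx$truth$interfaces$B)
})

fixture_models <- function(fs = fixture_spec()) {
  fx <- make_two_partner_fixture(fs)
  list(
    fx = fx,
    m1 = complex_model(fx$complex_1, "m1",
                       c(A = "shared_subunit", B = "partner_specific")),
    m2 = complex_model(fx$complex_2, "m2",
                       c(A = "shared_subunit", C = "partner_specific"))
  )
}

test_that("differential interface equals constructed truth on fixtures", {
  # overlapping footprints
  fm <- fixture_models(fixture_spec(
    partner_specs = list(
      list(partner_id = "B", contact_interval = c(10L, 25L)),
      list(partner_id = "C", contact_interval = c(20L, 40L)))))
  mp <- map_shared_subunit(fm$m1, fm$m2)
  d <- differential_interface(fm$m1, fm$m2, mp, "B", "C")
  expect_equal(as.integer(d$residues), 10:19)

  # disjoint footprints: full included interface survives
  fm2 <- fixture_models(fixture_spec(
    partner_specs = list(
      list(partner_id = "B", contact_interval = c(10L, 20L)),
      list(partner_id = "C", contact_interval = c(30L, 40L)))))
  d2 <- differential_interface(fm2$m1, fm2$m2,
                               map_shared_subunit(fm2$m1, fm2$m2), "B", "C")
  expect_equal(as.integer(d2$residues), 10:19)

  # identical footprints: empty differential
  fm3 <- fixture_models(fixture_spec(
    partner_specs = list(
      list(partner_id = "B", contact_interval = c(10L, 20L)),
      list(partner_id = "C", contact_interval = c(10L, 20L)))))
  d3 <- differential_interface(fm3$m1, fm3$m2,
                               map_shared_subunit(fm3$m1, fm3$m2), "B", "C")
  expect_length(d3$residues, 0)

  expect_error(differential_interface(fm$m1, fm$m2, mp, "B", "Z"), "neither")
})

test_that("differential set shrinks monotonically with the exclusion margin", {
  fm <- fixture_models(fixture_spec(
    partner_specs = list(
      list(partner_id = "B", contact_interval = c(10L, 30L)),
      list(partner_id = "C", contact_interval = c(25L, 45L)))))
  mp <- map_shared_subunit(fm$m1, fm$m2)
  prev <- NULL
  for (margin in c(0, 1, 2, 3, 5, 8)) {
    cur <- differential_interface(fm$m1, fm$m2, mp, "B", "C",
                                  exclusion_margin = margin)$residues
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("residues unresolved in the second model are dropped and reported", {
  fm <- fixture_models(fixture_spec(
    partner_specs = list(
      list(partner_id = "B", contact_interval = c(10L, 20L)),
      list(partner_id = "C", contact_interval = c(30L, 40L)))))
  a2 <- fm$fx$complex_2$atoms
  m2_missing <- complex_model(
    sw_structure(a2[!(a2$chain == "A" & a2$resno %in% 12:14), ]), "m2m",
    c(A = "shared_subunit", C = "partner_specific"))
  mp <- map_shared_subunit(fm$m1, m2_missing)
  d <- differential_interface(fm$m1, m2_missing, mp, "B", "C")
  expect_setequal(d$unresolved, as.character(12:14))
  expect_equal(as.integer(d$residues), setdiff(10:19, 12:14))
})

test_that("isolated-atom SASA matches the closed form within quadrature error", {
  st <- sw_structure(data.frame(
    chain = "A", resno = 1L, ins = "", resna = "UNK", atom = "C1",
    elem = "C", x = 0, y = 0, z = 0, occ = 1, stringsAsFactors = FALSE))
  prof <- sasa(st, probe_radius = 1.4, n_points = 960)
  exact <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(prof$atom_sasa, exact, tolerance = 0.01)
  expect_equal(prof$residue_sasa$sasa, prof$atom_sasa)
})

test_that("a caged atom has zero SASA and burial never adds area", {
  # carbon at origin enclosed by a dense shell of carbons at 2.5 A
  shell <- specswitch:::sphere_points(60) * 2.5
  atoms <- data.frame(
    chain = "A", resno = c(1L, rep(2L, 60)), ins = "", resna = "UNK",
    atom = paste0("C", 1:61), elem = "C",
    x = c(0, shell[, 1]), y = c(0, shell[, 2]), z = c(0, shell[, 3]),
    occ = 1, stringsAsFactors = FALSE)
  prof <- sasa(sw_structure(atoms))
  expect_equal(prof$atom_sasa[1], 0)
  # subadditivity: total <= sum of isolated areas
  iso_total <- 61 * 4 * pi * (1.70 + 1.4)^2
  expect_lt(sum(prof$atom_sasa), iso_total)
})

test_that("SASA is converged in point count and validates its inputs", {
  h <- make_helix(8)
  p1 <- sasa(h, n_points = 960)
  p2 <- sasa(h, n_points = 1920)
  # quadrature error measured against each atom's isolated-sphere area
  iso <- 4 * pi * (vdw_radius(h$atoms$elem) + 1.4)^2
  expect_lt(max(abs(p1$atom_sasa - p2$atom_sasa) / iso), 0.02)
  expect_error(sasa(h, n_points = 50), ">= 92")
  bad <- h
  bad$atoms$elem[1] <- "QQ"
  expect_error(sasa(bad), "QQ")
})

test_that("unique regions are the reference-only gap blocks of the MSA", {
  msa <- c(ref = "AAAAAAAA", sp = "AA----AA", hs = "AA----AA")
  ur <- unique_regions(msa, "ref")
  expect_equal(ur$regions$start, 3)
  expect_equal(ur$regions$end, 7)

  # no gaps anywhere: empty set
  ur2 <- unique_regions(c(ref = "AAAA", o = "CCCC"), "ref")
  expect_equal(nrow(ur2$regions), 0)

  # runs below min_len are discarded
  ur3 <- unique_regions(c(ref = "AAAAAA", o = "A--AAA"), "ref", min_len = 3)
  expect_equal(nrow(ur3$regions), 0)

  expect_error(unique_regions(c(ref = "AAA", o = "AAAA"), "ref"), "ragged")
  expect_error(unique_regions(msa, "nope"), "not in MSA")
})

test_that("unique regions match a brute-force column scan on random MSAs", {
  set.seed(31)
  for (t in 1:15) {
    ncol <- sample(20:60, 1)
    mk_row <- function(p_gap) {
      paste(ifelse(runif(ncol) < p_gap, "-", "A"), collapse = "")
    }
    rows <- c(ref = mk_row(0.1), o1 = mk_row(0.4), o2 = mk_row(0.4))
    ur <- unique_regions(rows, "ref", min_len = 2)
    # brute force: per reference residue, is its column gapped in all others?
    mat <- do.call(rbind, strsplit(rows, ""))
    refres <- which(mat[1, ] != "-")
    flag <- mat[2, refres] == "-" & mat[3, refres] == "-"
    # additionally the qualifying columns must be contiguous in the alignment
    runs <- rle(apply(mat[-1, , drop = FALSE] == "-", 2, all) & mat[1, ] != "-")
    covered <- logical(length(refres))
    if (nrow(ur$regions) > 0) {
      for (k in seq_len(nrow(ur$regions))) {
        covered[ur$regions$start[k]:(ur$regions$end[k] - 1)] <- TRUE
      }
    }
    # every covered reference position must be flagged by the oracle
    expect_true(all(flag[covered]), info = paste("case", t))
    # every maximal oracle run of length >= 2 must be covered
    pos <- 0
    for (r in seq_along(runs$lengths)) {
      n_ref_in_run <- sum(mat[1, (pos + 1):(pos + runs$lengths[r])] != "-")
      if (runs$values[r] && n_ref_in_run >= 2) {
        first_ref <- sum(mat[1, 1:pos] != "-") + 1
        expect_true(all(covered[first_ref:(first_ref + n_ref_in_run - 1)]),
                    info = paste("case", t, "run", r))
      }
      pos <- pos + runs$lengths[r]
    }
  }
})

test_that("annotation flags differential residues contacting unique loops", {
  fm <- fixture_models(fixture_spec(
    partner_specs = list(
      list(partner_id = "B", contact_interval = c(10L, 20L)),
      list(partner_id = "C", contact_interval = c(30L, 40L)))))
  mp <- map_shared_subunit(fm$m1, fm$m2)
  d <- differential_interface(fm$m1, fm$m2, mp, "B", "C")
  cm <- contact_map(fm$m1$structure, "A", "B", 4.5)
  # partner B has 10 residues (1..10); declare 4..10 unique to the reference
  msa <- c(B = strrep("A", 10), o1 = paste0("AAA", strrep("-", 7)),
           o2 = paste0("AAA", strrep("-", 7)))
  ur <- unique_regions(msa, "B")
  ann <- annotate_differential(d, ur, cm)
  # focal residue 10+k contacts partner residue k+1 by construction
  expect_equal(unname(ann$unique_loop_flags),
               c(rep(FALSE, 3), rep(TRUE, 7)))
  # empty unique set: all flags false
  ann0 <- annotate_differential(d, unique_regions(
    c(B = "AAAA", o = "AAAA"), "B"), cm)
  expect_true(all(!ann0$unique_loop_flags))
})
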