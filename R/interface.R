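# Inter-chain contact maps, per-partner interface sets, the differential
# interface of a shared subunit across two complex models, Shrake-Rupley
# SASA, and orthologue-gap (unique loop) detection.

#' Heavy-atom contact map between two chains
#'
#' A residue pair is a contact iff the minimum distance over its heavy-atom
#' pairs is at or below the cutoff. Candidate pairs are found with a spatial
#' grid (cell size = cutoff, 27-cell neighbourhoods), which is exact: every
#' atom pair within the cutoff falls in adjacent cells. `method = "brute"`
#' runs the all-pairs computation instead.
#'
#' @param structure an [sw_structure()].
#' @param chain_a,chain_b distinct chain ids.
#' @param cutoff heavy-atom distance cutoff (angstrom); default 4.5.
#' @param method `"grid"` (default) or `"brute"`.
#' @return object of class `sw_contactmap`: `chain_pair`, `cutoff`, and
#'   `contacts`, a data frame (`resno_a`, `ins_a`, `label_a`, `resno_b`,
#'   `ins_b`, `label_b`, `dist`) sorted by residue.
#' @export
contact_map <- function(structure, chain_a, chain_b, cutoff = 4.5,
                        method = c("grid", "brute")) {
  method <- match.arg(method)
  if (identical(chain_a, chain_b)) stop("chain_a and chain_b must differ")
  if (cutoff <= 0) stop("cutoff must be positive")
  at <- structure$atoms
  a <- at[at$chain == chain_a, , drop = FALSE]
  b <- at[at$chain == chain_b, , drop = FALSE]
  if (nrow(a) == 0) stop("chain '", chain_a, "' not in structure")
  if (nrow(b) == 0) stop("chain '", chain_b, "' not in structure")

  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  res_a <- resid_label(a$resno, a$ins)
  res_b <- resid_label(b$resno, b$ins)

  if (method == "grid") {
    cell_b <- paste(floor(xb[, 1] / cutoff), floor(xb[, 2] / cutoff),
                    floor(xb[, 3] / cutoff))
    b_by_cell <- split(seq_len(nrow(xb)), cell_b)
    ia <- floor(xa / cutoff)
    hits_i <- integer(0); hits_j <- integer(0)
    offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    for (i in seq_len(nrow(xa))) {
      keys <- paste(ia[i, 1] + offsets[, 1], ia[i, 2] + offsets[, 2],
                    ia[i, 3] + offsets[, 3])
      cand <- unlist(b_by_cell[keys], use.names = FALSE)
      if (length(cand) == 0) next
      d2 <- (xb[cand, 1] - xa[i, 1])^2 + (xb[cand, 2] - xa[i, 2])^2 +
        (xb[cand, 3] - xa[i, 3])^2
      ok <- d2 <= cutoff^2
      if (any(ok)) {
        hits_i <- c(hits_i, rep.int(i, sum(ok)))
        hits_j <- c(hits_j, cand[ok])
      }
    }
  } else {
    hits_i <- integer(0); hits_j <- integer(0)
    for (i in seq_len(nrow(xa))) {
      d2 <- (xb[, 1] - xa[i, 1])^2 + (xb[, 2] - xa[i, 2])^2 +
        (xb[, 3] - xa[i, 3])^2
      ok <- d2 <= cutoff^2
      if (any(ok)) {
        hits_i <- c(hits_i, rep.int(i, sum(ok)))
        hits_j <- c(hits_j, which(ok))
      }
    }
  }

  if (length(hits_i) == 0) {
    contacts <- data.frame(resno_a = integer(0), ins_a = character(0),
                           label_a = character(0), resno_b = integer(0),
                           ins_b = character(0), label_b = character(0),
                           dist = numeric(0), stringsAsFactors = FALSE)
  } else {
    d <- sqrt((xa[hits_i, 1] - xb[hits_j, 1])^2 +
                (xa[hits_i, 2] - xb[hits_j, 2])^2 +
                (xa[hits_i, 3] - xb[hits_j, 3])^2)
    key <- paste(res_a[hits_i], res_b[hits_j], sep = "\r")
    mind <- tapply(d, key, min)
    first <- !duplicated(key)
    ord_i <- hits_i[first]; ord_j <- hits_j[first]
    contacts <- data.frame(
      resno_a = a$resno[ord_i], ins_a = a$ins[ord_i],
      label_a = res_a[ord_i],
      resno_b = b$resno[ord_j], ins_b = b$ins[ord_j],
      label_b = res_b[ord_j],
      dist = as.numeric(mind[key[first]]),
      stringsAsFactors = FALSE
    )
    contacts <- contacts[order(contacts$resno_a, contacts$ins_a,
                               contacts$resno_b, contacts$ins_b), ]
    rownames(contacts) <- NULL
  }
  structure(list(chain_pair = c(chain_a, chain_b), cutoff = cutoff,
                 contacts = contacts),
            class = "sw_contactmap")
}

#' @export
print.sw_contactmap <- function(x, ...) {
  cat(sprintf("<sw_contactmap> %s:%s, cutoff %.2f A, %d residue pairs\n",
              x$chain_pair[1], x$chain_pair[2], x$cutoff, nrow(x$contacts)))
  invisible(x)
}

#' Interface residue set of one chain
#'
#' @param cmap an `sw_contactmap`.
#' @param focal_chain_id which side of the contact map to project onto.
#' @return object of class `sw_interface`: `focal_chain_id`,
#'   `partner_chain_id`, `cutoff`, and `residues`, a data frame (`resno`,
#'   `ins`, `label`) of focal residues appearing in at least one contact.
#' @export
interface_residues <- function(cmap, focal_chain_id) {
  if (!focal_chain_id %in% cmap$chain_pair) {
    stop("chain '", focal_chain_id, "' is not a side of this contact map")
  }
  side <- if (focal_chain_id == cmap$chain_pair[1]) "a" else "b"
  cc <- cmap$contacts
  df <- data.frame(resno = cc[[paste0("resno_", side)]],
                   ins = cc[[paste0("ins_", side)]],
                   label = cc[[paste0("label_", side)]],
                   stringsAsFactors = FALSE)
  df <- unique(df)
  df <- df[order(df$resno, df$ins), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(focal_chain_id = focal_chain_id,
                 partner_chain_id = setdiff(cmap$chain_pair, focal_chain_id),
                 cutoff = cmap$cutoff, residues = df),
            class = "sw_interface")
}

#' Differential interface of a shared subunit across two complex models
#'
#' Residues of the shared subunit that (i) contact the included partner at
#' the cutoff in model 1 and (ii) keep a minimum heavy-atom distance greater
#' than `cutoff + exclusion_margin` to every excluded partner, in whichever
#' model carries that partner. The margin asserts "does not bind" with a
#' safety buffer, because template-grafted models are approximate. Residues
#' unresolved in either model are excluded and reported.
#'
#' @param model_1,model_2 [complex_model()] objects sharing a subunit.
#' @param shared_map residue mapping from [map_shared_subunit()].
#' @param included_partner chain id of the partner (in model 1) whose
#'   interface is wanted.
#' @param excluded_partners character vector of chain ids that must not
#'   contact the selected residues; each is looked up in model 2 first, then
#'   model 1.
#' @param cutoff contact cutoff (angstrom), default 4.5.
#' @param exclusion_margin extra clearance (angstrom) beyond the cutoff
#'   required to call a residue free of an excluded partner; default 1.5.
#' @return object of class `sw_diffinterface`: selected residue labels, a
#'   per-residue provenance table with the distance to the included partner
#'   and the minimum distance to each excluded partner, and the residues
#'   dropped because they are unresolved in model 2.
#' @export
differential_interface <- function(model_1, model_2, shared_map,
                                   included_partner, excluded_partners,
                                   cutoff = 4.5, exclusion_margin = 1.5) {
  shared_1 <- shared_chain_id(model_1)
  shared_2 <- shared_chain_id(model_2)
  if (!included_partner %in% chain_ids(model_1$structure)) {
    stop("included partner '", included_partner, "' not in model 1")
  }
  where <- lapply(excluded_partners, function(p) {
    in2 <- p %in% setdiff(chain_ids(model_2$structure), shared_2)
    in1 <- p %in% setdiff(chain_ids(model_1$structure), shared_1)
    if (!in1 && !in2) stop("excluded partner '", p, "' in neither model")
    c(if (in2) 2L, if (in1) 1L)
  })
  names(where) <- excluded_partners

  cmap <- contact_map(model_1$structure, shared_1, included_partner, cutoff)
  iface <- interface_residues(cmap, shared_1)$residues
  if (nrow(iface) == 0) {
    return(empty_diff(shared_1, included_partner, excluded_partners,
                      cutoff, exclusion_margin))
  }

  pairs <- shared_map$aligned_pairs
  map_to_2 <- setNames(pairs[, 2], pairs[, 1])

  prov <- iface
  prov$dist_included <- vapply(seq_len(nrow(iface)), function(k) {
    cc <- cmap$contacts
    min(cc$dist[cc$label_a == iface$label[k]])
  }, numeric(1))

  keep <- rep(TRUE, nrow(iface))
  unresolved <- character(0)
  threshold <- cutoff + exclusion_margin
  for (p in excluded_partners) {
    dcol <- numeric(nrow(iface))
    for (k in seq_len(nrow(iface))) {
      dmin <- Inf
      for (m in where[[p]]) {
        if (m == 1L) {
          dmin <- min(dmin, min_dist_residue_to_chain(
            model_1$structure, shared_1, iface$resno[k], iface$ins[k], p))
        } else {
          r2 <- map_to_2[as.character(iface$resno[k])]
          if (is.na(r2)) { dmin <- NA_real_; break }
          dmin <- min(dmin, min_dist_residue_to_chain(
            model_2$structure, shared_2, r2, iface$ins[k], p))
        }
      }
      dcol[k] <- dmin
    }
    prov[[paste0("dist_", p)]] <- dcol
    bad_na <- is.na(dcol)
    if (any(bad_na)) unresolved <- union(unresolved, iface$label[bad_na])
    keep <- keep & !bad_na & dcol > threshold
  }
  sel <- prov[keep, , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(focal_chain_id = shared_1,
                 included_partner = included_partner,
                 excluded_partners = excluded_partners,
                 cutoff = cutoff, exclusion_margin = exclusion_margin,
                 residues = sel$label,
                 provenance = {
                   prov$selected <- keep
                   prov
                 },
                 unresolved = unresolved),
            class = "sw_diffinterface")
}

empty_diff <- function(focal, included, excluded, cutoff, margin) {
  structure(list(focal_chain_id = focal, included_partner = included,
                 excluded_partners = excluded, cutoff = cutoff,
                 exclusion_margin = margin, residues = character(0),
                 provenance = data.frame(), unresolved = character(0)),
            class = "sw_diffinterface")
}

#' @export
print.sw_diffinterface <- function(x, ...) {
  cat(sprintf(
    "<sw_diffinterface> %s: binds %s, clear of %s at %.1f+%.1f A: %d residues\n",
    x$focal_chain_id, x$included_partner,
    paste(x$excluded_partners, collapse = ","), x$cutoff, x$exclusion_margin,
    length(x$residues)))
  if (length(x$residues) > 0) cat("  ", paste(x$residues, collapse = " "), "\n")
  invisible(x)
}

#' Export a differential interface as TSV
#' @param diff an `sw_diffinterface`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_differential_tsv <- function(diff, path) {
  utils::write.table(diff$provenance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA by sphere-point counting: for each heavy atom, points on a
#' sphere of radius (vdW + probe) are tested for occlusion by neighbouring
#' atoms' probe-expanded spheres; the accessible fraction times the sphere
#' area gives the per-atom SASA.
#'
#' @param structure an [sw_structure()] (or `sw_chain`).
#' @param probe_radius probe radius (angstrom), default 1.4 (water).
#' @param n_points sphere points per atom (>= 92); default 960.
#' @return object of class `sw_sasa`: `atom_sasa` (per atom, in input
#'   order), `residue_sasa` (data frame `chain`, `resno`, `ins`, `label`,
#'   `resna`, `sasa`), `probe_radius`, `n_points`.
#' @export
sasa <- function(structure, probe_radius = 1.4, n_points = 960) {
  if (n_points < 92) stop("n_points must be >= 92")
  a <- as_atoms(structure)
  rad <- vdw_radius(a$elem)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  ri <- rad + probe_radius
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 > 0 & sqrt(d2) < ri[i] + rad + probe_radius)
    sp <- sweep(pts * ri[i], 2, xyz[i, ], "+")
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        if (all(buried)) break
        dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        buried <- buried | dj2 < (rad[j] + probe_radius)^2
      }
      acc <- sum(!buried)
    }
    area[i] <- 4 * pi * ri[i]^2 * acc / n_points
  }
  key <- paste(a$chain, a$resno, a$ins, sep = "\r")
  first <- !duplicated(key)
  res_sasa <- data.frame(
    chain = a$chain[first], resno = a$resno[first], ins = a$ins[first],
    label = resid_label(a$resno[first], a$ins[first]),
    resna = a$resna[first],
    sasa = as.numeric(tapply(area, key, sum)[unique(key)]),
    stringsAsFactors = FALSE
  )
  rownames(res_sasa) <- NULL
  structure(list(atom_sasa = area, residue_sasa = res_sasa,
                 probe_radius = probe_radius, n_points = n_points),
            class = "sw_sasa")
}

# parse an MSA into a named character vector of equal-length gapped rows
read_msa <- function(msa) {
  if (is.character(msa) && length(msa) == 1 && file.exists(msa)) {
    fmt <- if (grepl("\\.(sto|stk|stockholm)$", msa, ignore.case = TRUE)) {
      "stockholm"
    } else "fasta"
    aln <- Biostrings::readAAMultipleAlignment(msa, format = fmt)
    rows <- as.character(aln)
  } else if (is.character(msa)) {
    rows <- msa
  } else {
    stop("msa must be a file path or a named character vector of rows")
  }
  if (length(rows) < 2) stop("MSA needs at least 2 rows")
  if (length(unique(nchar(rows))) != 1) {
    stop("ragged MSA: rows differ in length")
  }
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    names(rows) <- paste0("row", seq_along(rows))
  }
  rows
}

#' Regions of a reference sequence absent from all orthologues
#'
#' Finds the maximal runs of alignment columns in which the reference row has
#' residues but every other row has a gap — insertions unique to the
#' reference species, such as partner loops present only in the organism
#' under study. Runs shorter than `min_len` reference residues are discarded
#' as alignment noise.
#'
#' @param msa aligned FASTA/Stockholm file path, or a named character vector
#'   of equal-length gapped rows.
#' @param reference_row name (or index) of the reference row.
#' @param min_len minimum number of reference residues per region; default 3.
#' @return object of class `sw_unique_regions`: `partner_id`, `regions`
#'   (data frame `start`, `end`, half-open, in ungapped reference
#'   numbering), `msa_id`.
#' @export
unique_regions <- function(msa, reference_row, min_len = 3) {
  rows <- read_msa(msa)
  if (is.numeric(reference_row)) reference_row <- names(rows)[reference_row]
  if (!reference_row %in% names(rows)) {
    stop("reference row '", reference_row, "' not in MSA")
  }
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  gaps <- mat %in% c("-", ".")
  dim(gaps) <- dim(mat)
  ref_i <- match(reference_row, names(rows))
  ref_res <- !gaps[ref_i, ]
  others_gap <- colSums(!gaps[-ref_i, , drop = FALSE]) == 0
  qualifying <- ref_res & others_gap

  ref_pos <- cumsum(ref_res)            # ungapped reference position per column
  r <- rle(qualifying)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  regions <- data.frame(start = integer(0), end = integer(0))
  for (k in keep) {
    cols <- starts[k]:ends[k]
    n_ref <- sum(ref_res[cols])
    if (n_ref >= min_len) {
      first_pos <- ref_pos[cols[1]]
      regions <- rbind(regions,
                       data.frame(start = first_pos,
                                  end = first_pos + n_ref))
    }
  }
  rownames(regions) <- NULL
  structure(list(partner_id = reference_row, regions = regions,
                 msa_id = if (is.character(msa) && length(msa) == 1) msa else "in-memory"),
            class = "sw_unique_regions")
}

#' Flag differential residues that touch unique partner regions
#'
#' Each differential residue is flagged `TRUE` iff at least one of its
#' contacts on the included partner falls inside a unique (orthologue-gap)
#' region of that partner. Partner residue numbering in the contact map must
#' correspond to the ungapped reference row numbering of the MSA.
#'
#' @param diff an `sw_diffinterface`.
#' @param unique_set an `sw_unique_regions` for the included partner.
#' @param cmap_1 the contact map (shared subunit vs included partner) that
#'   produced `diff`.
#' @return `diff` with a logical `unique_loop` column added to its
#'   provenance and a `unique_loop_flags` named logical vector.
#' @export
annotate_differential <- function(diff, unique_set, cmap_1) {
  regions <- unique_set$regions
  in_region <- function(resno) {
    if (nrow(regions) == 0) return(rep(FALSE, length(resno)))
    vapply(resno, function(r) any(r >= regions$start & r < regions$end),
           logical(1))
  }
  cc <- cmap_1$contacts
  flags <- vapply(diff$residues, function(lab) {
    partners <- cc$resno_b[cc$label_a == lab]
    length(partners) > 0 && any(in_region(partners))
  }, logical(1))
  names(flags) <- diff$residues
  diff$unique_loop_flags <- flags
  if (nrow(diff$provenance) > 0) {
    diff$provenance$unique_loop <-
      unname(flags[match(diff$provenance$label, names(flags))])
  }
  diff
}
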