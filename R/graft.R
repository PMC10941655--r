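# Template-based modelling by alignment-guided coordinate grafting, complex
# assembly, and residue mapping between the shared subunit of two models.
# Grafting deliberately replaces server-based homology modelling: the
# backbone is taken from the template with no loop building or minimisation,
# which is deterministic and sufficient for interface-residue identification
# (a backbone-proximity question).

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# ideal CB from backbone N, CA, C (tetrahedral, CA-CB 1.53 A)
ideal_cb <- function(n, ca, c) {
  nerf_place(c, n, ca, BB_GEOM$ca_cb, BB_GEOM$ang_n_ca_cb, BB_GEOM$dih_cb)
}

#' Thread a target sequence onto template coordinates
#'
#' For each aligned (target, template) residue pair, emits a residue carrying
#' the TARGET identity at the template's backbone coordinates, with author
#' numbering equal to the target sequence position. Identical residues keep
#' the template side chain; mismatches are truncated to N, CA, C, O, CB (the
#' CB built at ideal geometry if the template lacks one) rather than given
#' invented rotamers. Unaligned target residues are recorded as unmodelled,
#' never built.
#'
#' @param target_seq target one-letter sequence.
#' @param template_chain `sw_chain` providing coordinates.
#' @param alignment `sw_alignment` mapping target (a) to template (b)
#'   positions, 1-based over target letters / template residues present.
#' @param sidechain_policy `"keep_if_identical"` (default) or
#'   `"cb_truncate_all"`.
#' @return object of class `sw_grafted`: `chain` (the grafted `sw_chain`),
#'   `template_id`, `coverage`, `mismatch_positions`, `unmodelled_positions`.
#' @export
graft_model <- function(target_seq, template_chain, alignment,
                        sidechain_policy = c("keep_if_identical",
                                             "cb_truncate_all")) {
  sidechain_policy <- match.arg(sidechain_policy)
  check_protein_alphabet(target_seq, "target_seq")
  n_target <- nchar(target_seq)
  target_aa <- strsplit(target_seq, "")[[1]]
  rt <- residue_table(template_chain)
  pairs <- alignment$aligned_pairs
  dimnames(pairs) <- NULL

  bad <- pairs[, 2] > nrow(rt)
  if (any(bad)) {
    warning(sum(bad), " aligned positions beyond the template chain; ",
            "treated as unmodelled")
    pairs <- pairs[!bad, , drop = FALSE]
  }

  atoms_tmpl <- template_chain$atoms
  tmpl_key <- paste(atoms_tmpl$resno, atoms_tmpl$ins, sep = "\r")
  rt_key <- paste(rt$resno, rt$ins, sep = "\r")

  out_rows <- vector("list", nrow(pairs))
  modelled <- logical(n_target)
  mismatch <- integer(0)
  dropped <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    tpos <- pairs[k, 1]; mpos <- pairs[k, 2]
    res_atoms <- atoms_tmpl[tmpl_key == rt_key[mpos], , drop = FALSE]
    if (!all(c("N", "CA", "C") %in% res_atoms$atom)) {
      dropped <- c(dropped, tpos)
      next
    }
    aa <- target_aa[tpos]
    same <- identical(rt$one[mpos], aa)
    keep_sidechain <- same && sidechain_policy == "keep_if_identical"
    if (keep_sidechain) {
      res_out <- res_atoms
    } else {
      res_out <- res_atoms[res_atoms$atom %in% c(BACKBONE_ATOMS, "CB"), ,
                           drop = FALSE]
      if (aa == "G") {
        res_out <- res_out[res_out$atom != "CB", , drop = FALSE]
      } else if (!"CB" %in% res_out$atom) {
        p <- function(nm) unlist(res_atoms[res_atoms$atom == nm,
                                           c("x", "y", "z")][1, ])
        cb <- ideal_cb(p("N"), p("CA"), p("C"))
        res_out <- rbind(res_out, within(res_out[res_out$atom == "CA", ], {
          atom <- "CB"; elem <- "C"; x <- cb[1]; y <- cb[2]; z <- cb[3]
        }))
      }
    }
    res_out$resna <- AA_123[aa]
    res_out$resno <- tpos
    res_out$ins <- ""
    out_rows[[k]] <- res_out
    modelled[tpos] <- TRUE
    if (!same) mismatch <- c(mismatch, tpos)
  }
  atoms_out <- do.call(rbind, out_rows)
  if (is.null(atoms_out) || nrow(atoms_out) == 0) {
    stop("no residues could be modelled from this alignment")
  }
  if (length(dropped) > 0) {
    warning("template lacks backbone at target positions: ",
            paste(dropped, collapse = ", "), "; recorded as unmodelled")
  }
  atoms_out <- atoms_out[order(atoms_out$resno), , drop = FALSE]
  atoms_out$chain <- template_chain$chain_id
  rownames(atoms_out) <- NULL
  chain <- structure(list(chain_id = template_chain$chain_id,
                          entity_label = template_chain$entity_label,
                          atoms = atoms_out),
                     class = "sw_chain")
  structure(list(chain = chain,
                 template_id = template_chain$entity_label,
                 coverage = sum(modelled) / n_target,
                 mismatch_positions = mismatch,
                 unmodelled_positions = which(!modelled)),
            class = "sw_grafted")
}

#' @export
print.sw_grafted <- function(x, ...) {
  cat(sprintf(
    "<sw_grafted> chain %s from %s: coverage %.2f, %d mismatches, %d unmodelled\n",
    x$chain$chain_id, x$template_id, x$coverage,
    length(x$mismatch_positions), length(x$unmodelled_positions)))
  invisible(x)
}

#' Construct a complex model
#'
#' @param structure an [sw_structure()].
#' @param id model identifier (e.g. `"TORC1"`).
#' @param subunit_roles named character vector chain_id -> role, roles being
#'   `"shared_subunit"`, `"partner_specific"` or `"partner_shared"`; exactly
#'   one shared subunit and at least one specific partner are required.
#' @param provenance free-form list (template ids, per-chain rmsd, shifts).
#' @return object of class `sw_complex_model`.
#' @export
complex_model <- function(structure, id, subunit_roles, provenance = list()) {
  stopifnot(inherits(structure, "sw_structure"))
  cids <- chain_ids(structure)
  missing_chain <- setdiff(names(subunit_roles), cids)
  if (length(missing_chain) > 0) {
    stop("roles name chains absent from structure: ",
         paste(missing_chain, collapse = ", "))
  }
  valid <- c("shared_subunit", "partner_specific", "partner_shared")
  if (!all(subunit_roles %in% valid)) {
    stop("roles must be one of: ", paste(valid, collapse = ", "))
  }
  if (sum(subunit_roles == "shared_subunit") != 1) {
    stop("exactly one chain must have role 'shared_subunit'")
  }
  if (sum(subunit_roles == "partner_specific") < 1) {
    stop("at least one chain must have role 'partner_specific'")
  }
  structure(list(id = id, structure = structure,
                 subunit_roles = subunit_roles, provenance = provenance),
            class = "sw_complex_model")
}

#' @export
print.sw_complex_model <- function(x, ...) {
  cat("<sw_complex_model>", x$id, "\n")
  for (cid in names(x$subunit_roles)) {
    cat(sprintf("  %s: %s\n", cid, x$subunit_roles[[cid]]))
  }
  invisible(x)
}

shared_chain_id <- function(model) {
  names(model$subunit_roles)[model$subunit_roles == "shared_subunit"]
}

#' Assemble grafted chains into a complex model
#'
#' Superposes each grafted chain onto its designated template chain (CA
#' anchors through the graft's own target-template mapping), then relieves
#' residual inter-chain clashes by shifting each partner chain while the
#' shared subunit stays fixed. Provenance records the per-chain anchor rmsd
#' and shift.
#'
#' @param grafted named list of `sw_grafted` objects; names are template
#'   chain ids in `template_complex`.
#' @param template_complex the template [sw_structure()].
#' @param roles named character vector chain_id -> role (see
#'   [complex_model()]); must cover every grafted chain.
#' @param alignments named list of the `sw_alignment`s used for grafting
#'   (target -> template), same names as `grafted`.
#' @param id model identifier.
#' @param clash_args list of arguments passed on to [relieve_clashes()].
#' @return an `sw_complex_model`.
#' @export
assemble_complex <- function(grafted, template_complex, roles,
                             alignments, id = "model",
                             clash_args = list()) {
  if (is.null(names(grafted)) || any(!nzchar(names(grafted)))) {
    stop("'grafted' must be a named list keyed by template chain id")
  }
  missing_role <- setdiff(names(grafted), names(roles))
  if (length(missing_role) > 0) {
    stop("role map incomplete; missing roles for chain(s): ",
         paste(missing_role, collapse = ", "))
  }
  prov <- list(template_id = template_complex$id, chains = list())
  placed <- list()
  for (cid in names(grafted)) {
    g <- grafted[[cid]]
    tmpl_chain <- get_chain(template_complex, cid)
    aln <- alignments[[cid]]
    if (is.null(aln)) stop("no alignment supplied for chain '", cid, "'")
    # alignment 'a' positions are target positions = grafted author numbers;
    # re-index onto the residues actually present in the grafted chain
    present <- residue_table(g$chain)$resno
    pr <- aln$aligned_pairs
    a_idx <- match(pr[, 1], present)
    ok <- !is.na(a_idx)
    aln2 <- aln
    aln2$aligned_pairs <- cbind(a = a_idx[ok], b = pr[ok, 2])
    sp <- superpose_by_alignment(g$chain, tmpl_chain, aln2, atom = "CA")
    placed[[cid]] <- sp$chain
    prov$chains[[cid]] <- list(anchor_rmsd = sp$superposition$rmsd,
                               n_anchors = sp$superposition$n_pairs,
                               coverage = g$coverage)
  }
  atoms <- do.call(rbind, lapply(placed, function(ch) ch$atoms))
  rownames(atoms) <- NULL
  model_structure <- sw_structure(atoms, id = id, source_format = "generated")

  shared <- names(roles)[roles == "shared_subunit"]
  for (cid in setdiff(names(placed), shared)) {
    rc <- do.call(relieve_clashes,
                  c(list(complex = model_structure, movable_chain_id = cid),
                    clash_args))
    model_structure <- rc$structure
    prov$chains[[cid]]$shift <- rc$report$shift
    prov$chains[[cid]]$residual_overlap <- rc$report$residual_overlap
  }
  complex_model(model_structure, id = id,
                subunit_roles = roles[names(placed)], provenance = prov)
}

#' Map the shared subunit between two complex models
#'
#' Identity mapping by author residue number over positions present in both
#' models. Errors if the two models disagree on the residue identity at any
#' common position, since both must derive from the same target sequence.
#'
#' @param model_1,model_2 `sw_complex_model`s.
#' @return an `sw_alignment` whose `aligned_pairs` hold author residue
#'   numbers (model 1 side a, model 2 side b), with attributes `only_in_1`
#'   and `only_in_2` listing residues present in a single model.
#' @export
map_shared_subunit <- function(model_1, model_2) {
  c1 <- get_chain(model_1$structure, shared_chain_id(model_1))
  c2 <- get_chain(model_2$structure, shared_chain_id(model_2))
  rt1 <- residue_table(c1)
  rt2 <- residue_table(c2)
  common <- intersect(rt1$resno, rt2$resno)
  if (length(common) == 0) stop("shared subunits have no common residues")
  one1 <- rt1$one[match(common, rt1$resno)]
  one2 <- rt2$one[match(common, rt2$resno)]
  disagree <- common[one1 != one2]
  if (length(disagree) > 0) {
    stop("shared subunit residue identity disagrees at position(s): ",
         paste(utils::head(disagree, 10), collapse = ", "),
         " - both models must derive from the same target sequence")
  }
  out <- structure(
    list(seq_a_id = model_1$id, seq_b_id = model_2$id,
         seq_a = paste(one1, collapse = ""),
         seq_b = paste(one2, collapse = ""),
         row_a = paste(one1, collapse = ""),
         row_b = paste(one2, collapse = ""),
         aligned_pairs = cbind(a = common, b = common),
         score = NA_real_, n_columns = length(common),
         n_identical = length(common)),
    class = "sw_alignment"
  )
  attr(out, "only_in_1") <- setdiff(rt1$resno, common)
  attr(out, "only_in_2") <- setdiff(rt2$resno, common)
  out
}
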