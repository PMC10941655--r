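# End-to-end pipeline: read templates -> align -> graft -> assemble ->
# differential interface -> annotate -> propose -> clash/exposure filter ->
# group -> enumerate. Deterministic given config + inputs.

# evaluate a pipeline stage, prefixing errors with the stage name
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

default_config <- function() {
  list(
    seed = 1L,
    cutoff = 4.5,
    exclusion_margin = 1.5,
    exposure_threshold = 0.2,
    require_exposure = TRUE,
    require_clash = FALSE,
    grouping = list(method = "sequence_window", window_len = 10),
    msa = NULL, msa_reference = NULL,
    output_dir = NULL
  )
}

#' Load a run configuration
#'
#' @param config a YAML file path or a list; missing keys are filled with
#'   package defaults (cutoff 4.5 A, exclusion margin 1.5 A, exposure
#'   threshold 0.2, sequence-window grouping at 10 residues).
#' @return normalised config list.
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  utils::modifyList(default_config(), config)
}

# resolve a sequence entry: literal sequence string or FASTA path
resolve_sequence <- function(entry) {
  if (file.exists(entry) && !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", entry)) {
    unname(read_fasta_sequences(entry)[1])
  } else {
    toupper(entry)
  }
}

# build one complex model from a template path + chain role spec
build_model_from_template <- function(mspec, sequences, model_id) {
  tmpl <- stage("read", read_structure(mspec$template))
  shared <- mspec$shared
  specific <- mspec$included %||% mspec$specific
  extra <- setdiff(unlist(mspec$excluded), specific)
  extra <- intersect(extra, chain_ids(tmpl))
  chains <- c(shared, specific, extra)
  roles <- setNames(c("shared_subunit", "partner_specific",
                      rep("partner_shared", length(extra))), chains)
  grafted <- list(); alignments <- list()
  for (cid in chains) {
    tchain <- get_chain(tmpl, cid)
    tseq <- extract_sequence(tchain)
    target <- if (!is.null(sequences[[cid]])) {
      resolve_sequence(sequences[[cid]])
    } else tseq
    aln <- stage("align", if (identical(target, tseq)) {
      identity_alignment(target, tseq, seq_a_id = paste0(cid, "_target"),
                         seq_b_id = paste0(cid, "_template"))
    } else {
      global_align(target, tseq, seq_a_id = paste0(cid, "_target"),
                   seq_b_id = paste0(cid, "_template"))
    })
    grafted[[cid]] <- stage("graft", graft_model(target, tchain, aln))
    alignments[[cid]] <- aln
  }
  stage("assemble",
        assemble_complex(grafted, tmpl, roles, alignments, id = model_id))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fixture route: build both models from a synthetic two-partner complex
build_models_from_fixture <- function(fspec_cfg, seed) {
  fs <- fixture_spec(
    seed = fspec_cfg$seed %||% seed,
    n_res_focal = fspec_cfg$n_res_focal %||% 60L,
    partner_specs = list(
      list(partner_id = fspec_cfg$partner_1 %||% "B",
           contact_interval = as.integer(fspec_cfg$interval_1 %||% c(10L, 25L)),
           approach_distance = fspec_cfg$approach_distance %||% 3.8),
      list(partner_id = fspec_cfg$partner_2 %||% "C",
           contact_interval = as.integer(fspec_cfg$interval_2 %||% c(20L, 40L)),
           approach_distance = fspec_cfg$approach_distance %||% 3.8)),
    noise_sigma = fspec_cfg$noise_sigma %||% 0,
    sequence = fspec_cfg$sequence %||% NULL
  )
  fx <- make_two_partner_fixture(fs)
  p1 <- fs$partner_specs[[1]]$partner_id
  p2 <- fs$partner_specs[[2]]$partner_id
  list(
    model_1 = complex_model(fx$complex_1, "fixture_model_1",
                            setNames(c("shared_subunit", "partner_specific"),
                                     c("A", p1))),
    model_2 = complex_model(fx$complex_2, "fixture_model_2",
                            setNames(c("shared_subunit", "partner_specific"),
                                     c("A", p2))),
    included = p1, excluded = p2, truth = fx$truth
  )
}

#' Run the full specificity-switch design pipeline
#'
#' Executes the whole procedure on either a pair of template complexes
#' (config key `complexes`, with `model_1` carrying the partner whose
#' binding should be abolished) or a synthetic fixture (config key
#' `fixture`). Every decision is recorded in the returned design set; two
#' runs with the same config and inputs produce identical results.
#'
#' @param config list or YAML path; see [load_config()].
#' @return object of class `sw_design_set`: `proposals` (one row per
#'   differential residue with rule, clash and exposure evidence), `groups`,
#'   `combinations`, `target_region`, `differential`, `status`
#'   (`"ok"` or `"no-candidates"`), `config`.
#' @export
run_design <- function(config) {
  cfg <- load_config(config)

  if (!is.null(cfg$fixture)) {
    built <- stage("fixture", build_models_from_fixture(cfg$fixture, cfg$seed))
    model_1 <- built$model_1; model_2 <- built$model_2
    included <- built$included; excluded <- built$excluded
  } else if (!is.null(cfg$complexes)) {
    cspec <- cfg$complexes
    model_1 <- build_model_from_template(cspec$model_1, cfg$sequences,
                                         cspec$model_1$id %||% "model_1")
    model_2 <- build_model_from_template(cspec$model_2, cfg$sequences,
                                         cspec$model_2$id %||% "model_2")
    included <- cspec$model_1$included
    excluded <- unique(c(cspec$model_2$specific %||% character(0),
                         unlist(cspec$model_2$excluded),
                         unlist(cspec$model_1$excluded)))
    excluded <- setdiff(excluded, included)
  } else {
    stop("config needs either 'fixture' or 'complexes'")
  }

  shared_1 <- shared_chain_id(model_1)
  shared_map <- stage("map_shared", map_shared_subunit(model_1, model_2))
  diff <- stage("differential_interface",
                differential_interface(model_1, model_2, shared_map,
                                       included_partner = included,
                                       excluded_partners = excluded,
                                       cutoff = cfg$cutoff,
                                       exclusion_margin = cfg$exclusion_margin))
  cmap_1 <- contact_map(model_1$structure, shared_1, included, cfg$cutoff)
  if (!is.null(cfg$msa)) {
    uniq <- stage("unique_regions",
                  unique_regions(cfg$msa,
                                 cfg$msa_reference %||% 1L))
    diff <- stage("annotate", annotate_differential(diff, uniq, cmap_1))
  }

  if (length(diff$residues) == 0) {
    return(structure(list(proposals = data.frame(), groups = list(),
                          combinations = list(), target_region = c(NA, NA),
                          differential = diff, status = "no-candidates",
                          config = cfg),
                     class = "sw_design_set"))
  }

  rt <- residue_table(get_chain(model_1$structure, shared_1))
  props <- stage("propose", {
    rows <- lapply(diff$residues, function(lab) {
      i <- match(lab, rt$label)
      propose_mutation(rt$resno[i], rt$one[i])
    })
    do.call(rbind, rows)
  })

  props$clash_max <- NA_real_; props$clash_min <- NA_real_
  # one SASA evaluation of the shared subunit alone covers every proposal
  rel_prof <- stage("exposure",
                    relative_sasa_profile(get_chain(model_1$structure,
                                                    shared_1)))
  props$relative_sasa <-
    rel_prof$relative_sasa[match(props$position, rel_prof$resno)]
  props$exposed <- props$relative_sasa >= cfg$exposure_threshold
  for (k in seq_len(nrow(props))) {
    cr <- stage("clash_score",
                clash_score(model_1, props[k, ], included))
    props$clash_max[k] <- cr$max_overlap
    props$clash_min[k] <- cr$min_overlap
  }
  if (!is.null(diff$unique_loop_flags)) {
    props$unique_loop <- unname(
      diff$unique_loop_flags[match(diff$residues, names(diff$unique_loop_flags))])
  }

  keep <- rep(TRUE, nrow(props))
  if (isTRUE(cfg$require_exposure)) keep <- keep & props$exposed
  if (isTRUE(cfg$require_clash)) keep <- keep & props$clash_max > 0
  props$selected <- keep
  selected <- props[keep, , drop = FALSE]

  if (nrow(selected) == 0) {
    ds <- structure(list(proposals = props, groups = list(),
                         combinations = list(), target_region = c(NA, NA),
                         differential = diff, status = "no-candidates",
                         config = cfg),
                    class = "sw_design_set")
    return(ds)
  }

  gp <- cfg$grouping
  groups <- stage("group", group_targets(
    selected, method = gp$method %||% "sequence_window",
    window_len = gp$window_len %||% 10,
    partition = gp$partition, model = model_1,
    dist_cutoff = gp$dist_cutoff %||% 8))
  combos <- stage("enumerate", enumerate_combinations(groups))

  ds <- structure(
    list(proposals = props, groups = groups, combinations = combos,
         target_region = range(selected$position),
         differential = diff, status = "ok", config = cfg),
    class = "sw_design_set")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_design_report(ds, cfg$output_dir)
  }
  ds
}

#' @export
print.sw_design_set <- function(x, ...) {
  cat("<sw_design_set>", x$status, "\n")
  if (x$status == "ok") {
    sel <- x$proposals[x$proposals$selected, ]
    cat(sprintf("  target region %d..%d, %d proposals, %d groups, %d combinations\n",
                x$target_region[1], x$target_region[2], nrow(sel),
                length(x$groups), length(x$combinations)))
    cat("  ", paste(sprintf("%s%d%s", sel$wt_aa, sel$position, sel$mutant_aa),
                    collapse = " "), "\n")
  }
  invisible(x)
}

#' Write TSV + JSON design reports
#'
#' @param design an `sw_design_set`.
#' @param dir output directory (created if needed).
#' @return paths of the files written, invisibly.
#' @export
write_design_report <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "proposals.tsv")
  utils::write.table(design$proposals, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, "design.json")
  jsonlite::write_json(
    list(status = design$status,
         target_region = design$target_region,
         groups = design$groups,
         combinations = design$combinations,
         differential_residues = design$differential$residues,
         parameters = list(cutoff = design$config$cutoff,
                           exclusion_margin = design$config$exclusion_margin,
                           exposure_threshold = design$config$exposure_threshold,
                           seed = design$config$seed)),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}

#' Mutant sequences for each combination
#'
#' Applies each combination's substitutions to the wild-type sequence of the
#' shared subunit.
#'
#' @param design an `sw_design_set`.
#' @param wt_seq wild-type sequence, indexed by the proposals' author
#'   numbering (position i = letter i).
#' @param path optional FASTA output path.
#' @return named character vector of mutant sequences (one per combination).
#' @export
export_mutant_sequences <- function(design, wt_seq, path = NULL) {
  props <- design$proposals[design$proposals$selected, ]
  out <- vapply(names(design$combinations), function(nm) {
    s <- strsplit(wt_seq, "")[[1]]
    for (pos in design$combinations[[nm]]) {
      row <- props[props$position == pos, ]
      if (nrow(row) == 1 && pos <= length(s)) s[pos] <- row$mutant_aa
    }
    paste(s, collapse = "")
  }, character(1))
  if (!is.null(path)) write_fasta_sequences(out, path)
  out
}
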