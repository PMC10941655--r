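#' @import bio3d
#' @importFrom stats setNames
#' @importFrom utils read.table write.table
NULL

# three-letter -> one-letter code for the 20 standard amino acids
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_123 <- setNames(names(AA_321), unname(AA_321))

# common modified residues mapped to their parent amino acid ("mapped" mode)
AA_NONSTANDARD <- c(
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", HYP = "P",
  MLY = "K", CSO = "C", PCA = "E", KCX = "K"
)

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Construct a structure object
#'
#' A structure is a flat table of heavy atoms carrying the full
#' chain/residue/atom hierarchy in its columns, in the style of crystallographic
#' toolkits. Author residue numbering (plus insertion code) is the public
#' residue identifier throughout the package.
#'
#' @param atoms data frame with columns `chain`, `resno` (integer author
#'   numbering), `ins` (insertion code, `""` if none), `resna` (3-letter
#'   residue name), `atom` (atom name), `elem` (element symbol), `x`, `y`, `z`
#'   (angstroms), `occ` (occupancy).
#' @param id structure identifier.
#' @param source_format `"pdb"`, `"mmcif"` or `"generated"`.
#' @param metadata list; `title` and `resolution` are recognised.
#' @return object of class `sw_structure`.
#' @export
sw_structure <- function(atoms, id = "structure", source_format = "generated",
                         metadata = list()) {
  required <- c("chain", "resno", "ins", "resna", "atom", "elem",
                "x", "y", "z", "occ")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) {
    stop("empty structure: no atoms")
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    stop("non-finite coordinates in atoms table")
  }
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$ins <- ifelse(is.na(atoms$ins), "", as.character(atoms$ins))
  rownames(atoms) <- NULL
  structure(
    list(id = id, atoms = atoms, source_format = source_format,
         metadata = metadata),
    class = "sw_structure"
  )
}

#' @export
print.sw_structure <- function(x, ...) {
  ch <- chain_ids(x)
  cat("<sw_structure>", x$id, "(", x$source_format, ")\n")
  for (cid in ch) {
    a <- x$atoms[x$atoms$chain == cid, ]
    nres <- nrow(unique(a[, c("resno", "ins")]))
    cat(sprintf("  chain %s: %d residues, %d atoms\n", cid, nres, nrow(a)))
  }
  invisible(x)
}

#' Chain identifiers of a structure
#' @param structure an `sw_structure`.
#' @return character vector in order of first appearance.
#' @export
chain_ids <- function(structure) {
  unique(structure$atoms$chain)
}

#' Extract one chain from a structure
#' @param structure an `sw_structure`.
#' @param chain_id chain identifier.
#' @param entity_label optional free-text label (e.g. the subunit name).
#' @return object of class `sw_chain`.
#' @export
get_chain <- function(structure, chain_id, entity_label = chain_id) {
  a <- structure$atoms[structure$atoms$chain == chain_id, , drop = FALSE]
  if (nrow(a) == 0) {
    stop("chain '", chain_id, "' not present in structure '", structure$id, "'")
  }
  rownames(a) <- NULL
  structure(
    list(chain_id = chain_id, entity_label = entity_label, atoms = a),
    class = "sw_chain"
  )
}

#' @export
print.sw_chain <- function(x, ...) {
  cat(sprintf("<sw_chain> %s (%s): %d residues, %d atoms\n",
              x$chain_id, x$entity_label,
              nrow(residue_table(x)), nrow(x$atoms)))
  invisible(x)
}

# atoms table of either an sw_structure or an sw_chain
as_atoms <- function(x) {
  if (inherits(x, "sw_structure") || inherits(x, "sw_chain")) return(x$atoms)
  if (is.data.frame(x)) return(x)
  stop("expected an sw_structure, sw_chain or atoms data frame")
}

# residue label combining author number and insertion code, e.g. "740", "60A"
resid_label <- function(resno, ins) {
  paste0(resno, ifelse(is.na(ins) | ins == "", "", ins))
}

#' Per-residue table of a chain or structure
#'
#' @param x an `sw_chain` or `sw_structure`.
#' @return data frame with one row per residue in author order: `chain`,
#'   `resno`, `ins`, `label`, `resna`, `one` (one-letter code, `X` if
#'   nonstandard), `n_atoms`.
#' @export
residue_table <- function(x) {
  a <- as_atoms(x)
  key <- paste(a$chain, a$resno, a$ins, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(
    chain = a$chain[first], resno = a$resno[first], ins = a$ins[first],
    resna = a$resna[first],
    stringsAsFactors = FALSE
  )
  out$label <- resid_label(out$resno, out$ins)
  out$one <- unname(ifelse(out$resna %in% names(AA_321), AA_321[out$resna], "X"))
  out$n_atoms <- as.integer(table(key)[unique(key)])
  rownames(out) <- NULL
  out
}

# n x 3 coordinate matrix
atom_xyz <- function(x) {
  a <- as_atoms(x)
  m <- as.matrix(a[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

# element symbol from a PDB atom name when the element column is absent
element_from_name <- function(name) {
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA"),
         # only trust two-letter symbols for full-length names such as "SE";
         # "CA"/"CB" etc. are carbon
         ifelse(nchar(nm) == 2 & two %in% c("SE", "FE", "ZN", "MG", "CL", "BR"),
                two, substr(nm, 1, 1)),
         substr(nm, 1, 1))
}

sniff_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^(data_|loop_|_atom_site)", head_lines))) return("mmcif")
  if (any(grepl("^(ATOM|HETATM|HEADER|REMARK)", head_lines))) return("pdb")
  stop("cannot determine structure format of '", path, "'")
}

#' Read a macromolecular structure
#'
#' Reads PDB (fixed-column) or mmCIF files into the package's atom table.
#' Only the first model of multi-model files is kept. Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by altloc letter
#' order), waters are excluded and hydrogens are dropped by default, since all
#' downstream geometry (contacts, clashes, SASA) is heavy-atom based.
#'
#' @param path file path.
#' @param format `"auto"` (extension, then content sniffing), `"pdb"` or
#'   `"mmcif"`.
#' @param keep_hydrogens keep hydrogen/deuterium atoms (default `FALSE`).
#' @param keep_waters keep water molecules (default `FALSE`).
#' @return an [sw_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_hydrogens = FALSE, keep_waters = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- sniff_format(path)

  parsed <- withCallingHandlers(
    tryCatch(
      if (format == "pdb") {
        bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
      } else {
        bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
      },
      error = function(e) {
        stop("failed to parse '", path, "' as ", format, ": ",
             conditionMessage(e), call. = FALSE)
      }
    ),
    # advisory notices from the reader, not properties of the input
    warning = function(w) {
      if (grepl("beta version|helix/sheet", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0) stop("empty structure in '", path, "'")

  elem <- a$elesy
  if (is.null(elem)) elem <- rep("", nrow(a))
  elem <- toupper(trimws(elem))
  need <- is.na(elem) | elem == ""
  elem[need] <- element_from_name(a$elety[need])

  atoms <- data.frame(
    chain = as.character(a$chain),
    resno = as.integer(a$resno),
    ins = ifelse(is.na(a$insert), "", as.character(a$insert)),
    resna = toupper(trimws(as.character(a$resid))),
    atom = trimws(as.character(a$elety)),
    elem = elem,
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", as.character(a$alt)),
    stringsAsFactors = FALSE
  )
  atoms$chain[is.na(atoms$chain)] <- " "

  if (!keep_waters) atoms <- atoms[!(atoms$resna %in% WATER_NAMES), ]
  if (!keep_hydrogens) atoms <- atoms[!(atoms$elem %in% c("H", "D")), ]
  if (nrow(atoms) == 0) stop("empty structure in '", path,
                             "' after water/hydrogen filtering")

  # altloc resolution: within each (residue, atom name), keep the
  # highest-occupancy conformer, ties broken by altloc letter order
  if (any(atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom, sep = "\r")
    ord <- order(key, -atoms$occ, atoms$alt)
    atoms <- atoms[ord, ]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$ins,
                                     atoms$atom, sep = "\r")), ]
    # restore author order
    atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                         atoms$resno, atoms$ins, method = "radix"), ]
  }
  atoms$alt <- NULL

  metadata <- list()
  if (!is.null(parsed$header) && length(parsed$header) > 0) {
    metadata$title <- unname(parsed$header[1])
  }
  sw_structure(atoms,
               id = sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                        ignore.case = TRUE),
               source_format = format, metadata = metadata)
}

#' Write a structure to PDB or mmCIF
#'
#' Author numbering, insertion codes and chain identifiers are preserved.
#' The PDB writer enforces the format's single-character chain id limit.
#'
#' @param structure an [sw_structure()].
#' @param path output file path.
#' @param format `"pdb"` or `"mmcif"`; default chosen from the file extension.
#' @return the path, invisibly.
#' @export
write_structure <- function(structure, path,
                            format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  a <- structure$atoms
  if (nrow(a) == 0) stop("refusing to write an empty structure")

  if (format == "pdb") {
    if (any(nchar(a$chain) > 1)) {
      stop("PDB format allows single-character chain ids; offending: ",
           paste(unique(a$chain[nchar(a$chain) > 1]), collapse = ", "))
    }
    # PDB atom-name column convention: names of 1-3 characters for elements
    # with one-letter symbols start in column 14
    name_fmt <- ifelse(nchar(a$atom) >= 4 | nchar(a$elem) == 2,
                       sprintf("%-4s", a$atom),
                       sprintf(" %-3s", a$atom))
    lines <- sprintf(
      "ATOM  %5d %s%s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000L, name_fmt, " ", a$resna, a$chain, a$resno,
      ifelse(a$ins == "", " ", a$ins), a$x, a$y, a$z, a$occ, 0, a$elem
    )
    writeLines(c(lines, "END"), path)
  } else {
    ins <- ifelse(a$ins == "", "?", a$ins)
    lines <- sprintf(
      "ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
      seq_len(nrow(a)), a$elem, a$atom, a$resna, a$chain, a$resno, ins,
      a$x, a$y, a$z, a$occ, 0, a$resno, a$resna, a$chain, a$atom
    )
    header <- c(
      paste0("data_", gsub("[^A-Za-z0-9_-]", "_", structure$id)),
      "#", "loop_",
      paste0("_atom_site.",
             c("group_PDB", "id", "type_symbol", "label_atom_id",
               "label_alt_id", "label_comp_id", "label_asym_id",
               "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
               "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
               "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
               "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"))
    )
    writeLines(c(header, lines, "#"), path)
  }
  invisible(path)
}

#' One-letter sequence of a chain
#'
#' One letter per residue in author order. Chain breaks are not padded: the
#' sequence indexes the residues actually present, which is also the
#' convention used when mapping alignment positions back onto residues.
#'
#' @param chain an `sw_chain` (or single-chain `sw_structure`).
#' @param nonstandard `"strict"` maps any nonstandard residue to `X`;
#'   `"mapped"` translates common modified residues (e.g. MSE to M) via a
#'   fixed table, leaving the rest as `X`.
#' @return character scalar.
#' @export
extract_sequence <- function(chain, nonstandard = c("strict", "mapped")) {
  nonstandard <- match.arg(nonstandard)
  if (inherits(chain, "sw_structure")) {
    cid <- chain_ids(chain)
    if (length(cid) != 1) stop("structure has ", length(cid),
                               " chains; extract one with get_chain()")
    chain <- get_chain(chain, cid)
  }
  rt <- residue_table(chain)
  if (nrow(rt) == 0) stop("empty chain")
  one <- rt$one
  if (nonstandard == "mapped") {
    hit <- rt$resna %in% names(AA_NONSTANDARD)
    one[hit] <- AA_NONSTANDARD[rt$resna[hit]]
  }
  paste(one, collapse = "")
}

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta_sequences <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
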