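# PDB-format model input/output and the in-memory structure container used by
# every downstream stage. AI-predicted models (AlphaFold 2 / OpenFold /
# ESMFold style) carry per-residue pLDDT in the B-factor column; homology
# models may carry real B-factors, multiple chains and HETATM ligands.

AI_MODEL_TYPES <- c("alphafold2", "openfold", "esmfold")
MODEL_TYPES <- c(AI_MODEL_TYPES, "homology")

# Standard residue code tables. Nucleotide codes cover RNA and DNA
# single-letter/deoxy conventions used in PDB entries.
AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
NUCLEOTIDE_CODES <- c("A", "C", "G", "U", "T", "I",
                      "DA", "DC", "DG", "DT", "DU", "DI")

empty_atom_df <- function() {
  data.frame(serial = integer(), name = character(), resname = character(),
             chain = character(), resno = integer(), icode = character(),
             x = numeric(), y = numeric(), z = numeric(),
             occ = numeric(), b = numeric(), element = character(),
             stringsAsFactors = FALSE)
}

#' Construct a structure model
#'
#' The central in-memory container: protein atoms as a flat atom table
#' (one row per ATOM record), ligands as HETATM groups, and per-residue
#' pLDDT derived from harmonized B-factors for AI-predicted model types.
#'
#' @param atoms data.frame of protein atoms with columns `serial`, `name`,
#'   `resname`, `chain`, `resno`, `icode`, `x`, `y`, `z`, `occ`, `b`,
#'   `element`.
#' @param model_type one of `"alphafold2"`, `"openfold"`, `"esmfold"`,
#'   `"homology"`.
#' @param ligands list of ligand groups as produced by [read_model()]; each
#'   is a list with `het_id`, `chain`, `resno`, `icode`, `atoms`, `category`.
#' @param accession UniProt accession carried into the PDB HEADER on write.
#' @param description free-text protein description (PDB TITLE).
#' @param metadata named list of opaque pass-through values (e.g. template
#'   PDB id or z-score of a homology model).
#' @return an object of class `structure_model` with elements `atoms`,
#'   `residues` (one row per residue, with `plddt`), `ligands`, `accession`,
#'   `description`, `model_type`, `metadata`.
#' @export
structure_model <- function(atoms, model_type, ligands = list(),
                            accession = "UNKNOWN", description = "",
                            metadata = list()) {
  model_type <- match.arg(model_type, MODEL_TYPES)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) == 0L) stop("empty model: no protein atoms", call. = FALSE)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite atom coordinates", call. = FALSE)
  }
  if (any(atoms$serial < 1L)) stop("atom serial numbers must be >= 1", call. = FALSE)
  atoms$chain[is.na(atoms$chain) | atoms$chain == ""] <- "A"
  if (is.null(atoms$icode)) atoms$icode <- ""
  atoms$icode[is.na(atoms$icode)] <- ""

  rid <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
  first <- !duplicated(rid)
  residues <- data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
                         icode = atoms$icode[first], resname = atoms$resname[first],
                         stringsAsFactors = FALSE)
  # residue identity triples must be unique; a triple reappearing after an
  # interruption shows up as a duplicated run value
  if (anyDuplicated(rle(rid)$values)) {
    stop("duplicate residue (chain, resno, icode) triple", call. = FALSE)
  }

  if (model_type %in% AI_MODEL_TYPES) {
    if (length(unique(residues$chain)) > 1L) {
      stop("AI-predicted models must contain a single protein chain", call. = FALSE)
    }
    raw <- atoms$b[first]
    if (any(is.na(raw))) stop("missing B-factor/pLDDT value", call. = FALSE)
    residues$plddt <- harmonize_plddt_scale(raw)
  } else {
    residues$plddt <- NA_real_
  }

  structure(list(accession = accession, description = description,
                 model_type = model_type, atoms = atoms, residues = residues,
                 ligands = ligands, metadata = metadata),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s (%s)\n", x$accession, x$model_type))
  cat(sprintf("  %d residues in %d chain(s), %d atoms, %d ligand(s)\n",
              nrow(x$residues), length(unique(x$residues$chain)),
              nrow(x$atoms), length(x$ligands)))
  if (x$model_type %in% AI_MODEL_TYPES) {
    cat(sprintf("  pLDDT median %.1f [%.1f, %.1f]\n",
                stats::median(x$residues$plddt), min(x$residues$plddt),
                max(x$residues$plddt)))
  }
  invisible(x)
}

#' Harmonize pLDDT scores onto the percent scale
#'
#' Some prediction services emit pLDDT as fractions in \[0, 1\] (e.g. 0.953)
#' while others emit percentages (e.g. 95.32). If every value is <= 1 the
#' whole profile is taken to be fractional and multiplied by 100; output is
#' clipped to \[0, 100\]. The operation is idempotent.
#'
#' @param raw_bfactors numeric vector of raw per-residue B-factor values,
#'   all >= 0.
#' @return numeric vector on the 0-100 percent scale.
#' @export
harmonize_plddt_scale <- function(raw_bfactors) {
  if (length(raw_bfactors) == 0L) stop("empty pLDDT vector", call. = FALSE)
  if (any(!is.finite(raw_bfactors)) || any(raw_bfactors < 0)) {
    stop("pLDDT values must be finite and non-negative", call. = FALSE)
  }
  out <- if (max(raw_bfactors) <= 1.0) raw_bfactors * 100 else raw_bfactors
  pmin(pmax(out, 0), 100)
}

categorize_het <- function(resname) {
  if (resname %in% NUCLEOTIDE_CODES) return("nucleic_acid")
  if (resname %in% names(AA3)) return("hetatm_amino_acid")
  "small_molecule"
}

parse_pdb_atom_fields <- function(lines, lineno) {
  num <- function(s) suppressWarnings(as.numeric(s))
  x <- num(substr(lines, 31, 38))
  y <- num(substr(lines, 39, 46))
  z <- num(substr(lines, 47, 54))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    stop(sprintf("malformed coordinate field at line %d", lineno[bad[1]]),
         call. = FALSE)
  }
  occ <- num(substr(lines, 55, 60)); occ[is.na(occ)] <- 1
  b <- num(substr(lines, 61, 66)); b[is.na(b)] <- 0
  data.frame(
    serial = as.integer(num(substr(lines, 7, 11))),
    name = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    resno = as.integer(num(substr(lines, 23, 26))),
    icode = trimws(substr(lines, 27, 27)),
    x = x, y = y, z = z, occ = occ, b = b,
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE)
}

#' Read a PDB model file
#'
#' Parses ATOM records into the protein atom table and HETATM records into
#' ligand groups keyed by (het id, chain, residue number). Waters (HOH) are
#' dropped. Only the first MODEL of a multi-model file is read. For AI model
#' types the B-factor column is interpreted as per-residue pLDDT and
#' harmonized onto the percent scale.
#'
#' @param path path to a PDB file.
#' @param model_type model-type tag, see [structure_model()].
#' @return a `structure_model`.
#' @export
read_model <- function(path, model_type) {
  model_type <- match.arg(model_type, MODEL_TYPES)
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)

  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]

  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  "
  is_het <- rec == "HETATM"
  if (!any(is_atom)) stop(sprintf("empty model: no ATOM records in '%s'", path),
                          call. = FALSE)

  accession <- "UNKNOWN"
  description <- ""
  hdr <- grep("^HEADER", lines, value = TRUE)
  if (length(hdr)) {
    tok <- strsplit(trimws(substr(hdr[1], 11, 80)), "\\s+")[[1]]
    if (length(tok)) accession <- tok[length(tok)]
  }
  ttl <- grep("^TITLE ", lines, value = TRUE)
  if (length(ttl)) description <- trimws(paste(substr(ttl, 11, 80), collapse = " "))

  sel <- which(is_atom | is_het)
  fields <- parse_pdb_atom_fields(lines[sel], sel)
  fields$hetatm <- is_het[sel]
  # keep only first alternate location
  fields <- fields[fields$altloc %in% c("", " ", "A"), , drop = FALSE]
  fields$altloc <- NULL

  prot <- fields[!fields$hetatm, setdiff(names(fields), "hetatm"), drop = FALSE]
  het <- fields[fields$hetatm & fields$resname != "HOH",
                setdiff(names(fields), "hetatm"), drop = FALSE]

  ligands <- list()
  if (nrow(het)) {
    key <- paste(het$resname, het$chain, het$resno, het$icode, sep = "|")
    for (k in unique(key)) {
      g <- het[key == k, , drop = FALSE]
      ligands[[length(ligands) + 1L]] <- list(
        het_id = g$resname[1], chain = g$chain[1], resno = g$resno[1],
        icode = g$icode[1], atoms = g, category = categorize_het(g$resname[1]))
    }
  }

  structure_model(prot, model_type = model_type, ligands = ligands,
                  accession = accession, description = description)
}

fmt_atom_name <- function(name, element) {
  # element symbols occupy columns 13-14 right-justified; common organic
  # atoms with 1-char elements start in column 14
  if (nchar(name) >= 4L) return(substr(name, 1, 4))
  if (nchar(element) == 2L) sprintf("%-4s", name) else sprintf(" %-3s", name)
}

format_atom_record <- function(rec_type, a) {
  sprintf("%-6s%5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec_type, a$serial %% 100000L, fmt_atom_name(a$name, a$element),
          a$resname, a$chain, a$resno %% 10000L, ifelse(a$icode == "", " ", a$icode),
          a$x, a$y, a$z, a$occ, a$b, a$element)
}

#' Write a structure model as PDB
#'
#' Emits HEADER (accession), TITLE (description), ATOM records at standard
#' PDB precision (coordinates 3 decimals, B-factor/pLDDT 2 decimals), TER
#' after each protein chain and HETATM records for ligands after all ATOM
#' records. Reading the written file back reproduces coordinates and
#' B-factors at that precision.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  out <- c(sprintf("%-10s%s", "HEADER", model$accession),
           sprintf("%-10s%s", "TITLE", model$description))
  atoms <- model$atoms
  serial <- 0L
  for (ch in unique(atoms$chain)) {
    ca <- atoms[atoms$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(ca))) {
      serial <- serial + 1L
      a <- ca[i, ]; a$serial <- serial
      out <- c(out, format_atom_record("ATOM", a))
    }
    last <- ca[nrow(ca), ]
    serial <- serial + 1L
    out <- c(out, sprintf("TER   %5d      %3s %1s%4d", serial %% 100000L,
                          last$resname, last$chain, last$resno %% 10000L))
  }
  for (lig in model$ligands) {
    la <- lig$atoms
    for (i in seq_len(nrow(la))) {
      serial <- serial + 1L
      a <- la[i, ]; a$serial <- serial
      out <- c(out, format_atom_record("HETATM", a))
    }
  }
  out <- c(out, "END")
  tryCatch(writeLines(out, path),
           error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                            conditionMessage(e)), call. = FALSE))
  invisible(path)
}

MODEL_TYPE_LABELS <- c(alphafold2 = "AlphaFold2", openfold = "OpenFold",
                       esmfold = "ESMFold")

#' Dataset file name for a model at a given refinement stage
#'
#' Reproduces the deposited-file naming scheme: homology models are
#' `HM_[accession].pdb`; AI models are `[model_type]_[accession].pdb` with
#' stage prefixes `relaxed_`, `refined_`, `ligand_integrated_relaxed_` and
#' `ligand_integrated_refined_`.
#'
#' @param model_type see [structure_model()].
#' @param accession UniProt accession, non-empty.
#' @param stage one of `"native"`, `"relaxed"`, `"refined"`,
#'   `"relaxed_ligand"`, `"refined_ligand"`, `"homology"`.
#' @return file name string.
#' @export
dataset_filename <- function(model_type, accession, stage) {
  if (!nzchar(accession)) stop("empty accession", call. = FALSE)
  stage <- match.arg(stage, c("native", "relaxed", "refined",
                              "relaxed_ligand", "refined_ligand", "homology"))
  if (stage == "homology" || model_type == "homology") {
    if (stage != "homology" || model_type != "homology") {
      stop("stage 'homology' requires model_type 'homology'", call. = FALSE)
    }
    return(sprintf("HM_%s.pdb", accession))
  }
  label <- MODEL_TYPE_LABELS[[match.arg(model_type, AI_MODEL_TYPES)]]
  prefix <- switch(stage,
                   native = "",
                   relaxed = "relaxed_",
                   refined = "refined_",
                   relaxed_ligand = "ligand_integrated_relaxed_",
                   refined_ligand = "ligand_integrated_refined_")
  sprintf("%s%s_%s.pdb", prefix, label, accession)
}

# --- accessors used across modules ---------------------------------------

residue_key <- function(df) paste(df$chain, df$resno, df$icode, sep = "|")

#' One-letter amino-acid sequence of a chain
#' @param model a `structure_model`.
#' @param chain chain id; default first chain.
#' @return character scalar; unknown residue names become `"X"`.
#' @export
model_sequence <- function(model, chain = NULL) {
  res <- model$residues
  if (is.null(chain)) chain <- res$chain[1]
  rn <- res$resname[res$chain == chain]
  one <- AA3[rn]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' C-alpha coordinates of a chain
#' @inheritParams model_sequence
#' @return n x 3 matrix, one row per residue (NA rows where CA is absent).
#' @export
ca_coords <- function(model, chain = NULL) {
  res <- model$residues
  if (is.null(chain)) chain <- res$chain[1]
  res <- res[res$chain == chain, , drop = FALSE]
  at <- model$atoms[model$atoms$chain == chain & model$atoms$name == "CA", ,
                    drop = FALSE]
  m <- matrix(NA_real_, nrow(res), 3)
  idx <- match(residue_key(res), residue_key(at))
  ok <- !is.na(idx)
  m[ok, ] <- as.matrix(at[idx[ok], c("x", "y", "z")])
  m
}

atom_xyz <- function(df) unname(as.matrix(df[, c("x", "y", "z")]))

#' Subset a model to a residue mask
#'
#' Pure deletion: keeps the atoms of the selected residues with coordinates
#' untouched; ligands and metadata are carried over.
#'
#' @param model a `structure_model`.
#' @param keep logical vector over `model$residues`.
#' @return a `structure_model` containing only the kept residues.
#' @export
subset_residues <- function(model, keep) subset_model_residues(model, keep)

# internal name used throughout the package
subset_model_residues <- function(model, keep) {
  stopifnot(length(keep) == nrow(model$residues))
  keys <- residue_key(model$residues)[keep]
  sel <- residue_key(model$atoms) %in% keys
  structure_model(model$atoms[sel, , drop = FALSE], model$model_type,
                  ligands = model$ligands, accession = model$accession,
                  description = model$description, metadata = model$metadata)
}
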