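# Per-model and cross-model quality statistics: pLDDT summaries,
# Ramachandran dihedrals, a simple dihedral-region secondary-structure
# assignment, pairwise inter-model RMSD and the CSV statistics report.

#' pLDDT summary statistics of a model
#'
#' Minimum, quartiles (linear interpolation between order statistics) and
#' maximum of the per-residue pLDDT profile, plus the percentage of residues
#' strictly above 90 and strictly above 70.
#'
#' @param model a `structure_model` with per-residue pLDDT.
#' @return named list: `n_residues`, `plddt_min`, `plddt_q1`,
#'   `plddt_median`, `plddt_q3`, `plddt_max`, `pct_above_90`,
#'   `pct_above_70`.
#' @export
plddt_summary <- function(model) {
  p <- model$residues$plddt
  if (!length(p) || any(is.na(p))) {
    stop("model lacks per-residue pLDDT", call. = FALSE)
  }
  q <- stats::quantile(p, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n_residues = length(p), plddt_min = min(p), plddt_q1 = q[1],
       plddt_median = q[2], plddt_q3 = q[3], plddt_max = max(p),
       pct_above_90 = 100 * mean(p > 90), pct_above_70 = 100 * mean(p > 70))
}

#' Backbone dihedral angles (Ramachandran)
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).
#' Neighbours must be consecutive in residue numbering within the same
#' chain; terminal residues lack the corresponding angle (NA). Residues with
#' missing backbone atoms are skipped with a warning.
#'
#' @param model a `structure_model`.
#' @return data.frame with `chain`, `resno`, `resname`, `phi`, `psi`
#'   (degrees in (-180, 180\]).
#' @export
ramachandran <- function(model) {
  res <- model$residues
  at <- model$atoms
  akey <- paste(residue_key(at), at$name)
  get_atom <- function(i, name) {
    j <- match(paste(residue_key(res)[i], name), akey)
    if (is.na(j)) return(NULL)
    c(at$x[j], at$y[j], at$z[j])
  }
  n <- nrow(res)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  skipped <- FALSE
  for (i in seq_len(n)) {
    Ni <- get_atom(i, "N"); CAi <- get_atom(i, "CA"); Ci <- get_atom(i, "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) {
      skipped <- TRUE
      next
    }
    prev_ok <- i > 1L && res$chain[i - 1L] == res$chain[i] &&
      res$resno[i - 1L] == res$resno[i] - 1L
    next_ok <- i < n && res$chain[i + 1L] == res$chain[i] &&
      res$resno[i + 1L] == res$resno[i] + 1L
    if (prev_ok) {
      Cp <- get_atom(i - 1L, "C")
      if (!is.null(Cp)) phi[i] <- dihedral_angle(Cp, Ni, CAi, Ci)
    }
    if (next_ok) {
      Nn <- get_atom(i + 1L, "N")
      if (!is.null(Nn)) psi[i] <- dihedral_angle(Ni, CAi, Ci, Nn)
    }
  }
  if (skipped) warning("residues with missing backbone atoms were skipped")
  data.frame(chain = res$chain, resno = res$resno, resname = res$resname,
             phi = phi, psi = psi, stringsAsFactors = FALSE)
}

#' Secondary-structure fractions from backbone dihedrals
#'
#' Deliberately simple dihedral-region assignment (not DSSP): helix for
#' phi in (-100, -30) and psi in (-80, -5); strand for phi in (-180, -100)
#' and psi in (90, 180\] or (-180, -170); coil otherwise. Runs shorter than
#' 3 residues are reassigned to coil. Fractions are over residues with both
#' dihedrals defined and sum to 100.
#'
#' @param model a `structure_model`.
#' @return named list `helix`, `strand`, `coil` (percent).
#' @export
secondary_structure_fractions <- function(model) {
  rama <- ramachandran(model)
  ok <- !is.na(rama$phi) & !is.na(rama$psi)
  if (!any(ok)) return(list(helix = 0, strand = 0, coil = 100))
  phi <- rama$phi[ok]; psi <- rama$psi[ok]
  ss <- rep("coil", length(phi))
  ss[phi > -100 & phi < -30 & psi > -80 & psi < -5] <- "helix"
  ss[phi > -180 & phi < -100 &
       ((psi > 90 & psi <= 180) | (psi > -180 & psi < -170))] <- "strand"
  runs <- rle(ss)
  runs$values[runs$lengths < 3L & runs$values != "coil"] <- "coil"
  ss <- inverse.rle(runs)
  list(helix = 100 * mean(ss == "helix"),
       strand = 100 * mean(ss == "strand"),
       coil = 100 * mean(ss == "coil"))
}

#' Pairwise RMSD matrix between models of one protein
#'
#' For each pair, residues are corresponded by sequence position (residue
#' number) common to both models — homology models may cover only a
#' subsequence — then Kabsch-fitted on CA atoms. Pairs with fewer than 3
#' common residues get NA.
#'
#' @param models list of >= 2 `structure_model`s sharing an accession.
#' @return symmetric matrix of RMSDs (Angstrom) with zero diagonal.
#' @export
pairwise_model_rmsd <- function(models) {
  if (length(models) < 2L) stop("need at least 2 models", call. = FALSE)
  accs <- vapply(models, `[[`, character(1), "accession")
  if (length(unique(accs)) != 1L) {
    stop("models must share one accession", call. = FALSE)
  }
  n <- length(models)
  m <- matrix(0, n, n)
  labels <- vapply(models, `[[`, character(1), "model_type")
  dimnames(m) <- list(labels, labels)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ri <- models[[i]]$residues; rj <- models[[j]]$residues
      ci <- ri$chain[1]; cj <- rj$chain[1]
      ni <- ri$resno[ri$chain == ci]; nj <- rj$resno[rj$chain == cj]
      common <- intersect(ni, nj)
      if (length(common) < 3L) {
        m[i, j] <- m[j, i] <- NA_real_
        next
      }
      xi <- ca_coords(models[[i]], ci)[match(common, ni), , drop = FALSE]
      xj <- ca_coords(models[[j]], cj)[match(common, nj), , drop = FALSE]
      ok <- stats::complete.cases(xi) & stats::complete.cases(xj)
      if (sum(ok) < 3L) {
        m[i, j] <- m[j, i] <- NA_real_
        next
      }
      fit <- kabsch_fit(xi[ok, , drop = FALSE], xj[ok, , drop = FALSE])
      m[i, j] <- m[j, i] <- fit$rmsd
    }
  }
  m
}

#' Per-model statistics row
#'
#' One row of the statistics report for a single model: pLDDT summary (AI
#' models), ligand list, sequence coverage (homology models: monomer length
#' over full sequence length), secondary-structure fractions and opaque
#' pass-through quality metadata (z-score, template).
#'
#' @param model a `structure_model`.
#' @param full_sequence_length optional full-length protein sequence size
#'   used for homology coverage; defaults to the model's own length.
#' @return one-row data.frame.
#' @export
model_stats <- function(model, full_sequence_length = NULL) {
  res <- model$residues
  chains <- unique(res$chain)
  monomer_len <- sum(res$chain == chains[1])
  if (is.null(full_sequence_length)) full_sequence_length <- monomer_len
  cov <- floor(100 * monomer_len / full_sequence_length * 100 + 0.5) / 100
  is_ai <- model$model_type %in% AI_MODEL_TYPES
  ps <- if (is_ai) plddt_summary(model) else
    list(plddt_min = NA_real_, plddt_q1 = NA_real_, plddt_median = NA_real_,
         plddt_q3 = NA_real_, plddt_max = NA_real_, pct_above_90 = NA_real_,
         pct_above_70 = NA_real_)
  ss <- secondary_structure_fractions(model)
  lig <- paste(vapply(model$ligands, `[[`, character(1), "het_id"),
               collapse = ";")
  z <- model$metadata$z_score
  data.frame(accession = model$accession, model_type = model$model_type,
             n_residues = nrow(res), n_chains = length(chains),
             plddt_min = ps$plddt_min, plddt_q1 = ps$plddt_q1,
             plddt_median = ps$plddt_median, plddt_q3 = ps$plddt_q3,
             plddt_max = ps$plddt_max, pct_above_90 = ps$pct_above_90,
             pct_above_70 = ps$pct_above_70,
             sequence_coverage = cov, ligands = lig,
             z_score = if (is.null(z)) NA_real_ else as.numeric(z),
             helix_pct = ss$helix, strand_pct = ss$strand,
             coil_pct = ss$coil, stringsAsFactors = FALSE)
}

#' Write the statistics report CSV
#'
#' One row per model with a stable column order and RFC 4180 quoting.
#'
#' @param stats data.frame of rows from [model_stats()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_statistics_csv <- function(stats, path) {
  cols <- c("accession", "model_type", "n_residues", "n_chains",
            "plddt_min", "plddt_q1", "plddt_median", "plddt_q3", "plddt_max",
            "pct_above_90", "pct_above_70", "sequence_coverage", "ligands",
            "z_score", "helix_pct", "strand_pct", "coil_pct")
  if (nrow(stats) == 0L) {
    stats <- stats[, intersect(cols, names(stats)), drop = FALSE]
    for (cc in setdiff(cols, names(stats))) stats[[cc]] <- character(0)
  }
  utils::write.csv(stats[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = which(cols %in% c("accession", "model_type",
                                             "ligands")), na = "")
  invisible(path)
}
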