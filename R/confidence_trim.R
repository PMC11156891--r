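# Removal of low-confidence regions from AI-predicted models: windowed
# pLDDT averaging flags residues, flagged residues split chains into
# retained segments, and detached segments are pruned geometrically against
# the protein core (the largest retained segment). Trimming is pure
# deletion: no retained coordinate is ever modified.

#' Trimming policy
#'
#' Bundles the thresholds of the low-confidence removal procedure. Defaults:
#' pLDDT averaged over +/- 3 residues, removal below 70, detached segments
#' dropped when more than 10 A from the core unless within 5 A of a segment
#' that is itself within 10 A of the core, models with fewer than 10
#' surviving residues dropped, ligands kept only within 5 A of the trimmed
#' protein.
#'
#' @param window_halfwidth half-width of the pLDDT averaging window
#'   (residues).
#' @param plddt_threshold removal threshold on the window average; residues
#'   strictly below are flagged.
#' @param core_distance maximum segment-to-core distance (Angstrom).
#' @param chain_distance maximum segment-to-bridging-segment distance
#'   (Angstrom).
#' @param min_residues minimum surviving residue count; below it the whole
#'   model is dropped.
#' @param ligand_retention_distance maximum ligand-to-protein distance after
#'   trimming (Angstrom).
#' @param distance_atoms `"all"` (heavy-atom minimum, default) or `"ca"`.
#' @return object of class `trim_policy`.
#' @export
trim_policy <- function(window_halfwidth = 3L, plddt_threshold = 70,
                        core_distance = 10, chain_distance = 5,
                        min_residues = 10L, ligand_retention_distance = 5,
                        distance_atoms = c("all", "ca")) {
  stopifnot(window_halfwidth >= 1, plddt_threshold > 0, plddt_threshold < 100,
            core_distance > 0, chain_distance > 0, min_residues >= 1,
            ligand_retention_distance > 0)
  structure(list(window_halfwidth = as.integer(window_halfwidth),
                 plddt_threshold = plddt_threshold,
                 core_distance = core_distance,
                 chain_distance = chain_distance,
                 min_residues = as.integer(min_residues),
                 ligand_retention_distance = ligand_retention_distance,
                 distance_atoms = match.arg(distance_atoms)),
            class = "trim_policy")
}

#' Windowed average of a per-residue pLDDT profile
#'
#' `out[i]` is the arithmetic mean of the profile over positions
#' `i - halfwidth .. i + halfwidth`, with the window truncated at the chain
#' termini.
#'
#' @param plddt numeric per-residue profile (one chain), non-empty.
#' @param halfwidth window half-width in residues.
#' @return numeric vector of the same length.
#' @export
window_average_plddt <- function(plddt, halfwidth = 3L) {
  n <- length(plddt)
  if (n == 0L) stop("empty pLDDT profile", call. = FALSE)
  cs <- cumsum(c(0, plddt))
  lo <- pmax(seq_len(n) - halfwidth, 1L)
  hi <- pmin(seq_len(n) + halfwidth, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Flag residues whose window-averaged pLDDT falls below threshold
#'
#' Strict comparison: a residue exactly at the threshold is retained.
#'
#' @param window_avgs windowed averages from [window_average_plddt()].
#' @param threshold removal threshold.
#' @return logical removal mask.
#' @export
flag_low_confidence <- function(window_avgs, threshold = 70) {
  window_avgs < threshold
}

#' Partition retained residues into contiguous segments
#'
#' Maximal runs of consecutive retained residues, split wherever a flagged
#' residue or a chain boundary intervenes.
#'
#' @param model a `structure_model`.
#' @param mask logical removal mask aligned to `model$residues`.
#' @return list of segments; each has `chain`, `start_index`, `end_index`
#'   (positions in the original residue ordering, inclusive).
#' @export
segment_partition <- function(model, mask) {
  res <- model$residues
  stopifnot(length(mask) == nrow(res))
  segs <- list()
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch & !mask)
    if (!length(idx)) next
    brk <- c(0L, which(diff(idx) != 1L), length(idx))
    for (k in seq_len(length(brk) - 1L)) {
      run <- idx[(brk[k] + 1L):brk[k + 1L]]
      segs[[length(segs) + 1L]] <- list(chain = ch, start_index = run[1],
                                        end_index = run[length(run)])
    }
  }
  segs
}

# coordinates of all atoms (or CAs) of the residues of one segment
segment_xyz <- function(model, seg, distance_atoms = "all") {
  keys <- residue_key(model$residues)[seg$start_index:seg$end_index]
  at <- model$atoms
  if (distance_atoms == "ca") at <- at[at$name == "CA", , drop = FALSE]
  atom_xyz(at[residue_key(at) %in% keys, , drop = FALSE])
}

#' Geometric pruning of detached segments
#'
#' The core is the segment with the most residues (ties: lowest start
#' index). A non-core segment is kept iff its minimum inter-atomic distance
#' to the core is within `core_distance`, or it lies within `chain_distance`
#' of some segment that is itself within `core_distance` of the core (one
#' bridging hop, not iterated).
#'
#' @param model a `structure_model` (supplies the atom coordinates).
#' @param segments list of segments from [segment_partition()].
#' @param policy a [trim_policy()].
#' @return list with `kept` and `removed` segment lists.
#' @export
geometric_prune <- function(model, segments, policy = trim_policy()) {
  if (!length(segments)) return(list(kept = list(), removed = list()))
  sizes <- vapply(segments, function(s) as.numeric(s$end_index - s$start_index + 1),
                  numeric(1))
  starts <- vapply(segments, function(s) as.numeric(s$start_index), numeric(1))
  core_i <- order(-sizes, starts)[1]
  xyz <- lapply(segments, segment_xyz, model = model,
                distance_atoms = policy$distance_atoms)
  n <- length(segments)
  core_dist <- vapply(seq_len(n), function(i) {
    if (i == core_i) 0 else min_pair_dist(xyz[[i]], xyz[[core_i]])
  }, numeric(1))
  near_core <- core_dist <= policy$core_distance
  keep <- near_core
  for (i in which(!near_core)) {
    for (j in which(near_core & seq_len(n) != i)) {
      if (min_pair_dist(xyz[[i]], xyz[[j]]) <= policy$chain_distance) {
        keep[i] <- TRUE
        break
      }
    }
  }
  list(kept = segments[keep], removed = segments[!keep])
}

#' Discard ligands no longer contacting the protein
#'
#' A ligand survives iff at least one of its atoms is within
#' `ligand_retention_distance` of at least one protein atom.
#'
#' @param model a `structure_model`.
#' @param policy a [trim_policy()].
#' @return the model with distant ligands removed; attribute
#'   `"ligands_dropped"` lists the het ids removed.
#' @export
ligand_retention_filter <- function(model, policy = trim_policy()) {
  if (!length(model$ligands)) return(model)
  prot <- atom_xyz(model$atoms)
  keep <- vapply(model$ligands, function(lig) {
    min_pair_dist(atom_xyz(lig$atoms), prot) <= policy$ligand_retention_distance
  }, logical(1))
  dropped <- vapply(model$ligands[!keep], `[[`, character(1), "het_id")
  model$ligands <- model$ligands[keep]
  attr(model, "ligands_dropped") <- dropped
  model
}

#' Trim low-confidence regions from an AI-predicted model
#'
#' Single-pass composition: window-average the per-residue pLDDT profile on
#' the intact chains, flag residues strictly below the threshold, partition
#' the retained residues into segments, geometrically prune detached
#' segments, and apply the ligand retention filter. If fewer than
#' `min_residues` residues survive the model is dropped.
#'
#' @param model a `structure_model` with per-residue pLDDT.
#' @param policy a [trim_policy()].
#' @return list with `model` (trimmed `structure_model`, or `NULL` when
#'   dropped) and `report`, a list with `removed_by_plddt`,
#'   `removed_by_geometry` (residue index vectors), `segments_kept`,
#'   `model_dropped`, `ligands_dropped`.
#' @export
trim_model <- function(model, policy = trim_policy()) {
  res <- model$residues
  if (any(is.na(res$plddt))) {
    stop("model has residues without pLDDT; trimming needs per-residue confidence",
         call. = FALSE)
  }
  mask <- rep(FALSE, nrow(res))
  for (ch in unique(res$chain)) {
    sel <- res$chain == ch
    avg <- window_average_plddt(res$plddt[sel], policy$window_halfwidth)
    mask[sel] <- flag_low_confidence(avg, policy$plddt_threshold)
  }
  removed_plddt <- which(mask)

  segs <- segment_partition(model, mask)
  pruned <- geometric_prune(model, segs, policy)
  removed_geom <- unlist(lapply(pruned$removed, function(s)
    s$start_index:s$end_index))
  if (is.null(removed_geom)) removed_geom <- integer(0)

  keep <- rep(FALSE, nrow(res))
  for (s in pruned$kept) keep[s$start_index:s$end_index] <- TRUE

  report <- list(removed_by_plddt = removed_plddt,
                 removed_by_geometry = removed_geom,
                 segments_kept = pruned$kept,
                 model_dropped = sum(keep) < policy$min_residues,
                 ligands_dropped = character(0))
  if (report$model_dropped) {
    return(list(model = NULL, report = report))
  }
  trimmed <- subset_model_residues(model, keep)
  trimmed <- ligand_retention_filter(trimmed, policy)
  report$ligands_dropped <- attr(trimmed, "ligands_dropped")
  attr(trimmed, "ligands_dropped") <- NULL
  list(model = trimmed, report = report)
}
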