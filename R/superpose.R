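# Rigid-body superposition engine. The exact least-squares fit is the
# closed-form Kabsch solution (SVD of the cross-covariance, reflection
# corrected). Two correspondence builders emulate the two alignment
# strategies alternated during ligand transplantation: a sequence-guided one
# (global alignment + iterative outlier rejection) and a sequence-independent
# structure-guided one (fragment-seeded mutual-nearest-neighbour pairing).

#' Optimal rigid-body fit between paired point sets (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD between
#' `mobile %*% t(R) + t` and `reference`.
#'
#' @param mobile,reference n x 3 coordinate matrices with matched rows,
#'   n >= 3, not collinear.
#' @param strategy_label provenance label carried into the result.
#' @return object of class `superposition_result`: list with `rotation`
#'   (3 x 3, det +1), `translation`, `rmsd` (Angstrom), `n_pairs`,
#'   `strategy_label`.
#' @export
kabsch_fit <- function(mobile, reference, strategy_label = "kabsch") {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) stop("point sets differ in length", call. = FALSE)
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 point pairs", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  x <- sweep(mobile, 2, cm)
  y <- sweep(reference, 2, cr)
  h <- crossprod(x, y)
  sv <- svd(h)
  # collinear configurations leave the rotation about the common axis
  # undetermined
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)) {
    stop("degenerate (collinear) point configuration", call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.vector(cr - rot %*% cm)
  fitted <- apply_rigid(mobile, rot, trans)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd,
                 n_pairs = n, strategy_label = strategy_label),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition_result> %s: rmsd %.3f A over %d pairs\n",
              x$strategy_label, x$rmsd, x$n_pairs))
  invisible(x)
}

# internal: paired CA coordinate matrices for a correspondence
correspondence_coords <- function(corr) {
  list(mobile = corr$mobile_xyz[corr$pairs[, 1], , drop = FALSE],
       reference = corr$reference_xyz[corr$pairs[, 2], , drop = FALSE])
}

new_correspondence <- function(pairs, mobile_xyz, reference_xyz, label) {
  pairs <- as.matrix(pairs)
  structure(list(pairs = pairs, mobile_xyz = mobile_xyz,
                 reference_xyz = reference_xyz, label = label),
            class = "correspondence")
}

#' Sequence-guided residue correspondence between two chains
#'
#' Globally aligns the one-letter sequences of the two chains (BLOSUM62,
#' affine gaps: open 10, extend 0.5) and pairs aligned non-gap positions for
#' which both CA atoms are present.
#'
#' @param mobile,reference `structure_model`s.
#' @param mobile_chain,reference_chain chain ids (defaults: first chain).
#' @return a `correspondence`: matched residue index pairs plus the chains'
#'   CA coordinates.
#' @export
seq_guided_correspondence <- function(mobile, reference, mobile_chain = NULL,
                                      reference_chain = NULL) {
  sm <- model_sequence(mobile, mobile_chain)
  sr <- model_sequence(reference, reference_chain)
  if (!nzchar(sm) || !nzchar(sr)) stop("empty chain sequence", call. = FALSE)
  aln <- align_sequences(sm, sr)
  if (nrow(aln) == 0L) stop("no aligned positions", call. = FALSE)
  mx <- ca_coords(mobile, mobile_chain)
  rx <- ca_coords(reference, reference_chain)
  ok <- stats::complete.cases(mx[aln[, 1], , drop = FALSE]) &
    stats::complete.cases(rx[aln[, 2], , drop = FALSE])
  aln <- aln[ok, , drop = FALSE]
  if (nrow(aln) == 0L) stop("no aligned positions with CA atoms", call. = FALSE)
  new_correspondence(aln, mx, rx, "sequence")
}

# global pairwise alignment via Biostrings; returns 2-column matrix of
# matched (mobile, reference) positions
align_sequences <- function(s1, s2) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2),
    substitutionMatrix = data_env$BLOSUM62,
    gapOpening = 10, gapExtension = 0.5, type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  i <- cumsum(p != "-")
  j <- cumsum(s != "-")
  keep <- p != "-" & s != "-"
  cbind(mobile = i[keep], reference = j[keep])
}

# alignment score of two sequences under the same scheme (used for chain
# selection)
alignment_score <- function(s1, s2) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2),
    substitutionMatrix = data_env$BLOSUM62,
    gapOpening = 10, gapExtension = 0.5, type = "global",
    scoreOnly = TRUE))
}

#' Iteratively refined rigid fit with outlier rejection
#'
#' Kabsch-fits the corresponding CA pairs, drops pairs whose deviation
#' exceeds `reject_sd` standard deviations above the mean deviation, and
#' refits; stops when nothing is dropped, `max_cycles` is reached, or fewer
#' than 3 pairs would remain. The RMSD never increases across cycles.
#'
#' @param correspondence a `correspondence`.
#' @param max_cycles maximum refinement cycles (default 5).
#' @param reject_sd rejection threshold in standard deviations (default 2).
#' @return a `superposition_result` over the surviving pairs.
#' @export
refine_fit <- function(correspondence, max_cycles = 5L, reject_sd = 2.0) {
  cc <- correspondence_coords(correspondence)
  mob <- cc$mobile; ref <- cc$reference
  fit <- kabsch_fit(mob, ref, strategy_label = correspondence$label)
  for (cycle in seq_len(max_cycles)) {
    dev <- sqrt(rowSums((apply_rigid(mob, fit$rotation, fit$translation) - ref)^2))
    # floor guards against rejecting pairs on numerical noise of an
    # essentially exact fit
    cut <- max(mean(dev) + reject_sd * stats::sd(dev), 1e-6)
    keep <- is.na(cut) | dev <= cut
    if (all(keep)) break
    if (sum(keep) < 3L) break
    mob <- mob[keep, , drop = FALSE]
    ref <- ref[keep, , drop = FALSE]
    fit <- kabsch_fit(mob, ref, strategy_label = correspondence$label)
  }
  fit
}

#' Structure-guided (sequence-independent) residue correspondence
#'
#' Builds a correspondence without using residue identities: all fragment
#' pairs of `seed_length` consecutive CA positions are Kabsch-fitted and the
#' best-fitting pair seeds a transform, under which residues are paired by
#' mutual-nearest-neighbour CA proximity within `pair_cutoff`; pairing and
#' fitting are iterated to convergence.
#'
#' @inheritParams seq_guided_correspondence
#' @param seed_length fragment length for the seed search (default 8).
#' @param seed_stride stride between tried fragment starts (default 2).
#' @param seed_rmsd_max a seed is accepted only if its fragment RMSD is below
#'   this (default 2.5 A); otherwise a correspondence-failure error.
#' @param pair_cutoff CA distance cap for mutual-nearest-neighbour pairing
#'   (default 5 A).
#' @return a `correspondence`.
#' @export
structure_guided_correspondence <- function(mobile, reference,
                                            mobile_chain = NULL,
                                            reference_chain = NULL,
                                            seed_length = 8L, seed_stride = 2L,
                                            seed_rmsd_max = 2.5,
                                            pair_cutoff = 5.0) {
  mx <- ca_coords(mobile, mobile_chain)
  rx <- ca_coords(reference, reference_chain)
  mx_ok <- which(stats::complete.cases(mx))
  rx_ok <- which(stats::complete.cases(rx))
  if (length(mx_ok) < 3L || length(rx_ok) < 3L) {
    stop("chains too short for structure-guided correspondence", call. = FALSE)
  }
  k <- min(seed_length, length(mx_ok), length(rx_ok))
  starts_m <- unique(c(seq(1L, length(mx_ok) - k + 1L, by = seed_stride),
                       length(mx_ok) - k + 1L))
  starts_r <- unique(c(seq(1L, length(rx_ok) - k + 1L, by = seed_stride),
                       length(rx_ok) - k + 1L))
  best <- NULL
  for (a in starts_m) {
    fm <- mx[mx_ok[a:(a + k - 1L)], , drop = FALSE]
    for (b in starts_r) {
      fr <- rx[rx_ok[b:(b + k - 1L)], , drop = FALSE]
      fit <- tryCatch(kabsch_fit(fm, fr), error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$rmsd < best$rmsd)) best <- fit
    }
  }
  if (is.null(best) || best$rmsd > seed_rmsd_max) {
    stop("no seed fragment match between the two chains", call. = FALSE)
  }

  fit <- best
  pairs <- NULL
  for (iter in 1:10) {
    moved <- apply_rigid(mx[mx_ok, , drop = FALSE], fit$rotation, fit$translation)
    d2 <- outer(rowSums(moved^2), rowSums(rx[rx_ok, , drop = FALSE]^2), "+") -
      2 * tcrossprod(moved, rx[rx_ok, , drop = FALSE])
    d2[d2 < 0] <- 0
    nn_m <- apply(d2, 1, which.min)
    nn_r <- apply(d2, 2, which.min)
    mutual <- which(nn_r[nn_m] == seq_along(nn_m) &
                      sqrt(d2[cbind(seq_along(nn_m), nn_m)]) <= pair_cutoff)
    if (length(mutual) < 3L) {
      stop("structure-guided pairing found fewer than 3 mutual pairs", call. = FALSE)
    }
    new_pairs <- cbind(mobile = mx_ok[mutual], reference = rx_ok[nn_m[mutual]])
    if (!is.null(pairs) && identical(pairs, new_pairs)) break
    pairs <- new_pairs
    fit <- kabsch_fit(mx[pairs[, 1], , drop = FALSE],
                      rx[pairs[, 2], , drop = FALSE], "structure")
  }
  new_correspondence(pairs, mx, rx, "structure")
}

#' Local binding-site superposition around a ligand
#'
#' Restricts a full-chain correspondence to reference residues having at
#' least one atom within `radius` of any ligand atom, then refines a rigid
#' fit on those pairs. Used to decide whether a donor binding site matches a
#' site in the acceptor model.
#'
#' @param mobile `structure_model` (the acceptor AI model).
#' @param reference `structure_model` carrying the ligand (donor chain).
#' @param ligand a ligand entry of `reference`.
#' @param radius site radius in Angstrom.
#' @param strategy `"sequence"` or `"structure"`.
#' @param reference_chain donor chain id.
#' @param max_cycles,reject_sd refinement parameters, see [refine_fit()].
#' @return a `superposition_result` with `strategy_label`
#'   `"{strategy}@{radius}"`.
#' @export
local_site_superpose <- function(mobile, reference, ligand, radius,
                                 strategy = c("sequence", "structure"),
                                 reference_chain = NULL,
                                 max_cycles = 5L, reject_sd = 2.0) {
  strategy <- match.arg(strategy)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (is.null(reference_chain)) reference_chain <- ligand$chain
  corr <- if (strategy == "sequence") {
    seq_guided_correspondence(mobile, reference, reference_chain = reference_chain)
  } else {
    structure_guided_correspondence(mobile, reference,
                                    reference_chain = reference_chain)
  }

  # reference residues with any atom within `radius` of any ligand atom
  res <- reference$residues[reference$residues$chain == reference_chain, ,
                            drop = FALSE]
  at <- reference$atoms[reference$atoms$chain == reference_chain, , drop = FALSE]
  lig_xyz <- atom_xyz(ligand$atoms)
  at_xyz <- atom_xyz(at)
  d2 <- outer(rowSums(at_xyz^2), rowSums(lig_xyz^2), "+") -
    2 * tcrossprod(at_xyz, lig_xyz)
  near_atom <- sqrt(pmax(apply(d2, 1, min), 0)) <= radius
  near_res_keys <- unique(residue_key(at)[near_atom])
  in_site <- match(residue_key(res), near_res_keys, nomatch = 0L) > 0L
  site_idx <- which(in_site)

  keep <- corr$pairs[, 2] %in% site_idx
  if (sum(keep) < 3L) {
    stop(sprintf("binding site too small: %d paired residues within %g A",
                 sum(keep), radius), call. = FALSE)
  }
  site_corr <- new_correspondence(corr$pairs[keep, , drop = FALSE],
                                  corr$mobile_xyz, corr$reference_xyz,
                                  corr$label)
  fit <- refine_fit(site_corr, max_cycles = max_cycles, reject_sd = reject_sd)
  fit$strategy_label <- sprintf("%s@%g", strategy, radius)
  fit
}
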