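# Deterministic synthetic structures for exercising the refinement pipeline:
# ideal poly-alanine backbones built from prescribed (phi, psi) torsions,
# multi-segment models with prescribed pLDDT profiles and detached fragments
# at exact inter-segment distances, and donor/acceptor pairs with placed
# pseudo-ligands and geometric ground truths.

# Canonical backbone internal geometry (Engh-Huber-style averages).
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, omega = 180
)

#' Build a poly-alanine backbone from prescribed torsions
#'
#' Places N, CA, C, O atoms residue by residue using canonical bond lengths
#' and angles and the given (phi, psi) torsions, so the dihedrals measured on
#' the result equal the inputs. The workhorse behind [make_helix()] and the
#' strand/coil fixtures.
#'
#' @param n number of residues (>= 2).
#' @param phi,psi backbone torsions in degrees; scalars are recycled.
#' @param bfactor per-residue B-factor (pLDDT) values; scalar recycled.
#' @param sequence optional one-letter amino-acid string of length `n`
#'   setting the residue names (backbone geometry stays poly-alanine-like);
#'   default poly-alanine.
#' @param chain chain id.
#' @param start_resno first residue number.
#' @param model_type model-type tag for the resulting [structure_model()].
#' @param accession,description passed through to the model.
#' @return a `structure_model` of poly-alanine.
#' @export
make_backbone <- function(n, phi = -57, psi = -47, bfactor = 90,
                          sequence = NULL, chain = "A", start_resno = 1L,
                          model_type = "alphafold2",
                          accession = "SYNTH", description = "synthetic model") {
  if (n < 2) stop("need at least 2 residues", call. = FALSE)
  resnames <- if (is.null(sequence)) rep("ALA", n) else {
    one <- strsplit(toupper(sequence), "")[[1]]
    if (length(one) != n) stop("sequence length must equal n", call. = FALSE)
    rn <- names(AA3)[match(one, AA3)]
    if (any(is.na(rn))) stop("non-standard amino-acid letter", call. = FALSE)
    rn
  }
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  bfactor <- rep_len(bfactor, n)
  g <- BB_GEOM

  coords <- matrix(NA_real_, 4L * n, 3)  # N, CA, C, O per residue
  idx <- function(i, a) (i - 1L) * 4L + match(a, c("N", "CA", "C", "O"))
  # seed residue in a local frame
  coords[idx(1, "N"), ] <- c(0, 0, 0)
  coords[idx(1, "CA"), ] <- c(g$n_ca, 0, 0)
  coords[idx(1, "C"), ] <- place_atom(c(-1, 1, 0), coords[idx(1, "N"), ],
                                      coords[idx(1, "CA"), ],
                                      g$ca_c, g$ang_n_ca_c, phi[1])
  for (i in seq_len(n)) {
    Ni <- coords[idx(i, "N"), ]; CAi <- coords[idx(i, "CA"), ]
    Ci <- coords[idx(i, "C"), ]
    if (i < n) {
      Nn <- place_atom(Ni, CAi, Ci, g$c_n, g$ang_ca_c_n, psi[i])
      coords[idx(i + 1, "N"), ] <- Nn
      CAn <- place_atom(CAi, Ci, Nn, g$n_ca, g$ang_c_n_ca, g$omega)
      coords[idx(i + 1, "CA"), ] <- CAn
      coords[idx(i + 1, "C"), ] <- place_atom(Ci, Nn, CAn, g$ca_c,
                                              g$ang_n_ca_c, phi[i + 1])
    }
    # carbonyl O: torsion N-CA-C-O = psi + 180
    coords[idx(i, "O"), ] <- place_atom(Ni, CAi, Ci, g$c_o, g$ang_ca_c_o,
                                        psi[i] + 180)
  }

  atoms <- data.frame(
    serial = seq_len(4L * n),
    name = rep(c("N", "CA", "C", "O"), n),
    resname = rep(resnames, each = 4L),
    chain = chain,
    resno = rep(start_resno + seq_len(n) - 1L, each = 4L),
    icode = "",
    x = round(coords[, 1], 3), y = round(coords[, 2], 3),
    z = round(coords[, 3], 3),
    occ = 1, b = round(rep(bfactor, each = 4L), 2),
    element = rep(c("N", "C", "C", "O"), n),
    stringsAsFactors = FALSE)
  structure_model(atoms, model_type = model_type, accession = accession,
                  description = description)
}

#' Ideal alpha-helix toy protein
#'
#' Poly-alanine alpha helix built with canonical helical torsions
#' (phi = -57, psi = -47), giving ~1.5 A rise and ~100 degrees twist per
#' residue and consecutive CA-CA distances of ~3.8 A.
#'
#' @param n number of residues (>= 2).
#' @param ... passed to [make_backbone()].
#' @return a `structure_model`.
#' @export
make_helix <- function(n, ...) {
  make_backbone(n, phi = -57, psi = -47, ...)
}

# translate all atoms of residues in `range` (indices into the residue
# table) by vector v; returns the modified model
translate_residue_range <- function(model, range, v) {
  keys <- residue_key(model$residues)[range]
  sel <- residue_key(model$atoms) %in% keys
  model$atoms[sel, c("x", "y", "z")] <-
    sweep(model$atoms[sel, c("x", "y", "z")], 2, v, "+")
  structure_model(model$atoms, model$model_type, ligands = model$ligands,
                  accession = model$accession, description = model$description,
                  metadata = model$metadata)
}

#' Trimming fixture: helix with prescribed pLDDT profile and detached ranges
#'
#' Builds a helix whose B-factor column follows `plddt_profile`, then rigidly
#' translates selected residue ranges away from the remainder so that the
#' minimum inter-atomic distance between each translated range and the rest
#' of the model equals a requested gap exactly (solved numerically along the
#' translation direction).
#'
#' @param n_residues chain length.
#' @param plddt_profile numeric vector of length `n_residues`, or one of the
#'   named patterns `"constant"` or `"two-lobe-low-linker"`.
#' @param detach list of `list(range = i:j, distance = d, direction = v)`
#'   entries; `direction` defaults to the +z axis.
#' @param ... passed to [make_backbone()].
#' @return a `structure_model` with attribute `"detach_achieved"` recording
#'   the realized minimum distances.
#' @export
make_trim_fixture <- function(n_residues, plddt_profile = "constant",
                              detach = list(), ...) {
  if (is.character(plddt_profile)) {
    plddt_profile <- switch(
      match.arg(plddt_profile, c("constant", "two-lobe-low-linker")),
      constant = rep(90, n_residues),
      `two-lobe-low-linker` = {
        n_link <- 8L
        n_lobe <- (n_residues - n_link) %/% 2L
        c(rep(90, n_lobe), rep(50, n_link),
          rep(90, n_residues - n_lobe - n_link))
      })
  }
  if (length(plddt_profile) != n_residues) {
    stop("profile length must equal n_residues", call. = FALSE)
  }
  ranges <- lapply(detach, `[[`, "range")
  if (length(ranges) > 1L) {
    all_idx <- unlist(ranges)
    if (anyDuplicated(all_idx)) stop("overlapping detach ranges", call. = FALSE)
  }
  model <- make_helix(n_residues, bfactor = plddt_profile, ...)

  achieved <- numeric(0)
  for (d in detach) {
    v <- if (is.null(d$direction)) c(0, 0, 1) else d$direction
    v <- v / sqrt(sum(v^2))
    rest_keys <- residue_key(model$residues)[-d$range]
    seg_keys <- residue_key(model$residues)[d$range]
    rest_xyz <- atom_xyz(model$atoms[residue_key(model$atoms) %in% rest_keys, ])
    seg_xyz <- atom_xyz(model$atoms[residue_key(model$atoms) %in% seg_keys, ])
    gap <- function(s) min_pair_dist(sweep(seg_xyz, 2, v * s, "+"), rest_xyz) - d$distance
    # min distance is continuous and eventually increasing in s; bracket and solve
    hi <- d$distance + diff(range(c(seg_xyz, rest_xyz))) * 2 + 10
    s <- stats::uniroot(gap, c(0, hi), tol = 1e-9)$root
    model <- translate_residue_range(model, d$range, v * s)
    achieved <- c(achieved, d$distance + gap(s))
  }
  attr(model, "detach_achieved") <- achieved
  model
}

# place a rigid pseudo-ligand cluster of n_atoms near a point; coordinates
# are deterministic given the current RNG state
pseudo_ligand_atoms <- function(center, n_atoms, het_id, chain, resno,
                                spread = 1.2) {
  offs <- matrix(stats::rnorm(3 * n_atoms, sd = spread), n_atoms, 3)
  offs <- sweep(offs, 2, colMeans(offs))
  xyz <- sweep(offs, 2, center, "+")
  data.frame(serial = seq_len(n_atoms), name = paste0("C", seq_len(n_atoms)),
             resname = het_id, chain = chain, resno = resno, icode = "",
             x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
             z = round(xyz[, 3], 3), occ = 1, b = 0, element = "C",
             stringsAsFactors = FALSE)
}

add_ligand <- function(model, anchor_residue, offset, n_atoms = 6L,
                       het_id = "LIG", resno = 900L, chain = NULL,
                       min_clearance = 2.5, max_contact = 5) {
  ca <- ca_coords(model)
  if (is.null(chain)) chain <- model$residues$chain[1]
  prot <- atom_xyz(model$atoms)
  # slide the cluster center along the offset direction until it clears the
  # protein surface by the midpoint of the allowed contact band
  dir <- offset / sqrt(sum(offset^2))
  target <- (min_clearance + max_contact) / 2
  gap <- function(s) min_pair_dist(matrix(ca[anchor_residue, ] + dir * s,
                                          1, 3), prot) - target
  hi <- sqrt(sum(offset^2)) + diff(range(prot)) + target + 5
  s <- stats::uniroot(gap, c(0, hi), tol = 1e-8)$root
  center <- ca[anchor_residue, ] + dir * s
  atoms <- NULL
  for (try in 1:100) {
    cand <- pseudo_ligand_atoms(center, n_atoms, het_id, chain, resno,
                                spread = 1.0 * 0.9^(try - 1))
    d <- min_pair_dist(atom_xyz(cand), prot)
    if (d >= min_clearance && d <= max_contact) {
      atoms <- cand
      break
    }
  }
  if (is.null(atoms)) {
    stop("could not place a non-clashing, protein-contacting ligand", call. = FALSE)
  }
  lig <- list(het_id = het_id, chain = chain, resno = resno, icode = "",
              atoms = atoms, category = categorize_het(het_id))
  model$ligands <- c(model$ligands, list(lig))
  model
}

rigid_transform_model <- function(model, rotation, translation) {
  model$atoms[, c("x", "y", "z")] <-
    apply_rigid(atom_xyz(model$atoms), rotation, translation)
  model$ligands <- lapply(model$ligands, function(lig) {
    lig$atoms[, c("x", "y", "z")] <-
      apply_rigid(atom_xyz(lig$atoms), rotation, translation)
    lig
  })
  structure_model(model$atoms, model$model_type, ligands = model$ligands,
                  accession = model$accession, description = model$description,
                  metadata = model$metadata)
}

#' Donor/acceptor fixture pair for ligand transplantation
#'
#' Returns an AI-style acceptor model plus a homology-style donor carrying
#' pseudo-ligands, with the donor optionally rigidly transformed, truncated
#' to a subsequence, or duplicated into two chains. Ground-truth expected
#' post-transplant ligand coordinates (the acceptor-frame image of each donor
#' ligand) are computed by direct geometry inside the generator.
#'
#' @param n number of residues in the acceptor helix.
#' @param ligands list of `list(anchor, offset, n_atoms, het_id)` placements
#'   (anchor = residue index; offset = 3-vector from its CA).
#' @param rotation,translation rigid transform applied to the donor; default
#'   identity.
#' @param truncate optional residue index range retained in the donor.
#' @param duplicate_chain if `TRUE` the donor gets a second chain "B" (a
#'   translated copy) carrying one fewer ligand than chain "A".
#' @param seed integer seed fixing ligand atom clouds.
#' @return list with elements `ai`, `donor`, and `ground_truth` (list of
#'   expected acceptor-frame ligand coordinate matrices, in placement order).
#' @export
make_donor_pair <- function(n = 30L, ligands = list(list(anchor = n %/% 2L,
                                                         offset = c(4, 0, 0))),
                            rotation = diag(3), translation = c(0, 0, 0),
                            truncate = NULL, duplicate_chain = FALSE,
                            seed = 42L) {
  set.seed(seed)
  ai <- make_helix(n, accession = "SYNTH01")

  donor <- make_helix(n, model_type = "homology", accession = "SYNTH01")
  truth <- list()
  for (lg in ligands) {
    n_atoms <- if (is.null(lg$n_atoms)) 6L else lg$n_atoms
    het_id <- if (is.null(lg$het_id)) "LIG" else lg$het_id
    donor <- add_ligand(donor, lg$anchor, lg$offset, n_atoms = n_atoms,
                        het_id = het_id,
                        resno = 900L + length(truth))
    # ligand placed in the shared (acceptor) frame: ground truth is its
    # coordinates before the donor transform
    truth[[length(truth) + 1L]] <-
      atom_xyz(donor$ligands[[length(donor$ligands)]]$atoms)
  }
  if (!is.null(truncate)) {
    keep <- seq_len(nrow(donor$residues)) %in% truncate
    donor <- subset_model_residues(donor, keep)
  }
  if (duplicate_chain) {
    shift <- c(60, 0, 0)
    b_atoms <- donor$atoms
    b_atoms$chain <- "B"
    b_atoms[, c("x", "y", "z")] <- sweep(b_atoms[, c("x", "y", "z")], 2, shift, "+")
    b_ligs <- list()
    if (length(donor$ligands) > 1L) {
      b_ligs <- lapply(donor$ligands[-length(donor$ligands)], function(lig) {
        lig$chain <- "B"
        lig$atoms$chain <- "B"
        lig$atoms[, c("x", "y", "z")] <-
          sweep(lig$atoms[, c("x", "y", "z")], 2, shift, "+")
        lig
      })
    }
    donor <- structure_model(rbind(donor$atoms, b_atoms), "homology",
                             ligands = c(donor$ligands, b_ligs),
                             accession = donor$accession,
                             description = donor$description)
  }
  donor <- rigid_transform_model(donor, rotation, translation)
  list(ai = ai, donor = donor, ground_truth = truth)
}
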