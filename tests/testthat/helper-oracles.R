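# Independent brute-force oracles, written with plain loops and kept free of
# the package's internal helpers so they can act as second routes in
# dual-route checks.

# minimum inter-atomic distance by exhaustive pair enumeration
oracle_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# brute-force realization of the segment pruning rule: core = largest
# segment (ties: earliest), keep a segment iff within core_dist of the core
# or within chain_dist of a segment that is itself within core_dist of the
# core (single hop)
oracle_prune_keep <- function(xyz_list, sizes, starts, core_dist = 10,
                              chain_dist = 5) {
  n <- length(xyz_list)
  core <- which(sizes == max(sizes))
  core <- core[which.min(starts[core])]
  d_core <- numeric(n)
  for (i in seq_len(n)) {
    d_core[i] <- if (i == core) 0 else oracle_min_dist(xyz_list[[i]], xyz_list[[core]])
  }
  keep <- d_core <= core_dist
  for (i in seq_len(n)) {
    if (keep[i]) next
    for (j in seq_len(n)) {
      if (j == i || !(d_core[j] <= core_dist)) next
      if (oracle_min_dist(xyz_list[[i]], xyz_list[[j]]) <= chain_dist) {
        keep[i] <- TRUE
        break
      }
    }
  }
  keep
}

# random multi-segment single-chain model with one CA atom per residue;
# cluster centers drawn so that realized distances straddle the pruning
# thresholds. Returns the model plus its segment index ranges.
random_segment_model <- function(n_segments = NULL) {
  if (is.null(n_segments)) n_segments <- sample(2:5, 1)
  sizes <- sample(2:8, n_segments, replace = TRUE)
  atoms <- NULL
  segs <- list()
  resno <- 0L
  for (s in seq_len(n_segments)) {
    center <- runif(3, -14, 14)
    start <- resno + 1L
    for (r in seq_len(sizes[s])) {
      resno <- resno + 1L
      p <- center + rnorm(3, sd = 1.2)
      atoms <- rbind(atoms, data.frame(
        serial = resno, name = "CA", resname = "ALA", chain = "A",
        resno = resno, icode = "", x = p[1], y = p[2], z = p[3],
        occ = 1, b = 90, element = "C", stringsAsFactors = FALSE))
    }
    segs[[s]] <- list(chain = "A", start_index = start, end_index = resno)
  }
  model <- structure_model(atoms, "alphafold2")
  list(model = model, segments = segs, sizes = sizes,
       starts = vapply(segs, function(x) x$start_index, integer(1)))
}

segment_xyz_list <- function(model, segments) {
  lapply(segments, function(s) {
    idx <- s$start_index:s$end_index
    keys <- paste(model$residues$chain[idx], model$residues$resno[idx],
                  model$residues$icode[idx], sep = "|")
    akeys <- paste(model$atoms$chain, model$atoms$resno, model$atoms$icode,
                   sep = "|")
    as.matrix(model$atoms[akeys %in% keys, c("x", "y", "z")])
  })
}

# deform every residue by a random per-residue displacement of uniform
# magnitude that is orthogonal to the rigid-body modes of the CA set, so
# that the best attainable rigid-fit RMSD on CA pairs is approximately
# `magnitude`. All atoms of a residue move together.
orthogonal_deform <- function(model, magnitude) {
  res <- model$residues
  n <- nrow(res)
  X <- ca_coords(model)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  # 6 rigid modes as 3n-vectors: 3 translations, 3 infinitesimal rotations
  modes <- matrix(0, 3 * n, 6)
  for (k in 1:3) modes[seq(k, 3 * n, by = 3), k] <- 1
  axes <- diag(3)
  for (k in 1:3) {
    rot <- t(apply(Xc, 1, function(p) c(axes[k, 2] * p[3] - axes[k, 3] * p[2],
                                        axes[k, 3] * p[1] - axes[k, 1] * p[3],
                                        axes[k, 1] * p[2] - axes[k, 2] * p[1])))
    modes[, 3 + k] <- as.vector(t(rot))
  }
  q <- qr.Q(qr(modes))
  u <- rnorm(3 * n)
  for (iter in 1:8) {
    u <- u - q %*% crossprod(q, u)
    U <- matrix(u, n, 3, byrow = TRUE)
    U <- U / sqrt(rowSums(U^2)) * magnitude
    u <- as.vector(t(U))
  }
  U <- matrix(u, n, 3, byrow = TRUE)
  akey <- paste(model$atoms$chain, model$atoms$resno, model$atoms$icode,
                sep = "|")
  rkey <- paste(res$chain, res$resno, res$icode, sep = "|")
  model$atoms[, c("x", "y", "z")] <-
    model$atoms[, c("x", "y", "z")] + U[match(akey, rkey), ]
  structure_model(model$atoms, model$model_type, ligands = model$ligands,
                  accession = model$accession,
                  description = model$description, metadata = model$metadata)
}

expect_rotation_matrix <- function(r, tol = 1e-10) {
  expect_lt(max(abs(crossprod(r) - diag(3))), tol)
  expect_lt(abs(det(r) - 1), tol)
}
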