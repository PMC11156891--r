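# Transplantation of small-molecule ligands from a homology model (donor)
# into an AI-predicted model (acceptor) of the same protein. For each donor
# ligand, binding-site superpositions are tried over a grid of site radii
# and two correspondence strategies; the lowest-RMSD fit places the ligand
# if it passes the RMSD gate, and placed ligands are screened for steric
# clashes (optionally after an external energy-minimization hook). Acceptor
# protein coordinates are never modified.

#' Transplantation policy
#'
#' @param radii binding-site radii tried, in Angstrom (ascending).
#' @param strategies correspondence strategies tried: subset of
#'   `c("sequence", "structure")`.
#' @param rmsd_max RMSD gate: a ligand is only copied when the best local
#'   site RMSD is at or below this (Angstrom).
#' @param donor_contact_distance a donor ligand must have an atom within
#'   this distance of a donor protein atom to be considered bound.
#' @param clash_distance placed ligands with any heavy atom closer than this
#'   to a protein heavy atom are deleted.
#' @param retention_distance post-trim ligand retention distance.
#' @param max_cycles,reject_sd fit-refinement parameters, see
#'   [refine_fit()].
#' @return object of class `transplant_policy`.
#' @export
transplant_policy <- function(radii = c(5, 10, 15),
                              strategies = c("sequence", "structure"),
                              rmsd_max = 7, donor_contact_distance = 5,
                              clash_distance = 2.0, retention_distance = 5,
                              max_cycles = 5L, reject_sd = 2.0) {
  stopifnot(length(radii) >= 1, all(radii > 0), !is.unsorted(radii),
            rmsd_max > 0, donor_contact_distance > 0, clash_distance > 0)
  strategies <- match.arg(strategies, c("sequence", "structure"),
                          several.ok = TRUE)
  structure(list(radii = radii, strategies = strategies, rmsd_max = rmsd_max,
                 donor_contact_distance = donor_contact_distance,
                 clash_distance = clash_distance,
                 retention_distance = retention_distance,
                 max_cycles = as.integer(max_cycles), reject_sd = reject_sd),
            class = "transplant_policy")
}

# assign each ligand to the chain owning its nearest protein atom
ligand_chain_assignment <- function(model) {
  vapply(model$ligands, function(lig) {
    lx <- atom_xyz(lig$atoms)
    d <- vapply(unique(model$atoms$chain), function(ch) {
      min_pair_dist(lx, atom_xyz(model$atoms[model$atoms$chain == ch, ,
                                             drop = FALSE]))
    }, numeric(1))
    names(d)[which.min(d)]
  }, character(1))
}

#' Select the donor chain best matching the acceptor sequence
#'
#' Chains are scored by global sequence-alignment score against the acceptor
#' model's sequence; exact ties are broken by the number of ligands assigned
#' to the chain (nearest protein atom), remaining ties by chain id order.
#'
#' @param ai_model acceptor `structure_model`.
#' @param homology_model donor `structure_model`.
#' @return selected chain id.
#' @export
select_best_chain <- function(ai_model, homology_model) {
  chains <- unique(homology_model$residues$chain)
  if (length(chains) == 1L) return(chains)
  ai_seq <- model_sequence(ai_model)
  scores <- vapply(chains, function(ch)
    alignment_score(model_sequence(homology_model, ch), ai_seq), numeric(1))
  assign <- ligand_chain_assignment(homology_model)
  nlig <- vapply(chains, function(ch) sum(assign == ch), numeric(1))
  chains[order(-scores, -nlig, chains)][1]
}

#' Donor ligands eligible for transplantation
#'
#' Ligands assigned to the selected chain that are small molecules (DNA/RNA
#' and HETATM-recorded amino acids are excluded) and have at least one atom
#' within `donor_contact_distance` of a donor protein atom.
#'
#' @param homology_model donor `structure_model`.
#' @param chain selected donor chain id.
#' @param policy a [transplant_policy()].
#' @return list with `eligible` (ligand list) and `excluded` (data.frame of
#'   het id + reason).
#' @export
eligible_ligands <- function(homology_model, chain,
                             policy = transplant_policy()) {
  ligs <- homology_model$ligands
  if (!length(ligs)) {
    return(list(eligible = list(),
                excluded = data.frame(het_id = character(),
                                      reason = character())))
  }
  assign <- ligand_chain_assignment(homology_model)
  prot <- atom_xyz(homology_model$atoms)
  eligible <- list()
  ex_id <- character(); ex_why <- character()
  for (i in seq_along(ligs)) {
    lig <- ligs[[i]]
    if (assign[i] != chain) next
    if (lig$category != "small_molecule") {
      ex_id <- c(ex_id, lig$het_id); ex_why <- c(ex_why, "excluded_category")
    } else if (min_pair_dist(atom_xyz(lig$atoms), prot) >
               policy$donor_contact_distance) {
      ex_id <- c(ex_id, lig$het_id); ex_why <- c(ex_why, "no_donor_contact")
    } else {
      eligible[[length(eligible) + 1L]] <- lig
    }
  }
  list(eligible = eligible,
       excluded = data.frame(het_id = ex_id, reason = ex_why,
                             stringsAsFactors = FALSE))
}

#' Transplant one ligand via the best local-site superposition
#'
#' Tries every (radius, strategy) combination with [local_site_superpose()]
#' (acceptor as mobile, donor chain as reference), takes the fit with the
#' lowest RMSD, and — if it passes the RMSD gate — maps the ligand into the
#' acceptor frame with the inverse of that transform.
#'
#' @param ai_model acceptor `structure_model`.
#' @param homology_model donor `structure_model`.
#' @param chain donor chain id.
#' @param ligand donor ligand entry.
#' @param policy a [transplant_policy()].
#' @return list with `ligand` (placed ligand, or `NULL`), `outcome` (one of
#'   `"transplanted"`, `"rmsd_gate_failed"`, `"no_valid_fit"`), `best_rmsd`,
#'   `winning_strategy`.
#' @export
transplant_ligand <- function(ai_model, homology_model, chain, ligand,
                              policy = transplant_policy()) {
  fits <- list()
  for (strategy in policy$strategies) {
    for (radius in policy$radii) {
      fit <- tryCatch(
        local_site_superpose(ai_model, homology_model, ligand, radius,
                             strategy = strategy, reference_chain = chain,
                             max_cycles = policy$max_cycles,
                             reject_sd = policy$reject_sd),
        error = function(e) NULL)
      if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
    }
  }
  if (!length(fits)) {
    return(list(ligand = NULL, outcome = "no_valid_fit", best_rmsd = NA_real_,
                winning_strategy = NA_character_))
  }
  rmsds <- vapply(fits, `[[`, numeric(1), "rmsd")
  best <- fits[[which.min(rmsds)]]
  if (best$rmsd > policy$rmsd_max) {
    return(list(ligand = NULL, outcome = "rmsd_gate_failed",
                best_rmsd = best$rmsd, winning_strategy = best$strategy_label))
  }
  # the fit maps acceptor -> donor; the ligand goes the other way
  placed <- ligand
  lx <- atom_xyz(ligand$atoms)
  placed$atoms[, c("x", "y", "z")] <-
    sweep(lx, 2, best$translation) %*% best$rotation
  placed$chain <- ai_model$residues$chain[1]
  placed$atoms$chain <- placed$chain
  list(ligand = placed, outcome = "transplanted", best_rmsd = best$rmsd,
       winning_strategy = best$strategy_label)
}

#' Screen placed ligands for steric clashes
#'
#' Optionally runs an external energy-minimization hook on the complex
#' first (a command template containing `{in}` and `{out}` PDB path
#' placeholders), then deletes every ligand having any heavy atom closer
#' than `clash_distance` to any protein heavy atom.
#'
#' @param model `structure_model` with placed ligands.
#' @param policy a [transplant_policy()].
#' @param minimizer_hook optional command template string.
#' @return the screened model; attribute `"clashed"` lists deleted het ids.
#' @export
clash_screen <- function(model, policy = transplant_policy(),
                         minimizer_hook = NULL) {
  if (!is.null(minimizer_hook) && length(model$ligands)) {
    model <- run_minimizer_hook(model, minimizer_hook)
  }
  if (!length(model$ligands)) {
    attr(model, "clashed") <- character(0)
    return(model)
  }
  prot <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  px <- atom_xyz(prot)
  keep <- vapply(model$ligands, function(lig) {
    la <- lig$atoms[lig$atoms$element != "H", , drop = FALSE]
    min_pair_dist(atom_xyz(la), px) >= policy$clash_distance
  }, logical(1))
  clashed <- vapply(model$ligands[!keep], `[[`, character(1), "het_id")
  model$ligands <- model$ligands[keep]
  attr(model, "clashed") <- clashed
  model
}

run_minimizer_hook <- function(model, hook) {
  fin <- tempfile(fileext = ".pdb")
  fout <- tempfile(fileext = ".pdb")
  on.exit(unlink(c(fin, fout)))
  write_model(model, fin)
  cmd <- gsub("{out}", fout, gsub("{in}", fin, hook, fixed = TRUE),
              fixed = TRUE)
  status <- system(paste(cmd, "2>/tmp/structrefine_hook.err"))
  if (status != 0L || !file.exists(fout)) {
    err <- tryCatch(paste(readLines("/tmp/structrefine_hook.err", warn = FALSE),
                          collapse = "\n"), error = function(e) "")
    stop(sprintf("minimizer hook failed (exit %d): %s", status, err),
         call. = FALSE)
  }
  out <- read_model(fout, model$model_type)
  out$accession <- model$accession
  out$description <- model$description
  out$metadata <- model$metadata
  out
}

#' Transplant all eligible ligands from a donor into an acceptor model
#'
#' Whole procedure: select the best-matching donor chain, enumerate eligible
#' ligands, transplant each independently with its own best local fit, and
#' clash-screen the result. Acceptor protein atoms are never moved.
#'
#' @param ai_model acceptor `structure_model`.
#' @param homology_model donor `structure_model` (same accession).
#' @param policy a [transplant_policy()].
#' @param minimizer_hook optional external minimizer command template.
#' @return list with `model` (acceptor with placed ligands) and `report`
#'   (data.frame: `het_id`, `outcome`, `best_rmsd`, `winning_strategy`,
#'   `chain_selected`).
#' @export
transplant_all <- function(ai_model, homology_model,
                           policy = transplant_policy(),
                           minimizer_hook = NULL) {
  if (!identical(ai_model$accession, homology_model$accession)) {
    stop("acceptor and donor must share an accession", call. = FALSE)
  }
  empty_report <- data.frame(het_id = character(), outcome = character(),
                             best_rmsd = numeric(),
                             winning_strategy = character(),
                             chain_selected = character(),
                             stringsAsFactors = FALSE)
  if (!length(homology_model$ligands)) {
    return(list(model = ai_model, report = empty_report))
  }
  chain <- select_best_chain(ai_model, homology_model)
  el <- eligible_ligands(homology_model, chain, policy)
  report <- empty_report
  if (nrow(el$excluded)) {
    report <- rbind(report, data.frame(het_id = el$excluded$het_id,
                                       outcome = el$excluded$reason,
                                       best_rmsd = NA_real_,
                                       winning_strategy = NA_character_,
                                       chain_selected = chain,
                                       stringsAsFactors = FALSE))
  }
  model <- ai_model
  placed_ids <- character(0)
  for (lig in el$eligible) {
    tr <- transplant_ligand(ai_model, homology_model, chain, lig, policy)
    if (tr$outcome == "transplanted") {
      tr$ligand$resno <- 9000L + length(model$ligands)
      tr$ligand$atoms$resno <- tr$ligand$resno
      model$ligands <- c(model$ligands, list(tr$ligand))
      placed_ids <- c(placed_ids, tr$ligand$het_id)
    }
    report <- rbind(report, data.frame(het_id = lig$het_id,
                                       outcome = tr$outcome,
                                       best_rmsd = tr$best_rmsd,
                                       winning_strategy = tr$winning_strategy,
                                       chain_selected = chain,
                                       stringsAsFactors = FALSE))
  }
  model <- clash_screen(model, policy, minimizer_hook)
  clashed <- attr(model, "clashed")
  attr(model, "clashed") <- NULL
  if (length(clashed)) {
    hit <- report$outcome == "transplanted" & report$het_id %in% clashed
    report$outcome[hit] <- "clash_after_minimization"
  }
  list(model = model, report = report)
}
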