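# End-to-end composition of the refinement stages: for every AI-predicted
# model, optional external relaxation then confidence trimming; when a
# homology-model donor for the same accession is present, ligand
# transplantation runs first and the ligand-integrated model flows through
# relaxation, trimming and ligand retention. Stage order is fixed:
# transplant -> relax (hook) -> trim -> retention.

#' Pipeline configuration
#'
#' @param input_dir directory of input PDB files, named by the dataset
#'   scheme: `[ModelType]_[accession].pdb` for native AI models and
#'   `HM_[accession].pdb` for homology-model donors.
#' @param output_dir directory for refined outputs (created if missing).
#' @param trim a [trim_policy()].
#' @param transplant a [transplant_policy()].
#' @param minimizer_hook optional external relaxation command template with
#'   `{in}`/`{out}` placeholders; `NULL` skips relaxation.
#' @param stages subset of `c("transplant", "trim")`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir, trim = trim_policy(),
                            transplant = transplant_policy(),
                            minimizer_hook = NULL,
                            stages = c("transplant", "trim")) {
  stages <- match.arg(stages, c("transplant", "trim"), several.ok = TRUE)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 trim = trim, transplant = transplant,
                 minimizer_hook = minimizer_hook, stages = stages),
            class = "pipeline_config")
}

parse_input_filename <- function(fname) {
  base <- sub("\\.pdb$", "", basename(fname))
  if (grepl("^HM_", base)) {
    return(list(model_type = "homology", accession = sub("^HM_", "", base)))
  }
  for (mt in names(MODEL_TYPE_LABELS)) {
    prefix <- paste0(MODEL_TYPE_LABELS[[mt]], "_")
    if (startsWith(base, prefix)) {
      return(list(model_type = mt,
                  accession = substring(base, nchar(prefix) + 1L)))
    }
  }
  NULL
}

#' Run the refinement pipeline over a directory of models
#'
#' @param config a [pipeline_config()].
#' @return manifest list: per-category output file vectors (`refined`,
#'   `relaxed_ligand`, `refined_ligand`), `dropped` (models trimmed below
#'   the survival threshold), `failed` (per-model error messages), and
#'   `log` (per-model outcome codes). The manifest is also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$input_dir)) stop("input directory does not exist",
                                          call. = FALSE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  files <- sort(list.files(config$input_dir, pattern = "\\.pdb$",
                           full.names = TRUE))
  parsed <- lapply(files, parse_input_filename)
  keep <- !vapply(parsed, is.null, logical(1))
  files <- files[keep]; parsed <- parsed[keep]
  is_donor <- vapply(parsed, function(p) p$model_type == "homology", logical(1))
  donors <- files[is_donor]
  names(donors) <- vapply(parsed[is_donor], `[[`, character(1), "accession")

  manifest <- list(refined = character(0), relaxed_ligand = character(0),
                   refined_ligand = character(0), dropped = character(0),
                   failed = character(0), log = list())

  for (k in which(!is_donor)) {
    info <- parsed[[k]]
    tag <- basename(files[k])
    outcome <- tryCatch({
      model <- read_model(files[k], info$model_type)
      model$accession <- info$accession
      codes <- character(0)

      donor_path <- donors[info$accession]
      with_ligands <- NULL
      if ("transplant" %in% config$stages && !is.na(donor_path)) {
        donor <- read_model(donor_path, "homology")
        donor$accession <- info$accession
        tr <- transplant_all(model, donor, config$transplant,
                             minimizer_hook = config$minimizer_hook)
        with_ligands <- tr$model
        codes <- c(codes, paste0("transplant:",
                                 paste(tr$report$outcome, collapse = ",")))
        fn <- dataset_filename(info$model_type, info$accession,
                               "relaxed_ligand")
        write_model(with_ligands, file.path(config$output_dir, fn))
        manifest$relaxed_ligand <- c(manifest$relaxed_ligand, fn)
      }

      if ("trim" %in% config$stages) {
        relaxed <- if (!is.null(config$minimizer_hook)) {
          run_minimizer_hook(model, config$minimizer_hook)
        } else model
        tr <- trim_model(relaxed, config$trim)
        if (tr$report$model_dropped) {
          manifest$dropped <- c(manifest$dropped, tag)
          codes <- c(codes, "trim:dropped")
        } else {
          fn <- dataset_filename(info$model_type, info$accession, "refined")
          write_model(tr$model, file.path(config$output_dir, fn))
          manifest$refined <- c(manifest$refined, fn)
          codes <- c(codes, "trim:ok")
        }
        if (!is.null(with_ligands)) {
          trl <- trim_model(with_ligands, config$trim)
          if (!trl$report$model_dropped) {
            fn <- dataset_filename(info$model_type, info$accession,
                                   "refined_ligand")
            write_model(trl$model, file.path(config$output_dir, fn))
            manifest$refined_ligand <- c(manifest$refined_ligand, fn)
            codes <- c(codes, "trim_ligand:ok")
          } else {
            codes <- c(codes, "trim_ligand:dropped")
          }
        }
      }
      codes
    }, error = function(e) {
      manifest$failed <<- c(manifest$failed,
                            sprintf("%s: %s", tag, conditionMessage(e)))
      "error"
    })
    manifest$log[[tag]] <- outcome
  }

  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  manifest
}
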