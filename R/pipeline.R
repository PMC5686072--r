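# Pipeline configuration and the end-to-end screening funnel:
# library -> pharmacophore screen -> ensemble docking scores -> consensus ->
# Pareto -> property filters -> shortlist, with a per-stage audit log and
# content hashes for written artifacts.

PIPELINE_KEYS <- c("seed", "model", "library", "sizes", "rmsd_max",
                   "scores", "consensus_fraction", "top_n",
                   "properties", "min_solubility", "out_dir")

#' Validate a pipeline configuration
#'
#' @param config Named list, or path to a YAML file. Recognised keys:
#'   `seed` (integer), `model` (a [pharmacophore_model()] or path to a PDB
#'   structure used with the SxIP preset), `library` (list of
#'   [conformer_features()], an SDF path, or a list
#'   `list(n_hits=, n_decoys=, jitter_sigma=)` describing a synthetic
#'   plant), `sizes`, `rmsd_max`, `scores` (CSV path, [score_matrix()], or
#'   `"synthetic"`), `consensus_fraction`, `top_n`, `properties` (CSV path
#'   or data frame), `min_solubility`, `out_dir`. Unknown keys are
#'   rejected.
#' @return The validated config list, class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown) > 0L)
    stop_dynappi(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
                 "dynappi_config_error")
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.null(config$rmsd_max) && config$rmsd_max <= 0)
    stop_dynappi("rmsd_max must be positive", "dynappi_config_error")
  if (!is.null(config$consensus_fraction) &&
      !(config$consensus_fraction > 0 && config$consensus_fraction <= 1))
    stop_dynappi("consensus_fraction must be in (0, 1]", "dynappi_config_error")
  structure(config, class = "pipeline_config")
}

#' Run the screening-to-shortlist pipeline
#'
#' Stages: resolve the pharmacophore model; load or plant the conformer
#' library; screen it ([screen_library()]); obtain a compound x receptor
#' score matrix for the surviving compounds (imported, supplied, or
#' generated with the planted affinity order for synthetic campaigns);
#' aggregate across receptor conformations; run the selection funnel
#' ([run_selection()]). Identical config and seed give identical outputs;
#' when `out_dir` is set, the hit table and shortlist are written as CSV
#' and their MD5 content hashes returned.
#'
#' @param config A [pipeline_config()] (or list / YAML path coerced to one).
#' @return List with `shortlist`, `hits`, `audit` (stage counts incl. the
#'   screen), `seed`, and `artifacts` (paths + md5 hashes) when `out_dir`
#'   is set.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  seed <- config$seed

  # model
  model <- config$model
  if (is.null(model))
    stop_dynappi("stage 'model' failed: no pharmacophore model configured",
                 "dynappi_stage_error")
  if (is.character(model)) model <- build_sxip_model(model)

  # library
  lib_cfg <- config$library
  truth <- NULL
  if (is.null(lib_cfg))
    stop_dynappi("stage 'library' failed: no library configured", "dynappi_stage_error")
  if (is.character(lib_cfg)) {
    library <- read_library_sdf(lib_cfg)
  } else if (is.list(lib_cfg) && !is.null(lib_cfg$n_hits)) {
    planted <- plant_conformer_library(model, lib_cfg$n_hits, lib_cfg$n_decoys %||% 0,
                                       jitter_sigma = lib_cfg$jitter_sigma %||% 0.05,
                                       seed = seed)
    library <- planted$library
    truth <- planted$truth
  } else {
    library <- lib_cfg
  }

  # screen
  hits <- screen_library(library, model, sizes = config$sizes %||% c(5, 6, 7),
                         rmsd_max = config$rmsd_max %||% 0.5)
  audit <- data.frame(stage = "screen", n_in = length(library), n_out = nrow(hits))

  # scores
  sc <- config$scores
  if (is.null(sc))
    stop_dynappi("stage 'scores' failed: no score source configured",
                 "dynappi_stage_error")
  if (is.character(sc) && length(sc) == 1L && sc == "synthetic") {
    if (nrow(hits) == 0L) {
      scores <- NULL
    } else {
      order_ids <- hits$molecule_id  # screen order: best geometric match first
      scores <- make_score_matrix(order_ids,
                                  n_conformations = 20, noise_sd = 1, seed = seed)
    }
  } else if (is.character(sc)) {
    scores <- import_scores(sc)
  } else {
    scores <- sc
  }

  # properties: default neutral table for synthetic campaigns
  props <- config$properties
  if (is.character(props)) props <- read.csv(props, stringsAsFactors = FALSE)
  if (is.null(props) && nrow(hits) > 0L) {
    props <- data.frame(id = hits$molecule_id, heavy_atoms = 20, mw = 300,
                        logp = 2, hbd = 1, hba = 4, solubility = 1e-3)
  }

  if (nrow(hits) == 0L || is.null(scores)) {
    sel <- list(shortlist = data.frame(id = character(0)), audit = audit)
    shortlist <- sel$shortlist
  } else {
    scores <- scores[rownames(scores) %in% hits$molecule_id, , drop = FALSE]
    # aggregate across receptor conformations, then feed the ensemble mean
    # into the selection funnel as the (single) consensus scoring column
    agg <- aggregate_ensemble_scores(scores)
    sel_scores <- matrix(agg$mean, ncol = 1,
                         dimnames = list(agg$id, "ensemble_mean"))
    sel <- run_selection(list(
      scores = score_matrix(sel_scores, higher_is_better = TRUE),
      properties = props,
      consensus_fraction = config$consensus_fraction %||% 0.25,
      top_n = config$top_n,
      min_solubility = config$min_solubility %||% 1e-4))
    audit <- rbind(audit, sel$audit)
    shortlist <- sel$shortlist
  }

  out <- list(shortlist = shortlist, hits = hits, audit = audit,
              truth = truth, seed = seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(hits = file.path(config$out_dir, "hits.csv"),
               shortlist = file.path(config$out_dir, "shortlist.csv"))
    write.csv(hits, paths[["hits"]], row.names = FALSE)
    write.csv(shortlist, paths[["shortlist"]], row.names = FALSE)
    audit_path <- file.path(config$out_dir, "audit.json")
    jsonlite::write_json(list(seed = seed, stages = audit,
                              hashes = as.list(tools::md5sum(paths))),
                         audit_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    out$artifacts <- data.frame(path = c(paths, audit = audit_path),
                                md5 = c(tools::md5sum(paths), NA))
  }
  out
}
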