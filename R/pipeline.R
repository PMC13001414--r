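#' Default end-to-end run configuration
#'
#' The demo scale (20 variants x 4 replicas x 200 frames, compactness
#' metrics on a thinned subset of wild-type frames) completes on one CPU
#' in a few minutes; the full study design is 16 replicas x 1000 frames.
#'
#' @param seed master RNG seed.
#' @param out_dir output directory.
#' @param n_replicas,n_frames synthetic design per variant.
#' @param wild_type,position,prefix variant panel definition.
#' @param pca_k number of principal components for ranking.
#' @param metrics_frames number of wild-type frames realized as
#'   coordinates for the compactness stage (0 disables it).
#' @return a `run_config` list, YAML-serializable.
#' @export
default_run_config <- function(seed = 1, out_dir = tempfile("idprun"),
                               n_replicas = 4, n_frames = 200,
                               wild_type = MLP_WT, position = 2,
                               prefix = "MLP", pca_k = 2,
                               metrics_frames = 25) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    wild_type = wild_type,
    position = as.integer(position),
    prefix = prefix,
    n_replicas = as.integer(n_replicas),
    n_frames = as.integer(n_frames),
    pca_k = as.integer(pca_k),
    metrics_frames = as.integer(metrics_frames),
    grouping = default_grouping(),
    region_map = lapply(default_region_map(), function(r)
      lapply(seq_len(nrow(r)), function(j) as.list(r[j, ])))
  ), class = "run_config")
}

#' Run-config YAML round trip
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `save_run_config`: `path` invisibly; `load_run_config`: a
#'   `run_config` equal to the saved one.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  for (f in c("seed", "position", "n_replicas", "n_frames", "pca_k",
              "metrics_frames"))
    obj[[f]] <- as.integer(obj[[f]])
  structure(obj, class = "run_config")
}

## materialize the region_map entry of a config as a region_map object
config_region_map <- function(config) {
  if (is.null(config$region_map)) return(default_region_map())
  known <- setdiff(RAMA_CLASSES, "unassigned")
  bad <- setdiff(names(config$region_map), known)
  if (length(bad))
    stop("configuration error: unknown region name(s): ",
         paste(bad, collapse = ", "))
  map <- structure(lapply(config$region_map, function(rects)
    do.call(rbind, lapply(rects, as.data.frame))), class = "region_map")
  validate_region_map(map)
  map
}

#' Run the full analysis pipeline
#'
#' Panel construction, synthetic ensemble generation per variant
#' (variant-specific propensity at the mutated position), per-replica
#' occupancy, replica-averaged summaries, deviation profiles versus
#' wild type, the 3-class feature matrix, PCA, variant ranking, and an
#' optional compactness stage on realized wild-type coordinates. All
#' stages are deterministic given `config$seed`; outputs are written to
#' `config$out_dir` together with a machine-readable manifest.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @return invisibly, a list with the in-memory results: `panel`,
#'   `occupancy` (list of `occupancy_set`), `summaries`, `deviations`,
#'   `features`, `pca`, `scores`, `ranking`, `compactness` (or NULL),
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  map <- config_region_map(config)  # fail fast on bad region config
  grouping <- config$grouping %||% default_grouping()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  log_msg <- function(stage, ...)
    message(sprintf("[idpensemble:%s] %s", stage, sprintf(...)))

  log_msg("panel", "building %d-member panel at position %d",
          20, config$position)
  panel <- make_variant_panel(config$wild_type, config$position,
                              config$prefix)
  write_panel_fasta(panel, out("panel.fasta"))
  write_panel_json(panel, out("panel.json"))

  log_msg("simulate", "%d variants x %d replicas x %d frames",
          length(panel$members), config$n_replicas, config$n_frames)
  occ_sets <- list()
  for (i in seq_along(panel$members)) {
    v <- panel$members[[i]]
    prof <- default_propensity_profile(v, mutate_position = config$position)
    ens <- generate_ensemble(v, prof, n_replicas = config$n_replicas,
                             n_frames = config$n_frames,
                             seed = config$seed + 1000L * i,
                             map = map)
    occ_sets[[v$label]] <- occupancy(ens$dihedrals, map)
  }
  for (lab in names(occ_sets))
    write_occupancy_csv(occ_sets[[lab]],
                        out(sprintf("occupancy_%s.csv", lab)))

  log_msg("occupancy", "averaging profiles across replicas")
  summaries <- lapply(occ_sets, average_profiles)
  wt_label <- panel$wild_type$label
  deviations <- lapply(setdiff(names(summaries), wt_label), function(lab)
    deviation_profile(summaries[[lab]], summaries[[wt_label]]))
  names(deviations) <- setdiff(names(summaries), wt_label)
  for (lab in names(deviations))
    write_deviation_csv(deviations[[lab]],
                        out(sprintf("deviation_%s.csv", lab)))

  log_msg("compare", "PCA on %d trajectories", length(occ_sets) *
            config$n_replicas)
  X <- build_features(occ_sets, grouping)
  model <- fit_pca(X)
  scores <- project_pca(model, X, k = config$pca_k)
  ranking <- rank_variants(scores, wt_label)
  write_pca_json(model, out("pca_model.json"))
  write_ranking_csv(ranking, out("ranking.csv"))

  compact <- NULL
  if (config$metrics_frames > 0) {
    log_msg("compact", "compactness metrics on %d wild-type frames",
            config$metrics_frames)
    wt_prof <- default_propensity_profile(panel$wild_type)
    per_rep <- max(1L,
                   config$metrics_frames %/% min(config$n_replicas, 4L))
    ens <- generate_ensemble(panel$wild_type, wt_prof,
                             n_replicas = min(config$n_replicas, 4L),
                             n_frames = per_rep,
                             seed = config$seed + 99L, coords = TRUE,
                             map = map)
    rec <- compactness_records(ens)
    utils::write.csv(cbind(variant = wt_label, rec),
                     out("compactness_wt.csv"),
                     row.names = FALSE, quote = FALSE)
    compact <- ensemble_summary(rec)
  }

  manifest <- list(
    package = "idpensemble",
    version = as.character(utils::packageVersion("idpensemble")),
    seed = config$seed,
    design = list(variants = length(panel$members),
                  replicas = config$n_replicas,
                  frames = config$n_frames),
    config_hash = digest_config(config),
    outputs = list.files(config$out_dir)
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg("done", "outputs in %s", config$out_dir)
  invisible(list(panel = panel, occupancy = occ_sets,
                 summaries = summaries, deviations = deviations,
                 features = X, pca = model, scores = scores,
                 ranking = ranking, compactness = compact,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## stable content hash of a config (serialization-based, no extra deps)
digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config)[sort(names(unclass(config)))], tmp,
          compress = FALSE)
  unname(tools::md5sum(tmp))
}
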