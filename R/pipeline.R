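#' Compute the drug embedding for a pipeline variant
#'
#' * `"full"` — similarity -> random walk diffusion -> PPMI -> autoencoder
#'   fusion (five networks).
#' * `"no_atc"` — same but without the ATC network (four networks).
#' * `"mda_raw"` — autoencoder fusion of the min-max-scaled similarity
#'   matrices, skipping the diffusion stages.
#' * `"sim_avg"` — no autoencoder: the five similarity matrices are
#'   averaged into one integrated similarity matrix whose rows serve as
#'   drug features directly (the simplest baseline).
#'
#' All variants are label-free: no interaction information enters here.
#'
#' @param dataset a `ddi_dataset`.
#' @param config a [pipeline_config()].
#' @param variant one of `"full"`, `"no_atc"`, `"mda_raw"`, `"sim_avg"`.
#' @return a `unified_embedding` (for `sim_avg`, the averaged similarity
#'   matrix wrapped as one).
#' @export
build_embedding <- function(dataset, config,
                            variant = c("full", "no_atc", "mda_raw", "sim_avg")) {
  variant <- match.arg(variant)
  atc <- if (variant == "no_atc") NULL else dataset$atc
  sims <- build_all_similarities(dataset$features, atc, dataset$catalog)
  seed <- config$cv$seed
  if (variant == "sim_avg") {
    avg <- Reduce(`+`, lapply(sims, `[[`, "values")) / length(sims)
    rownames(avg) <- dataset$catalog$drug_ids
    return(structure(list(values = avg, d_u = ncol(avg)),
                     class = "unified_embedding"))
  }
  mats <- if (variant == "mda_raw") {
    lapply(sims, `[[`, "values")
  } else {
    nets <- build_all_networks(sims, alpha = config$alpha,
                               epsilon = config$epsilon)
    lapply(nets, `[[`, "values")
  }
  scaled <- scale_networks(mats)
  train_mda(scaled$nets, config$mda, seed = substream_seed(seed, variant))$embedding
}

#' Run one ablation variant under shared folds
#'
#' All variants are evaluated through [run_cv()] with the same `config`,
#' hence identical CV folds and fold seeds — results are directly
#' comparable across variants.
#'
#' @param dataset a `ddi_dataset`.
#' @param config a [pipeline_config()].
#' @param variant see [build_embedding()].
#' @return a `cv_report`.
#' @export
ablation_run <- function(dataset, config,
                         variant = c("full", "no_atc", "mda_raw", "sim_avg")) {
  variant <- match.arg(variant)
  run_cv(dataset, config, variant = variant)
}

#' Run the full pipeline end to end with file artifacts
#'
#' Executes featurize -> embed-networks -> fuse -> evaluate, writing every
#' stage artifact (similarities, topological networks, embedding,
#' metrics, manifest) under `outdir`. A stage whose output files already
#' exist under `outdir` is skipped and its artifacts are reloaded, so a
#' run is resumable; delete files to force recomputation.
#'
#' @param dataset a `ddi_dataset`, or `NULL` to simulate one from
#'   `synth` (the `--simulate` path).
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param synth optional [synth_config()] used when `dataset` is `NULL`.
#' @return list with `report` (a `cv_report`), `embedding` and
#'   `manifest` (paths, config snapshot and wall times per stage).
#' @export
run_pipeline <- function(dataset = NULL, config = pipeline_config(),
                         outdir = tempfile("ddinet_run_"), synth = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), stages = list(),
                   outdir = outdir)
  timer <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    manifest$stages[[name]] <<- list(seconds = proc.time()[["elapsed"]] - t0)
    out
  }
  if (is.null(dataset)) {
    if (is.null(synth)) synth <- synth_config()
    dataset <- timer("simulate", generate_dataset(synth))
    write_dataset(dataset, file.path(outdir, "data"))
  }
  catalog <- dataset$catalog
  sim_paths <- file.path(outdir, paste0("similarity_",
                                        c("struct", "target", "pathway",
                                          "enzyme", "atc"), ".tsv"))
  names(sim_paths) <- c("struct", "target", "pathway", "enzyme", "atc")
  if (all(file.exists(sim_paths))) {
    ddi_log("info", "resuming: similarity matrices found in %s", outdir)
    sims <- lapply(names(sim_paths), function(nm) {
      similarity_matrix(load_matrix(sim_paths[[nm]], catalog), nm)
    })
    names(sims) <- names(sim_paths)
  } else {
    sims <- timer("featurize",
                  build_all_similarities(dataset$features, dataset$atc, catalog))
    for (nm in names(sims)) save_matrix(sims[[nm]]$values, sim_paths[[nm]], catalog)
  }
  net_paths <- file.path(outdir, paste0("network_", names(sims), ".tsv"))
  names(net_paths) <- names(sims)
  if (all(file.exists(net_paths))) {
    ddi_log("info", "resuming: topological networks found in %s", outdir)
    nets <- lapply(names(net_paths), function(nm) {
      structure(list(source_name = nm,
                     values = load_matrix(net_paths[[nm]], catalog)),
                class = "ppmi_network")
    })
    names(nets) <- names(net_paths)
  } else {
    nets <- timer("embed_networks",
                  build_all_networks(sims, alpha = config$alpha,
                                     epsilon = config$epsilon))
    for (nm in names(nets)) save_matrix(nets[[nm]]$values, net_paths[[nm]], catalog)
  }
  emb_path <- file.path(outdir, "embedding.tsv")
  if (file.exists(emb_path)) {
    ddi_log("info", "resuming: embedding found in %s", outdir)
    embedding <- structure(list(values = load_matrix(emb_path, catalog)),
                           class = "unified_embedding")
    embedding$d_u <- ncol(embedding$values)
  } else {
    scaled <- scale_networks(lapply(nets, `[[`, "values"))
    embedding <- timer("fuse",
                       train_mda(scaled$nets, config$mda,
                                 seed = substream_seed(config$cv$seed, "full"))$embedding)
    save_matrix(embedding$values, emb_path, catalog)
  }
  report <- timer("evaluate", run_cv(dataset, config, embedding = embedding))
  metrics_df <- data.frame(metric = names(report$aggregate),
                           mean = as.numeric(report$aggregate),
                           sd = as.numeric(report$sd))
  write_delim_file(metrics_df, file.path(outdir, "metrics.tsv"))
  jsonlite::write_json(list(scene = report$scene,
                            aggregate = as.list(report$aggregate),
                            sd = as.list(report$sd),
                            chance_f1_macro = report$chance_f1_macro),
                       file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  save_type_map(dataset$ddis, file.path(outdir, "type_map.tsv"))
  manifest$paths <- list(similarities = as.list(sim_paths),
                         networks = as.list(net_paths),
                         embedding = emb_path,
                         metrics = file.path(outdir, "metrics.json"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(report = report, embedding = embedding, manifest = manifest)
}
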