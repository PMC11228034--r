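# Pipeline driver: one configuration object, one call, every stage, with
# per-stage seeds derived from the global seed and all artifacts written
# under a config-stamped manifest.

#' Build a pipeline run configuration
#'
#' Either synthetic mode (`wiring` is a [wiring_spec()]; bilateral pairs,
#' synapse clouds, and an eyemap with planted receptive fields are
#' generated alongside) or real-data mode (`edges_path` plus input/output
#' id vectors, and optional location/eyemap files).
#'
#' @param out_dir output directory for artifacts.
#' @param seed global seed; every stochastic stage uses
#'   `derive_seed(seed, stage)`.
#' @param threshold synapse threshold (default 5).
#' @param n_shuffles shuffle-null size (default 1000).
#' @param k_range cluster-number range for conditional-input K-means and
#'   output spectral clustering.
#' @param wiring a `wiring_spec` for synthetic mode, or NULL.
#' @param edges_path,inputs,outputs real-data edge list and axis ids.
#' @param run_bilateral,run_synapse_typing,run_rf stage switches; stages
#'   missing their inputs are skipped with a notice regardless.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, threshold = 5L,
                       n_shuffles = 1000L, k_range = 2:10,
                       wiring = wiring_spec(),
                       edges_path = NULL, inputs = NULL, outputs = NULL,
                       run_bilateral = TRUE, run_synapse_typing = TRUE,
                       run_rf = TRUE) {
  stopifnot(is.character(out_dir), length(out_dir) == 1)
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed),
      threshold = as.integer(threshold),
      n_shuffles = as.integer(n_shuffles), k_range = as.integer(k_range),
      wiring = wiring, edges_path = edges_path,
      inputs = inputs, outputs = outputs,
      run_bilateral = isTRUE(run_bilateral),
      run_synapse_typing = isTRUE(run_synapse_typing),
      run_rf = isTRUE(run_rf)
    ),
    class = "run_config"
  )
}

#' Run the full wiring-analysis pipeline
#'
#' Executes, in order: matrix assembly, input summaries, PCA spectrum test,
#' bilateral stereotypy test, participation ratio, conditional-input
#' analysis, output clustering, synapse typing (when synapse locations are
#' available), and receptive-field estimation (when an eyemap is
#' available). Stages missing their inputs are skipped with a notice.
#' Every artifact is a CSV or JSON file under `cfg$out_dir`; the manifest
#' records the full configuration, its hash, per-stage seeds, and the
#' artifact list, so a rerun with the same seed is byte-identical.
#'
#' @param cfg a [run_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  emit_csv <- function(obj, name) {
    p <- file.path(cfg$out_dir, paste0(name, ".csv"))
    utils::write.csv(obj, p, row.names = FALSE)
    artifacts <<- c(artifacts, basename(p))
  }
  emit_json <- function(obj, name) {
    p <- file.path(cfg$out_dir, paste0(name, ".json"))
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <<- c(artifacts, basename(p))
  }
  stage_seed <- function(stage) derive_seed(cfg$seed, stage)

  # --- matrix assembly ------------------------------------------------
  synthetic <- is.null(cfg$edges_path)
  if (synthetic) {
    m <- generate_wiring(cfg$wiring, seed = stage_seed("wiring"))
    groups <- setNames(
      paste0("G", attr(m, "input_community")), input_ids(m)
    )
  } else {
    edges <- read_edges(cfg$edges_path)
    m <- build_matrix(edges, cfg$inputs, cfg$outputs,
                      threshold = cfg$threshold)
    groups <- setNames(rep("all", nrow(m$W)), input_ids(m))
  }
  write_edges(m, file.path(cfg$out_dir, "matrix_edges.csv"))
  artifacts <- c(artifacts, "matrix_edges.csv")

  # --- summaries ------------------------------------------------------
  summ <- summarize_inputs(m, groups)
  emit_csv(summ$group_summary, "group_summary")
  emit_csv(summ$input_ranking, "input_ranking")

  # --- spectrum test --------------------------------------------------
  spec_cfg <- shuffle_config(cfg$n_shuffles, seed = stage_seed("spectrum"))
  spect <- pca_spectrum_test(m, spec_cfg)
  emit_json(list(
    observed_fractions = spect$observed_fractions,
    null_mean = spect$null_mean, null_lo = spect$null_lo,
    null_hi = spect$null_hi,
    components_outside = spect$components_outside,
    n_shuffles = spect$n_shuffles, seed = spec_cfg$seed
  ), "spectrum")

  # --- bilateral test -------------------------------------------------
  bil <- NULL
  if (cfg$run_bilateral && synthetic) {
    pair <- generate_bilateral_pair(cfg$wiring, "independent",
                                    seed = stage_seed("bilateral"))
    bil <- bilateral_identity_test(
      pair$left, pair$right, pair$tmap,
      shuffle_config(cfg$n_shuffles, seed = stage_seed("bilateral_null"))
    )
    emit_json(list(
      observed_count = bil$observed_count, p_value = bil$p_value,
      n_eligible = bil$n_eligible, mode = bil$mode,
      null_mean = mean(bil$null_counts)
    ), "bilateral")
  } else if (cfg$run_bilateral) {
    message("bilateral stage skipped: needs a hemisphere pair")
  }

  # --- participation ratio -------------------------------------------
  pr <- participation_ratio(m)
  emit_json(pr, "participation_ratio")

  # --- conditional input ----------------------------------------------
  ci <- conditional_input_analysis(
    m, shuffle_config(cfg$n_shuffles, seed = stage_seed("condinput")),
    k_range = cfg$k_range
  )
  emit_csv(as.data.frame(ci$z), "conditional_input_z")
  emit_csv(as.data.frame(ci$count), "conditional_input_count")

  # --- output clustering ----------------------------------------------
  clus <- cluster_outputs(m, k_range = cfg$k_range,
                          seed = stage_seed("cluster"))
  emit_csv(
    data.frame(output_id = names(clus$labels), cluster = clus$labels),
    "output_clusters"
  )
  emit_json(list(
    selected_k = clus$selected_k, silhouette = as.list(clus$silhouette),
    no_clear_structure = clus$no_clear_structure,
    row_order = clus$row_order, col_order = clus$col_order
  ), "cluster_orders")

  # --- synapse typing -------------------------------------------------
  syn <- NULL
  if (cfg$run_synapse_typing && synthetic) {
    s <- stage_seed("syntype")
    mk_cloud <- function(class, i) {
      list(points = generate_synapse_cloud(class, n_synapses = 20,
                                           scale = if (class == "bouton_claw") 500 else 10000,
                                           seed = derive_seed(s, paste0(class, i))),
           label = class)
    }
    labeled <- c(lapply(1:30, function(i) mk_cloud("bouton_claw", i)),
                 lapply(1:30, function(i) mk_cloud("en_passant", i)))
    syn <- calibrate_and_classify(labeled, seed = derive_seed(s, "split"))
    emit_json(syn$calibration, "synapse_typing")
  } else if (cfg$run_synapse_typing) {
    message("synapse-typing stage skipped: no synapse locations")
  }

  # --- receptive fields ----------------------------------------------
  rf_out <- NULL
  if (cfg$run_rf && synthetic) {
    s <- stage_seed("rf")
    eye <- make_hex_eyemap(n_columns = 361)
    specs <- with_seed(s, lapply(1:5, function(i) {
      list(neuron_id = paste0("V", i),
           center = sample(eye$column_ids, 1), n_columns = 20)
    }))
    vs <- generate_visual_system(eye, specs, seed = derive_seed(s, "system"))
    rf_rows <- do.call(rbind, lapply(names(vs$skeletons), function(id) {
      cov <- covered_columns(vs$skeletons[[id]], eye, vs$layer,
                             vs$threshold_nm)
      rf <- rf_from_columns(cov, eye)
      data.frame(neuron_id = id, n_covered = length(rf$covered),
                 size = rf$size,
                 centroid_x = rf$centroid[1], centroid_y = rf$centroid[2],
                 centroid_z = rf$centroid[3])
    }))
    rf_out <- rf_rows
    emit_csv(rf_rows, "receptive_fields")
  } else if (cfg$run_rf) {
    message("receptive-field stage skipped: no eyemap")
  }

  # --- manifest -------------------------------------------------------
  cfg_plain <- cfg
  cfg_plain$wiring <- unclass(cfg_plain$wiring)
  cfg_json <- jsonlite::toJSON(unclass(cfg_plain), auto_unbox = TRUE,
                               digits = NA, null = "null")
  manifest <- list(
    config = jsonlite::fromJSON(cfg_json),
    config_hash = str_hash(as.character(cfg_json)),
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
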