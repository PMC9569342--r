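#' Default pipeline configuration
#'
#' All stage parameters in one (JSON-serializable) list: generator settings,
#' networking tolerances and thresholds, classifier grid, series-detection
#' rules and annotation tolerance. The t-SNE layout settings used by the
#' upstream visualization tool (perplexity 25, 5000 iterations, learning
#' rate 200, early exaggeration 12) are recorded for provenance only;
#' layout is out of scope.
#'
#' @param seed RNG seed for the simulate stage.
#' @return named list of stage parameter lists.
#' @export
default_config <- function(seed = 42L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_series = 20L, n_full = 12L, n_decoys = 200L,
                    mass_jitter_ppm = 2, envelope_noise = 0.05),
    network = list(frag_tol = 0.02, min_matched = 2L, min_score = 0.65,
                   window_top_k = 6L, window_half = 50,
                   precursor_exclusion = 17),
    classify = list(max_cl = 3L, max_br = 2L, margin_threshold = 0.02),
    series = list(ppm_tol = 5, rt_rule = "warn", min_msms_cosine = 0.5,
                  require_condition = TRUE),
    annotate = list(ppm_tol = 5),
    provenance = list(tsne = list(iterations = 5000L, perplexity = 25,
                                  learning_rate = 200,
                                  early_exaggeration = 12))
  )
}

.write_manifest <- function(dir, stage, config, inputs, outputs) {
  # paths recorded as basenames so manifests are location-independent and
  # reruns with identical config produce identical manifest bytes
  checksum <- function(paths) {
    paths <- unlist(paths, use.names = FALSE)
    if (length(paths) == 0L) return(list())
    paths <- paths[file.exists(paths)]
    sums <- tools::md5sum(paths)
    as.list(stats::setNames(unname(sums), basename(paths)))
  }
  manifest <- list(
    stage = stage,
    package = "halonet",
    version = as.character(utils::packageVersion("halonet")),
    config = config,
    input_checksums = checksum(unlist(inputs, use.names = FALSE)),
    outputs = as.list(basename(unlist(outputs, use.names = FALSE)))
  )
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run pipeline stages
#'
#' Orchestrates the stages on files in `out_dir`:
#' \describe{
#'   \item{simulate}{generate the synthetic dataset (features.csv,
#'     spectra.mgf, truth.tsv).}
#'   \item{network}{build the modified-cosine molecular network
#'     (network.graphml).}
#'   \item{classify}{MS1-envelope halogen calls (halogen_calls.csv).}
#'   \item{series}{OSMAC substitution-series detection (series.csv,
#'     series_report.csv when the network exists).}
#'   \item{annotate}{reference-library annotation (annotations.csv).}
#'   \item{all}{all of the above, in order.}
#' }
#' Every stage writes a JSON run manifest (config echo, input checksums,
#' package version). Wall-clock timestamps are deliberately omitted so a
#' rerun with identical config yields identical artifact checksums.
#' Existing artifacts are not overwritten unless `force = TRUE`.
#'
#' @param stage one of simulate, network, classify, series, annotate, all.
#' @param config list from [default_config()] (or a JSON file path).
#' @param out_dir working/output directory.
#' @param force overwrite existing artifacts.
#' @return named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "network", "classify",
                                   "series", "annotate"),
                         config = default_config(), out_dir,
                         force = FALSE) {
  stage <- match.arg(stage)
  if (is.character(config) && length(config) == 1L &&
      file.exists(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed)) stop("invalid config: missing field 'seed'",
                                 call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- if (stage == "all") c("simulate", "network", "classify",
                                  "series", "annotate") else stage
  paths <- list(features = file.path(out_dir, "features.csv"),
                mgf = file.path(out_dir, "spectra.mgf"),
                truth = file.path(out_dir, "truth.tsv"),
                network = file.path(out_dir, "network.graphml"),
                calls = file.path(out_dir, "halogen_calls.csv"),
                series = file.path(out_dir, "series.csv"),
                series_report = file.path(out_dir, "series_report.csv"),
                annotations = file.path(out_dir, "annotations.csv"))
  artifacts <- list()
  guard <- function(p) {
    if (file.exists(p) && !force) {
      stop("artifact exists (use force = TRUE to overwrite): ", p,
           call. = FALSE)
    }
  }
  load_ft <- function() {
    if (!file.exists(paths$features)) {
      stop("missing input: ", paths$features, call. = FALSE)
    }
    read_feature_csv(paths$features,
                     mgf = if (file.exists(paths$mgf)) paths$mgf)
  }

  for (st in stages) {
    if (st == "simulate") {
      guard(paths$features)
      sim_cfg <- do.call(generator_config,
                         c(list(seed = config$seed),
                           config$simulate[names(config$simulate) %in%
                                             names(formals(generator_config))]))
      generate_dataset(sim_cfg, dir = out_dir)
      artifacts$features <- paths$features
      artifacts$mgf <- paths$mgf
      artifacts$truth <- paths$truth
      artifacts$manifest_simulate <-
        .write_manifest(out_dir, "simulate", config, list(),
                        paths[c("features", "mgf", "truth")])
      message("simulate: wrote ", paths$features)
    } else if (st == "network") {
      guard(paths$network)
      ft <- load_ft()
      p <- config$network
      net <- build_network(ft, min_matched = p$min_matched,
                           min_score = p$min_score, frag_tol = p$frag_tol)
      export_graphml(net, paths$network)
      artifacts$network <- paths$network
      artifacts$manifest_network <-
        .write_manifest(out_dir, "network", config,
                        paths[c("features", "mgf")], paths["network"])
      message("network: ", igraph::vcount(net), " nodes, ",
              igraph::ecount(net), " edges")
    } else if (st == "classify") {
      guard(paths$calls)
      ft <- load_ft()
      p <- config$classify
      calls <- classify_features(ft, max_cl = p$max_cl, max_br = p$max_br,
                                 margin_threshold = p$margin_threshold)
      utils::write.csv(calls, paths$calls, row.names = FALSE, quote = FALSE)
      artifacts$calls <- paths$calls
      artifacts$manifest_classify <-
        .write_manifest(out_dir, "classify", config, paths["features"],
                        paths["calls"])
      message("classify: ", sum(calls$status == "confident" &
                                  (calls$n_cl > 0 | calls$n_br > 0),
                                na.rm = TRUE),
              " confident halogen calls")
    } else if (st == "series") {
      guard(paths$series)
      ft <- load_ft()
      p <- config$series
      calls <- if (file.exists(paths$calls)) {
        utils::read.csv(paths$calls, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
      } else NULL
      ser <- find_series(ft, ppm_tol = p$ppm_tol, rt_rule = p$rt_rule,
                         min_msms_cosine = p$min_msms_cosine,
                         require_condition = p$require_condition,
                         halogen_calls = calls)
      utils::write.csv(series_table(ser), paths$series, row.names = FALSE,
                       quote = FALSE)
      artifacts$series <- paths$series
      if (file.exists(paths$network)) {
        net <- igraph::read_graph(paths$network, format = "graphml")
        utils::write.csv(series_report(ser, net), paths$series_report,
                         row.names = FALSE)
        artifacts$series_report <- paths$series_report
      }
      artifacts$manifest_series <-
        .write_manifest(out_dir, "series", config,
                        paths[c("features", "calls")], paths["series"])
      message("series: ", length(ser), " substitution series")
    } else if (st == "annotate") {
      guard(paths$annotations)
      ft <- load_ft()
      ann <- match_library(ft, ppm_tol = config$annotate$ppm_tol)
      utils::write.csv(ann, paths$annotations, row.names = FALSE,
                       quote = FALSE)
      artifacts$annotations <- paths$annotations
      artifacts$manifest_annotate <-
        .write_manifest(out_dir, "annotate", config, paths["features"],
                        paths["annotations"])
      message("annotate: ", nrow(ann), " library hits")
    }
  }
  invisible(artifacts)
}
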