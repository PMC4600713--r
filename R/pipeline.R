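#' Pipeline configuration
#'
#' Gathers every tunable of the analysis in one structured object. Either
#' supply `generator` parameters (synthetic cohort) or `input_paths`
#' (existing connectome files, one per scan, optionally with
#' `input_subjects` / `input_scans` tags and a `labels_path`).
#'
#' @param generator a [generator_params] object, or NULL when reading files.
#' @param n_subjects,n_scans cohort design for the generator.
#' @param input_paths,input_subjects,input_scans,labels_path file-based
#'   input description (`input_format` as in [read_connectome]).
#' @param input_format connectome file format.
#' @param scheme,c stabilization scheme and constant (see [stabilize]).
#' @param boundary list of [boundary_controllability] tunables
#'   (`n_runs`, `resolution`, `consensus_threshold`, `order`).
#' @param k hub count.
#' @param degree_mode `"sum"` or `"mean"` (see [weighted_degree]).
#' @param diagnostics diagnostics aggregated in the cohort stage.
#' @param seed master seed (drives generation and boundary partitioning).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_params(),
                            n_subjects = 8, n_scans = 3,
                            input_paths = NULL, input_subjects = NULL,
                            input_scans = NULL, labels_path = NULL,
                            input_format = "auto",
                            scheme = "spectral", c = 1,
                            boundary = list(n_runs = 100, resolution = 1,
                                            consensus_threshold = 0.95,
                                            order = "breadth_first"),
                            k = 30, degree_mode = "sum",
                            diagnostics = c("avg_ctrl", "modal_ctrl",
                                            "boundary_ctrl"),
                            seed = 1) {
  cfg <- list(generator = generator, n_subjects = n_subjects,
              n_scans = n_scans, input_paths = input_paths,
              input_subjects = input_subjects, input_scans = input_scans,
              labels_path = labels_path, input_format = input_format,
              scheme = scheme, c = c, boundary = boundary, k = k,
              degree_mode = degree_mode, diagnostics = diagnostics,
              seed = as.integer(seed))
  if (is.null(cfg$generator) && is.null(cfg$input_paths))
    stop("config needs either generator params or input paths")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Any field of [pipeline_config] may appear; `generator:` holds
#' [generator_params] fields.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- NULL
  if (!is.null(y$generator)) gen <- do.call(generator_params, y$generator)
  args <- y[setdiff(names(y), "generator")]
  do.call(pipeline_config, c(list(generator = gen), args))
}

#' Run the full controllability pipeline
#'
#' Generate (or ingest) a cohort of connectomes, stabilize each scan,
#' compute all per-region controllability diagnostics, then the
#' cross-subject cohort analysis, writing every result table plus a run
#' manifest under `out_dir`:
#'
#' * `profiles.tsv` — per-region x scan diagnostics,
#' * `labels.tsv` — region-system assignments,
#' * `mean_ranks.tsv`, `hubs.tsv`, `enrichment.tsv`,
#'   `system_hub_means.tsv`, `correlations.tsv` — cohort tables,
#' * `manifest.yaml` — the full configuration, seed and package version.
#'
#' Given identical configuration and seed, every output file is
#' byte-identical across runs.
#'
#' @param config a [pipeline_config] (or a YAML path).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage messages.
#' @return the [cohort_analysis] result, invisibly, with attribute
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }

  cohort <- stage("ingest", {
    if (!is.null(config$input_paths)) {
      say("reading ", length(config$input_paths), " connectome file(s)")
      Map(function(p, s, r) read_connectome(p, config$input_format,
                                            subject = s, scan = r),
          config$input_paths,
          config$input_subjects %||% sprintf("S%d",
                                             seq_along(config$input_paths)),
          config$input_scans %||% rep("1", length(config$input_paths)))
    } else {
      say("generating cohort: ", config$n_subjects, " subjects x ",
          config$n_scans, " scans, N = ", config$generator$n_regions)
      gen <- config$generator
      gen$seed <- config$seed
      generate_cohort(gen, config$n_subjects, config$n_scans)
    }
  })
  regions <- cohort[[1]]$regions

  labels <- stage("labels", {
    if (!is.null(config$labels_path)) read_system_labels(config$labels_path)
    else generate_system_labels(length(regions), seed = config$seed,
                                regions = regions)
  })
  write_system_labels(labels, file.path(out_dir, "labels.tsv"))

  profiles <- stage("profiles", {
    say("computing control profiles for ", length(cohort), " scan(s)")
    bp <- config$boundary
    bp$seed <- config$seed
    do.call(rbind, lapply(cohort, function(conn) {
      sys <- stabilize(conn, scheme = config$scheme, c = config$c)
      control_profile(conn, sys, boundary_params = bp,
                      degree_mode = config$degree_mode)
    }))
  })
  write_profiles(profiles, file.path(out_dir, "profiles.tsv"))

  result <- stage("cohort", {
    say("aggregating across scans")
    cohort_analysis(profiles, labels, k = config$k,
                    diagnostics = config$diagnostics)
  })
  write_result_table(result$mean_ranks, file.path(out_dir, "mean_ranks.tsv"))
  hubs_df <- do.call(rbind, lapply(names(result$hubs), function(d)
    data.frame(diagnostic = d, rank = seq_along(result$hubs[[d]]),
               region_id = result$hubs[[d]], stringsAsFactors = FALSE)))
  write_result_table(hubs_df, file.path(out_dir, "hubs.tsv"))
  if (!is.null(result$enrichment))
    write_result_table(result$enrichment,
                       file.path(out_dir, "enrichment.tsv"))
  if (!is.null(result$hub_means))
    write_result_table(result$hub_means,
                       file.path(out_dir, "system_hub_means.tsv"))
  write_result_table(result$correlations,
                     file.path(out_dir, "correlations.tsv"))

  manifest <- list(
    package = "netctrl",
    version = as.character(utils::packageVersion("netctrl")),
    seed = config$seed,
    config = unclass_config(config))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  say("results written to ", out_dir)
  attr(result, "out_dir") <- out_dir
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip classes so the manifest serializes as plain YAML
unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  if (!is.null(cfg$generator)) cfg$generator <- unclass(cfg$generator)
  cfg
}
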