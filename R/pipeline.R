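# End-to-end orchestration: synthetic (or file-based) inputs -> bioactivity
# trace -> delay alignment -> feature detection -> molecular network ->
# bioactive mapping, with all artifacts written to an output directory.

#' Run the whole pipeline
#'
#' Inputs come either from `config$paths` (an MS run plus a plate CSV, and
#' optionally a calibrant run/plate pair for delay estimation) or, when no
#' paths are set, from the synthetic generator configured in
#' `config$synthetic` (which also simulates a calibrant injection with the
#' same delay). The stages are: plate normalization and trace construction;
#' delay estimation (calibrant) or the configured delay; delay correction
#' and bioactivity peak calling; MZmine-style feature detection; FBMN-style
#' export; modified-cosine network construction; RT correlation of
#' bioactive peaks with features; in-source relation annotation; bioactive
#' node marking.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory for artifacts (created if needed); `NULL`
#'   writes nothing.
#' @return Invisibly, a list with `trace`, `peaks`, `delay`, `features`
#'   (full table), `network_features` (monoisotopic MS2-bearing subset),
#'   `network`, `assignments`, `relations`, `truth` (synthetic only).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  layout <- config_layout(config)
  params <- config_params(config)
  truth <- NULL

  if (is.null(config$paths$msrun)) {
    spec <- synthetic_run_spec(
      run_length = config$synthetic$run_length,
      ms1_interval = config$synthetic$ms1_interval,
      top_n = config$synthetic$top_n,
      delay = config$synthetic$delay,
      seed = config$synthetic$seed, layout = layout)
    compounds <- demo_compounds(config$synthetic$compound_set)
    sim <- simulate_run(spec, compounds)
    run <- sim$run; truth <- sim$truth
    plate <- simulate_plate(spec, compounds)
    cal_spec <- synthetic_run_spec(
      run_length = 10, ms1_interval = config$synthetic$ms1_interval,
      top_n = config$synthetic$top_n, delay = config$synthetic$delay,
      seed = config$synthetic$seed + 1000L,
      layout = plate_layout(wells_per_sample = min(100L, layout$wells_per_sample),
                            fraction_seconds = layout$fraction_seconds))
    cal <- demo_compounds("calibrant")
    cal_run <- simulate_run(cal_spec, cal)$run
    cal_plate <- simulate_plate(cal_spec, cal)
    cal_layout <- cal_spec$layout
  } else {
    run <- read_msrun(config$paths$msrun)
    plate <- read_plate_csv(config$paths$plate, layout)
    cal_run <- if (!is.null(config$paths$calibrant_msrun))
      read_msrun(config$paths$calibrant_msrun) else NULL
    cal_plate <- if (!is.null(config$paths$calibrant_plate))
      read_plate_csv(config$paths$calibrant_plate, layout) else NULL
    cal_layout <- layout
  }

  # -- delay: calibrant-estimated when possible, else configured ----------
  delay <- if (!is.null(cal_run) && !is.null(cal_plate)) {
    cal_trace <- build_trace(
      normalize_plate(cal_plate, cal_layout,
                      config$plate$include_controls_in_median), cal_layout)
    estimate_delay(base_peak_chromatogram(cal_run), cal_trace,
                   max_delay = config$alignment$max_delay)
  } else if (!is.null(config$alignment$delay)) {
    structure(list(delay_min = config$alignment$delay, ms_apex_min = NA_real_,
                   bio_apex_min = NA_real_, calibrant = "configured"),
              class = "delay_model")
  } else {
    structure(list(delay_min = 0, ms_apex_min = NA_real_,
                   bio_apex_min = NA_real_, calibrant = "none"),
              class = "delay_model")
  }

  # -- bioactivity chromatogram on the MS time axis -----------------------
  norm <- normalize_plate(plate, layout, config$plate$include_controls_in_median)
  trace <- apply_delay(build_trace(norm, layout), delay)
  peaks <- detect_bioactivity_peaks(trace, config$bioactivity$threshold,
                                    config$bioactivity$min_width)

  # -- features and network ----------------------------------------------
  features <- detect_features(run, params)
  netfeats <- filter_rows_with_ms2(features[features$is_monoisotopic, , drop = FALSE])
  spectra <- netfeats$ms2
  for (k in seq_along(spectra)) spectra[[k]]$feature_id <- netfeats$id[k]
  nodes <- data.frame(id = netfeats$id, mz = netfeats$mz, rt = netfeats$rt,
                      height = netfeats$height, area = netfeats$area)
  net <- build_network(spectra, nodes = nodes,
                       cosine_threshold = config$networking$cosine_threshold,
                       min_matched = config$networking$min_matched,
                       precursor_tol = config$networking$precursor_tol,
                       fragment_tol = config$networking$fragment_tol,
                       topK = config$networking$topK)

  # -- bioactive mapping --------------------------------------------------
  assignments <- map_bioactive_features(netfeats, peaks,
                                        rt_tolerance = config$mapping$rt_tolerance)
  relations <- annotate_insource_relations(assignments,
                                           mz_tol = config$mapping$mz_tol)
  net <- mark_network(net, assignments)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_trace_csv(trace, file.path(outdir, "trace.csv"))
    write_delay_json(delay, file.path(outdir, "delay.json"))
    write_fbmn_bundle(netfeats, outdir)
    write_graphml(net, file.path(outdir, "network.graphml"))
    write_edgelist_tsv(net, file.path(outdir, "edges.tsv"))
    write_assignment_csv(assignments, file.path(outdir, "assignments.csv"),
                         relations)
    if (!is.null(truth))
      utils::write.csv(truth, file.path(outdir, "truth.csv"), row.names = FALSE)
  }

  invisible(list(trace = trace, peaks = peaks, delay = delay,
                 features = features, network_features = netfeats,
                 network = net, assignments = assignments,
                 relations = relations, truth = truth))
}
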