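# Pipeline configuration: one nested list holding every tunable of the
# chain, JSON round-trippable, with unknown keys rejected loudly.

#' Pipeline configuration
#'
#' Defaults are the platform's published parameters: MZmine-style detection
#' thresholds (see [detection_params()]), a 16x24 plate with 350 six-second
#' fractions and controls in column 24, bioactivity peak calling at
#' normalized response 0.8 over at least 2 fractions, network edges above
#' cosine 0.7 with at least 4 matched peaks (0.02 Da precursor / 0.9 Da
#' fragment tolerances), RT mapping tolerance 0.1 min and in-source relation
#' tolerance 0.005 Da, and a 0.3-min bioassay delay for the synthetic world.
#'
#' @param ... Named overrides; each name must be a top-level section
#'   (`detection`, `plate`, `bioactivity`, `alignment`, `networking`,
#'   `mapping`, `synthetic`, `paths`) holding a named list of overrides for
#'   that section. Unknown sections or keys are rejected.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    detection = unclass(detection_params()),
    plate = list(rows = 16L, columns = 24L, control_column = 24L,
                 wells_per_sample = 350L, fraction_seconds = 6,
                 collection_start = 0, traversal = "serpentine",
                 include_controls_in_median = FALSE),
    bioactivity = list(threshold = 0.8, min_width = 2L),
    alignment = list(delay = NULL, max_delay = 5, n_points = 512L),
    networking = list(cosine_threshold = 0.7, min_matched = 4L,
                      precursor_tol = 0.02, fragment_tol = 0.9, topK = NULL),
    mapping = list(rt_tolerance = 0.1, mz_tol = 0.005),
    synthetic = list(seed = 42L, compound_set = "bacillus", delay = 0.3,
                     run_length = 41, ms1_interval = 2, top_n = 3L),
    paths = list(msrun = NULL, plate = NULL, calibrant_msrun = NULL,
                 calibrant_plate = NULL)
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(ov)) {
    stopifnot(is.list(ov[[sec]]))
    badk <- setdiff(names(ov[[sec]]), names(cfg[[sec]]))
    if (length(badk))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(badk, collapse = ", "))
    cfg[[sec]][names(ov[[sec]])] <- ov[[sec]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline config as JSON
#'
#' Unknown sections or keys in the file are rejected with a clear message;
#' the file round-trips losslessly through [pipeline_config()] defaults.
#'
#' @param path JSON file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  # drop explicit nulls so defaults apply
  x <- lapply(x, function(sec) Filter(Negate(is.null), sec))
  x <- Filter(function(sec) length(sec) > 0L, x)
  do.call(pipeline_config, x)
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

config_layout <- function(cfg) {
  p <- cfg$plate
  plate_layout(rows = p$rows, columns = p$columns,
               control_column = p$control_column,
               wells_per_sample = p$wells_per_sample,
               fraction_seconds = p$fraction_seconds,
               collection_start = p$collection_start,
               traversal = p$traversal)
}

config_params <- function(cfg) do.call(detection_params, cfg$detection)
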