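#' Full run configuration
#'
#' Collects every tunable of the pipeline in one serializable object with
#' sections mirroring the processing stages: `scene` (odor generation),
#' `osn` (receptor sampling), `glomerular` (normalization + contrast
#' enhancement), `gamma` (phase discretization), `epl` (attractor network),
#' and `evaluation`. Unknown keys are rejected with an error naming them, so
#' a typo in a config file cannot silently fall back to a default.
#'
#' @param scene,osn,glomerular,gamma,epl,evaluation Named lists overriding
#'   individual defaults of each section.
#' @param seed Global integer seed; all randomness derives from it through
#'   named substreams.
#' @param out_dir Output directory for artifacts written by the CLI.
#' @param log_level One of `"quiet"`, `"info"`, `"debug"`.
#' @return A nested list of class `bulb_config`.
#' @export
#' @examples
#' cfg <- bulb_config(scene = list(n_receptors = 36), seed = 7)
#' cfg$scene$n_receptors
bulb_config <- function(scene = list(), osn = list(), glomerular = list(),
                        gamma = list(), epl = list(), evaluation = list(),
                        seed = 42L, out_dir = ".", log_level = "info") {
  defaults <- list(
    scene = list(
      n_receptors = 72L, sparsity = 0.5, concentration = 1.0,
      bernoulli_fraction = 0.5, plume_sigma = 0.0,
      mixture_rule = "sum-saturate", mixture_K = 1.0
    ),
    osn = list(
      n_sibling = 30L, hill_n = 1, ec50_center = 1,
      ec50_spread_decades = 4, random_ec50 = FALSE
    ),
    glomerular = list(
      target_mean = 0.25, clip = "hard", drive_gain = "relative",
      inhibition_amplitude = 0.5, inhibition_halfmax = 0.2,
      inhibition_steepness = 2, excitation_gain = 1, stringency = 1
    ),
    gamma = list(
      bins_per_cycle = 8L, cycles_per_presentation = 5L,
      spike_threshold = 0.1
    ),
    epl = list(
      mtc_per_column = 1L, gc_to_mtc_ratio = 25,
      coincidence_min = 3L, coincidence_max = 6L,
      early_window = 0L, excitability_spread = 0.1, lag_tolerance = 2L
    ),
    evaluation = list(
      n_draws = 20L, criterion = 0.9, min_similarity = 0.5
    )
  )
  user <- list(scene = scene, osn = osn, glomerular = glomerular,
               gamma = gamma, epl = epl, evaluation = evaluation)
  cfg <- defaults
  for (sec in names(user)) {
    unknown <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(unknown)) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(unknown, collapse = ", "))
    }
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg$seed <- as.integer(seed)
  cfg$out_dir <- out_dir
  if (!log_level %in% c("quiet", "info", "debug")) {
    stop("unknown log_level '", log_level, "'")
  }
  cfg$log_level <- log_level
  structure(cfg, class = "bulb_config")
}

#' @export
print.bulb_config <- function(x, ...) {
  cat("<bulb_config>  seed =", x$seed, "\n")
  for (sec in c("scene", "osn", "glomerular", "gamma", "epl", "evaluation")) {
    vals <- vapply(x[[sec]], function(v) paste(format(v), collapse = "/"), "")
    cat(sprintf("  %-11s %s\n", paste0(sec, ":"),
                paste(names(vals), vals, sep = "=", collapse = " ")))
  }
  invisible(x)
}

#' Read / write a run configuration (YAML or JSON)
#'
#' Configurations round-trip losslessly; files with unknown keys are rejected
#' with an error listing them. Format is chosen by file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @param config A [bulb_config()] object.
#' @return A `bulb_config` (for `read_config`); `path` invisibly (for
#'   `write_config`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unrecognized config extension (want .yaml/.yml/.json): ", path)
  }
  known_top <- c("scene", "osn", "glomerular", "gamma", "epl", "evaluation",
                 "seed", "out_dir", "log_level")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "))
  }
  args <- raw[intersect(names(raw), known_top)]
  do.call(bulb_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "bulb_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

# materialize parameter objects from config sections
config_osn <- function(cfg) {
  do.call(osn_params, c(cfg$osn, list(seed = cfg$seed)))
}
config_ntce <- function(cfg) {
  g <- cfg$glomerular
  ntce_params(g$inhibition_amplitude, g$inhibition_halfmax,
              g$inhibition_steepness, g$excitation_gain, g$stringency)
}
config_gamma <- function(cfg) do.call(gamma_params, cfg$gamma)

# stable content hash of a config (FNV-1a over its serialized form), used in
# run manifests
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
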