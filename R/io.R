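#' Read a multichannel sensor matrix from CSV
#'
#' Rows are presentations, columns sensor channels, values in `[0, 1]` after
#' optional min-max rescaling. The file must have a header row; ragged rows,
#' non-numeric cells, empty files, and out-of-range values (when rescaling is
#' off) are each rejected with a distinct message naming the offending
#' location.
#'
#' @param path CSV file path.
#' @param rescale If `TRUE`, each column is min-max rescaled to `[0, 1]`;
#'   if `FALSE` (default), values outside `[0, 1]` are an error.
#' @param verbose Log row/column counts.
#' @return List with `channels` (numeric matrix) and `n_presentations`,
#'   `n_channels`.
#' @export
read_sensor_csv <- function(path, rescale = FALSE, verbose = FALSE) {
  if (!file.exists(path)) stop("sensor file not found: ", path)
  if (file.size(path) == 0L) stop("sensor file is empty: ", path)
  widths <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(widths) < 2L) stop("sensor file has a header but no data rows: ", path)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged CSV: row ", bad, " has ", widths[bad],
         " fields, expected ", widths[1L])
  }
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow(df), ncol(df),
           dimnames = list(NULL, names(df)))
  )
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at row ", bad[1L], ", column '",
         colnames(m)[bad[2L]], "'")
  }
  if (rescale) {
    rng <- apply(m, 2, range)
    span <- rng[2L, ] - rng[1L, ]
    span[span == 0] <- 1
    m <- sweep(sweep(m, 2, rng[1L, ]), 2, span, "/")
  } else if (any(m < 0 | m > 1)) {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)[1L, ]
    stop("value out of [0, 1] at row ", bad[1L], ", column '",
         colnames(m)[bad[2L]], "' (", signif(m[bad[1L], bad[2L]], 4),
         "); pass rescale = TRUE to min-max rescale")
  }
  if (verbose) {
    message("read_sensor_csv: ", nrow(m), " presentations x ",
            ncol(m), " channels")
  }
  list(channels = m, n_presentations = nrow(m), n_channels = ncol(m))
}

MODEL_FORMAT_VERSION <- "1.0.0"

#' Save / load a trained EPL network
#'
#' The archive is a single JSON document: metadata (format version, network
#' geometry, granule-cell table, class labels) plus the dense weight arrays
#' and stored signatures. `load_model(save_model(...))` reproduces identical
#' classification behavior. Loading refuses archives with a missing or
#' higher-major format version or with missing required fields.
#'
#' @param state An [epl_network()] object (or a [bulb_fit()], whose network
#'   is saved together with its config).
#' @param path Destination file.
#' @return `path` invisibly (for `save_model`); the restored object (for
#'   `load_model`).
#' @export
save_model <- function(state, path) {
  fit <- NULL
  if (inherits(state, "bulb_fit")) {
    fit <- state
    state <- fit$network
  }
  stopifnot(inherits(state, "epl_network"))
  sig <- lapply(state$class_signatures, function(p) {
    x <- as.integer(p); x[is.na(x)] <- -1L; x  # -1 encodes SILENT
  })
  doc <- list(
    format_version = MODEL_FORMAT_VERSION,
    package = "bulbsim",
    geometry = list(
      n_columns = state$n_columns, mtc_per_column = state$mtc_per_column,
      n_mtc = state$n_mtc, gc_to_mtc_ratio = state$gc_to_mtc_ratio,
      coincidence_range = state$coincidence_range,
      early_window = state$early_window,
      lag_tolerance = state$lag_tolerance,
      excitability_offsets = state$excitability_offsets,
      seed = state$seed, replenish_count = state$replenish_count
    ),
    gamma = unclass(state$gamma),
    gc = list(  # NA-free encoding: "" = unassigned class, -1 = unset w_pot
      column = state$gc$column, k = state$gc$k, window = state$gc$window,
      state = state$gc$state,
      class = ifelse(is.na(state$gc$class), "", state$gc$class),
      w_pot = ifelse(is.na(state$gc$w_pot), -1, state$gc$w_pot)
    ),
    w_exc = state$w_exc,
    w_inh = state$w_inh,
    class_signatures = sig
  )
  if (!is.null(fit)) {
    doc$config <- unclass(fit$config)
    if (!is.null(fit$signatures)) {
      doc$signatures <- lapply(fit$signatures, function(s) {
        if (inherits(s, "odor_signature")) s$affinity else as.numeric(s)
      })
      names(doc$signatures) <- fit$labels
    }
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("corrupt model archive: ",
                                           conditionMessage(e)))
  if (is.null(doc$format_version)) {
    stop("model archive has no format version field; refusing to load")
  }
  major <- as.integer(strsplit(doc$format_version, ".", fixed = TRUE)[[1L]][1L])
  have <- as.integer(strsplit(MODEL_FORMAT_VERSION, ".", fixed = TRUE)[[1L]][1L])
  if (is.na(major) || major > have) {
    stop("model archive format version ", doc$format_version,
         " is newer than supported ", MODEL_FORMAT_VERSION)
  }
  required <- c("geometry", "gamma", "gc", "w_exc", "w_inh",
                "class_signatures")
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    stop("model archive is missing field(s): ", paste(missing, collapse = ", "))
  }
  geo <- doc$geometry
  gamma <- gamma_params(doc$gamma$bins_per_cycle,
                        doc$gamma$cycles_per_presentation,
                        doc$gamma$spike_threshold)
  gc <- data.frame(
    column = as.integer(doc$gc$column), k = as.integer(doc$gc$k),
    window = as.integer(doc$gc$window), state = as.character(doc$gc$state),
    class = ifelse(doc$gc$class == "", NA_character_,
                   as.character(doc$gc$class)),
    w_pot = ifelse(doc$gc$w_pot < 0, NA_real_, as.numeric(doc$gc$w_pot)),
    stringsAsFactors = FALSE
  )
  sigs <- lapply(doc$class_signatures, function(x) {
    x <- as.integer(x); x[x < 0] <- NA_integer_; x
  })
  state <- structure(
    list(
      n_columns = as.integer(geo$n_columns),
      mtc_per_column = as.integer(geo$mtc_per_column),
      n_mtc = as.integer(geo$n_mtc),
      col_of_mtc = rep(seq_len(geo$n_columns), each = geo$mtc_per_column),
      excitability_offsets = geo$excitability_offsets,
      gc_to_mtc_ratio = geo$gc_to_mtc_ratio,
      coincidence_range = as.integer(geo$coincidence_range),
      early_window = as.integer(geo$early_window),
      lag_tolerance = as.integer(geo$lag_tolerance),
      gamma = gamma,
      seed = as.integer(geo$seed),
      replenish_count = as.integer(geo$replenish_count),
      gc = gc,
      w_exc = matrix(as.numeric(doc$w_exc), nrow(gc), geo$n_mtc),
      w_inh = matrix(as.numeric(doc$w_inh), nrow(gc), geo$n_mtc),
      class_signatures = sigs,
      version = doc$format_version
    ),
    class = "epl_network"
  )
  if (!is.null(doc$config) && length(doc$config)) {
    cfg_args <- doc$config[c("scene", "osn", "glomerular", "gamma", "epl",
                             "evaluation", "seed", "out_dir", "log_level")]
    cfg <- do.call(bulb_config, cfg_args[!vapply(cfg_args, is.null, NA)])
    sig_aff <- if (!is.null(doc$signatures)) {
      lapply(doc$signatures, as.numeric)
    } else NULL
    return(structure(list(network = state, config = cfg,
                          signatures = sig_aff,
                          labels = names(sigs), patterns = unname(sigs)),
                     class = "bulb_fit"))
  }
  state
}
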