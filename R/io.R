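# Plain-text readers and writers for records, fiducials, features and
# models. The WFDB-style writer emits a human-readable header (record name,
# lead count, sampling frequency, sample count, lead names) next to a
# whitespace-separated signal file; the CSV writer emits samples x leads
# with a header row. Labels travel in a sidecar CSV of (record_id, labels).

#' Write an ECG record as CSV (samples x leads)
#'
#' @param record An `ecg_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  df <- as.data.frame(t(record$signal))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an ECG record from CSV
#'
#' @param path CSV of samples x leads with lead names in the header.
#' @param fs Sampling frequency in Hz (CSV carries no header metadata).
#' @param labels Character vector of labels for the record.
#' @param record_id Identifier; defaults to the file name.
#' @return An `ecg_record` (without ground-truth beat times).
#' @export
read_ecg_csv <- function(path, fs, labels = character(),
                         record_id = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  sig <- t(as.matrix(df))
  structure(
    list(signal = sig, fs = fs, labels = labels, beat_times = integer(),
         record_id = record_id),
    class = "ecg_record"
  )
}

#' Write an ECG record in WFDB-style text format
#'
#' Produces `<name>.hea` (text header: record name, number of leads,
#' sampling frequency, number of samples, then one lead name per line) and
#' `<name>.txt` (whitespace-separated samples x leads).
#'
#' @param record An `ecg_record`.
#' @param dir Output directory (created if missing).
#' @param name Base file name; defaults to the record id.
#' @return The header path, invisibly.
#' @export
write_ecg_wfdb <- function(record, dir, name = record$record_id) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hea <- file.path(dir, paste0(name, ".hea"))
  dat <- file.path(dir, paste0(name, ".txt"))
  writeLines(c(
    sprintf("%s %d %g %d", name, nrow(record$signal), record$fs,
            ncol(record$signal)),
    rownames(record$signal) %||% paste0("lead", seq_len(nrow(record$signal)))
  ), hea)
  utils::write.table(t(record$signal), dat, row.names = FALSE,
                     col.names = FALSE)
  invisible(hea)
}

#' Read a WFDB-style text record
#'
#' @param hea_path Path to the `.hea` header written by [write_ecg_wfdb()].
#' @param labels Labels for the record.
#' @return An `ecg_record`.
#' @export
read_ecg_wfdb <- function(hea_path, labels = character()) {
  lines <- readLines(hea_path)
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  n_leads <- as.integer(hdr[2])
  fs <- as.numeric(hdr[3])
  leads <- lines[2:(1 + n_leads)]
  dat <- file.path(dirname(hea_path), paste0(hdr[1], ".txt"))
  sig <- t(as.matrix(utils::read.table(dat)))
  rownames(sig) <- leads
  structure(
    list(signal = sig, fs = fs, labels = labels, beat_times = integer(),
         record_id = hdr[1]),
    class = "ecg_record"
  )
}

#' Write a dataset with its label sidecar
#'
#' @param records List of `ecg_record`s.
#' @param dir Output directory.
#' @param format `"wfdb"` (default) or `"csv"`.
#' @return The sidecar path, invisibly.
#' @export
write_dataset <- function(records, dir, format = c("wfdb", "csv")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (r in records) {
    if (format == "wfdb") write_ecg_wfdb(r, dir)
    else write_ecg_csv(r, file.path(dir, paste0(r$record_id, ".csv")))
  }
  sidecar <- file.path(dir, "labels.csv")
  utils::write.csv(
    data.frame(
      record_id = vapply(records, `[[`, "", "record_id"),
      labels = vapply(records, function(r) paste(r$labels, collapse = ","), "")
    ),
    sidecar, row.names = FALSE
  )
  invisible(sidecar)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the records and `labels.csv`.
#' @param fs Sampling frequency for `"csv"` format records.
#' @return List of `ecg_record`s.
#' @export
read_dataset <- function(dir, fs = 500) {
  sidecar <- utils::read.csv(file.path(dir, "labels.csv"),
                             colClasses = "character")
  purrr::map(seq_len(nrow(sidecar)), function(i) {
    id <- sidecar$record_id[i]
    labels <- strsplit(sidecar$labels[i], ",")[[1]]
    hea <- file.path(dir, paste0(id, ".hea"))
    if (file.exists(hea)) read_ecg_wfdb(hea, labels = labels)
    else read_ecg_csv(file.path(dir, paste0(id, ".csv")), fs = fs,
                      labels = labels, record_id = id)
  })
}

#' Write a fiducial table as CSV
#'
#' @param fiducials A `fiducial_points` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fiducials_csv <- function(fiducials, path) {
  utils::write.csv(as.data.frame(fiducials), path, row.names = FALSE)
  invisible(path)
}

#' Write the feature catalog manifest as JSON
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_json <- function(path) {
  jsonlite::write_json(feature_catalog(), path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write an attribute-selection report
#'
#' JSON with the ranking, row norms, hyperparameters and objective trace,
#' plus a companion CSV of (rank, feature, category, row norm).
#'
#' @param fit An `mlfs_fit`.
#' @param json_path,csv_path Output paths (`NULL` to skip either).
#' @return `json_path`, invisibly.
#' @export
write_selection_report <- function(fit, json_path, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(ranking = tidy(fit), hyperparams = fit$hyperparams,
           trace = fit$trace, converged = fit$converged,
           iterations = fit$iterations),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
      pretty = TRUE
    )
  }
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(tidy(fit)), csv_path, row.names = FALSE)
  }
  invisible(json_path)
}

# Recursively convert parameters (arrays/matrices/vectors) to JSON-safe
# lists carrying dims, and back.
.pack <- function(x) {
  if (is.list(x)) return(lapply(x, .pack))
  list(dim = dim(x) %||% length(x), data = as.vector(x))
}
.unpack <- function(x) {
  if (!is.list(x)) return(x)
  if (!is.null(names(x)) && identical(sort(names(x)), c("data", "dim"))) {
    d <- unlist(x$dim)
    v <- as.numeric(unlist(x$data))
    if (length(d) > 1) array(v, dim = d) else v
  } else {
    lapply(x, .unpack)
  }
}

#' Save a CNN-GRU model checkpoint as JSON
#'
#' Weights and configuration are serialised to a single JSON document; the
#' companion [load_model()] restores them exactly (up to double-precision
#' text round-trip).
#'
#' @param model A `cnn_gru_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  payload <- list(
    params = .pack(model$params),
    config = model$config[setdiff(names(model$config), "shapes")],
    loss_trace = model$loss_trace,
    epochs_run = model$epochs_run
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a CNN-GRU model checkpoint
#'
#' @param path JSON checkpoint from [save_model()].
#' @return A `cnn_gru_model` (without training history beyond the trace).
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path) # no simplification; .unpack rebuilds
  cfg <- payload$config
  config <- network_config(
    n_labels = cfg$n_labels, input_channels = cfg$input_channels,
    conv_blocks = purrr::map(cfg$conv_blocks, function(b) lapply(b, unlist)),
    pool_size = cfg$pool_size, pool_stride = cfg$pool_stride,
    padding = cfg$padding, gru_hidden = cfg$gru_hidden,
    dense_sizes = unlist(cfg$dense_sizes)
  )
  structure(
    list(params = .unpack(payload$params), config = config,
         loss_trace = unlist(payload$loss_trace),
         val_trace = numeric(0),
         epochs_run = payload$epochs_run),
    class = "cnn_gru_model"
  )
}

#' Write a metric report as JSON and one-row CSV
#'
#' @param report A `metric_report` from [evaluate_multilabel()].
#' @param json_path,csv_path Output paths (`NULL` to skip either).
#' @return `json_path`, invisibly.
#' @export
write_metric_report <- function(report, json_path, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(metrics = as.list(tibble::as_tibble(report)),
           accuracy_mode = attr(report, "accuracy_mode"),
           confusion = attr(report, "confusion")),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
      pretty = TRUE
    )
  }
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(tibble::as_tibble(report)), csv_path,
                     row.names = FALSE)
  }
  invisible(json_path)
}
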