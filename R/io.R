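# File formats: two-column text records, delimited ground-truth and result
# tables, JSON model checkpoints. Sample indices are written 0-based (and
# read back to the package's 1-based in-memory convention); time in seconds.

#' Write / read an ICP record as two-column text
#'
#' Format: CSV with header `time_s,icp`, one row per sample.
#'
#' @param record An [icp_record()].
#' @param path File path.
#' @return `read_icp_record` returns an `icp_record`; the writer returns
#'   `path` invisibly.
#' @export
write_icp_record <- function(record, path) {
  stopifnot(inherits(record, "icp_record"))
  df <- data.frame(time_s = (seq_along(record$samples) - 1) / record$fs,
                   icp = record$samples)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_icp_record
#' @param fs Sampling rate override; by default inferred from the time
#'   column.
#' @export
read_icp_record <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "icp") %in% names(df)))
    icpr_stop("icpr_io", "record file must have columns time_s, icp")
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$time_s))
  icp_record(df$icp, round(fs))
}

#' Write / read a ground-truth table
#'
#' Columns: `pulse_id`, `onset_sample`, `p1_norm_idx`, `p2_norm_idx`,
#' `true_ratio`, `calculable`. Sample and normalized-frame indices are
#' 0-based in the file (normalized indices in \[0, 179\], with 0 doubling as
#' the non-calculable sentinel, whose rows always carry `calculable=false`).
#'
#' @param truth Ground-truth data frame from [generate_record()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  df <- data.frame(pulse_id = truth$pulse_id - 1L,
                   onset_sample = truth$onset_sample - 1L,
                   p1_norm_idx = pmax(truth$p1_norm_idx - 1L, 0L),
                   p2_norm_idx = pmax(truth$p2_norm_idx - 1L, 0L),
                   true_ratio = truth$true_ratio,
                   calculable = tolower(truth$calculable))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path)
  calc <- as.logical(toupper(df$calculable))
  data.frame(pulse_id = df$pulse_id + 1L,
             onset_sample = df$onset_sample + 1L,
             p1_norm_idx = ifelse(calc, df$p1_norm_idx + 1L, 0L),
             p2_norm_idx = ifelse(calc, df$p2_norm_idx + 1L, 0L),
             true_ratio = df$true_ratio,
             calculable = calc)
}

#' Write / read a normalized pulse matrix with provenance
#'
#' CSV: provenance columns (`pulse_id`, `onset_sample` 0-based,
#' `duration_samples`, `raw_min`, `raw_max`) followed by `v1..v180`.
#'
#' @param pm A `pulse_matrix` from [preprocess_record()].
#' @param path File path.
#' @export
write_pulse_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "pulse_matrix"))
  vals <- as.data.frame(pm$pulses)
  names(vals) <- paste0("v", seq_len(ncol(vals)))
  meta <- pm$meta
  meta$onset_sample <- meta$onset_sample - 1L
  utils::write.csv(cbind(meta, vals), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pulse_matrix
#' @export
read_pulse_matrix <- function(path) {
  df <- utils::read.csv(path)
  vcols <- grep("^v\\d+$", names(df))
  meta <- df[, setdiff(seq_along(df), vcols), drop = FALSE]
  meta$onset_sample <- meta$onset_sample + 1L
  structure(list(pulses = as.matrix(df[, vcols, drop = FALSE]),
                 meta = meta, n_dropped = 0L),
            class = "pulse_matrix")
}

#' Write / read framework output tables
#'
#' The per-pulse table gains a `smoothed` column so the display series
#' round-trips alongside the raw ratios.
#'
#' @param output A `framework_output` from [run_framework()].
#' @param path File path.
#' @export
write_framework_output <- function(output, path) {
  stopifnot(inherits(output, "framework_output"))
  df <- output$per_pulse
  df$smoothed <- output$smoothed
  df$selected <- tolower(df$selected)
  df$i1 <- pmax(df$i1 - 1L, 0L)  # 0-based in files
  df$i2 <- pmax(df$i2 - 1L, 0L)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_framework_output
#' @export
read_framework_output <- function(path) {
  df <- utils::read.csv(path)
  sel <- as.logical(toupper(df$selected))
  per_pulse <- data.frame(pulse_id = df$pulse_id,
                          onset_time_s = df$onset_time_s,
                          selected = sel,
                          i1 = ifelse(df$i1 > 0, df$i1 + 1L, 0L),
                          i2 = ifelse(df$i2 > 0, df$i2 + 1L, 0L),
                          ratio = as.numeric(df$ratio))
  structure(list(per_pulse = per_pulse, smoothed = as.numeric(df$smoothed),
                 n_dropped_beats = NA_integer_),
            class = "framework_output")
}

#' Save / load a model checkpoint
#'
#' JSON serialization of the model's architecture configuration, parameters,
#' batch-normalization running statistics and training history; full
#' precision, plain text.
#'
#' @param model An `icpr_model`.
#' @param path File path (.json).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "icpr_model"))
  obj <- list(task = model$task, kind = model$kind,
              cfg = unclass(model$cfg),
              params = lapply(model$params, function(p)
                list(dim = dim(p) %||% length(p), data = as.numeric(p))),
              bn = model$bn,
              history = model$history,
              train_config = if (!is.null(model$train_config))
                unclass(model$train_config) else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    d <- unlist(p$dim)
    x <- as.numeric(unlist(p$data))
    if (length(d) > 1L) dim(x) <- d
    x
  })
  cfg <- obj$cfg
  cfg_class <- if (obj$task == "selection") "selector_config" else "designator_config"
  if (!is.null(cfg$channels)) cfg$channels <- as.integer(unlist(cfg$channels))
  class(cfg) <- cfg_class
  bn <- lapply(obj$bn, function(s) list(mean = as.numeric(unlist(s$mean)),
                                        var = as.numeric(unlist(s$var))))
  structure(list(task = obj$task, kind = obj$kind, cfg = cfg, params = params,
                 bn = bn, history = obj$history),
            class = "icpr_model")
}
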