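abort_invalid <- function(msg) {
  stop(structure(class = c("validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read a time-series CSV (header mandatory, monotone time column)
#'
#' @param path CSV path; first column must be `time_s`, remaining columns
#'   are channels.
#' @return Data frame as stored, validated.
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort_invalid(sprintf("%s: empty or missing time-series file", path))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "time_s") {
    abort_invalid(sprintf("%s: header must start with a time_s column", path))
  }
  dt <- diff(df$time_s)
  if (length(dt) && any(dt <= 0)) {
    line <- which(dt <= 0)[1] + 2L  # +1 header, +1 second row of the pair
    abort_invalid(sprintf("%s: non-monotone time column at line %d", path, line))
  }
  df
}

#' Write a time-series CSV at full float precision
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces the doubles exactly.
#'
#' @param df data frame whose first column is `time_s`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(df, path) {
  if (names(df)[1] != "time_s") {
    abort_invalid("first column must be time_s")
  }
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(lapply(df, function(col) {
               if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
             }), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Write an image/RF frame stack with a JSON schema sidecar
#'
#' Stacks are stored as flat little-endian IEEE floats in R column-major
#' order (`rows` fastest) with a `<path>.json` sidecar recording the
#' dataset kind, dtype, dimensions and physical attributes, enabling
#' seek-based chunked reads.
#'
#' @param stack `rows x cols x frames` array.
#' @param path output binary path (sidecar written to `<path>.json`).
#' @param kind dataset kind: `"bmode"`, `"rf"` or `"spec"`.
#' @param dtype `"float32"` or `"float64"`.
#' @param attrs named list of extra attributes; `bmode` stacks require a
#'   `pixel_pitch_mm` entry.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, kind = c("bmode", "rf", "spec"),
                              dtype = c("float32", "float64"), attrs = list()) {
  kind <- match.arg(kind)
  dtype <- match.arg(dtype)
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  if (kind == "bmode" && is.null(attrs$pixel_pitch_mm)) {
    abort_invalid("bmode stacks require a pixel_pitch_mm attribute")
  }
  size <- if (dtype == "float32") 4L else 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(stack), con, size = size, endian = "little")
  meta <- c(list(dataset = kind, dtype = dtype, dim = dim(stack),
                 order = "column_major"), attrs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path binary path (expects a `<path>.json` sidecar).
#' @param expect_kind optional kind to validate against (`"bmode"`, `"rf"`,
#'   `"spec"`); a mismatch is a schema error.
#' @param frames optional integer vector of frame indices to read
#'   (seek-based partial read).
#' @return `rows x cols x frames` array with the sidecar attributes
#'   attached as the `"meta"` attribute.
#' @export
read_frame_stack <- function(path, expect_kind = NULL, frames = NULL) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) abort_invalid(sprintf("%s: missing stack file", path))
  if (!file.exists(sidecar)) {
    abort_invalid(sprintf("%s: missing JSON sidecar", sidecar))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("dataset", "dtype", "dim")) {
    if (is.null(meta[[field]])) {
      abort_invalid(sprintf("%s: sidecar missing required attribute '%s'",
                            sidecar, field))
    }
  }
  if (meta$dataset == "bmode" && is.null(meta$pixel_pitch_mm)) {
    abort_invalid(sprintf("%s: bmode sidecar missing attribute 'pixel_pitch_mm'",
                          sidecar))
  }
  if (!is.null(expect_kind) && !identical(meta$dataset, expect_kind)) {
    abort_invalid(sprintf("%s: dataset kind is '%s', expected '%s'",
                          path, meta$dataset, expect_kind))
  }
  dims <- as.integer(meta$dim)
  size <- if (meta$dtype == "float32") 4L else 8L
  con <- file(path, "rb")
  on.exit(close(con))
  if (is.null(frames)) {
    vals <- readBin(con, numeric(), n = prod(dims), size = size,
                    endian = "little")
    out <- array(vals, dim = dims)
  } else {
    per <- dims[1] * dims[2]
    out <- array(0, dim = c(dims[1], dims[2], length(frames)))
    for (i in seq_along(frames)) {
      seek(con, (frames[i] - 1) * per * size)
      out[, , i] <- readBin(con, numeric(), n = per, size = size,
                            endian = "little")
    }
  }
  attr(out, "meta") <- meta
  out
}

#' Save a trained model checkpoint (JSON structure + binary tensors)
#'
#' @param model a `moment_cnn` from [train_moment_net()].
#' @param path output binary path; structure goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "moment_cnn"))
  p <- model$params
  tensors <- c(
    unlist(lapply(1:7, function(s) list(p$conv_w[[s]], p$conv_b[[s]],
                                        p$bn_gamma[[s]], p$bn_beta[[s]],
                                        p$bn_rmean[[s]], p$bn_rvar[[s]])),
           recursive = FALSE),
    list(p$fc_w, p$fc_b, model$mean_image))
  flat <- unlist(lapply(tensors, as.numeric))
  lens <- vapply(tensors, length, integer(1))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(flat, con, size = 8L, endian = "little")
  meta <- list(
    format = "moment_cnn_checkpoint_v1",
    input_hw = model$spec$input_hw, kernel_size = model$spec$kernel_size,
    pool_size = model$spec$pool_size, filters = model$spec$filters,
    dropout = model$spec$dropout, seed = model$seed,
    tensor_lengths = lens,
    conv_w_dims = lapply(p$conv_w, dim),
    record = model$record
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a trained model checkpoint
#' @param path checkpoint path from [write_checkpoint()].
#' @return A `moment_cnn` model (training record restored as a tibble).
#' @export
read_checkpoint <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "moment_cnn_checkpoint_v1")) {
    abort_invalid(sprintf("%s: not a moment_cnn checkpoint", path))
  }
  lens <- as.integer(meta$tensor_lengths)
  con <- file(path, "rb"); on.exit(close(con))
  flat <- readBin(con, numeric(), n = sum(lens), size = 8L, endian = "little")
  splits <- split(flat, rep(seq_along(lens), lens))
  spec <- build_cnn(as.integer(meta$input_hw), meta$kernel_size,
                    meta$pool_size, as.integer(meta$filters), meta$dropout)
  p <- list(conv_w = vector("list", 7), conv_b = vector("list", 7),
            bn_gamma = vector("list", 7), bn_beta = vector("list", 7),
            bn_rmean = vector("list", 7), bn_rvar = vector("list", 7))
  cw_dims <- meta$conv_w_dims
  at <- 0L
  for (s in 1:7) {
    d <- if (is.matrix(cw_dims)) as.integer(cw_dims[s, ])
         else as.integer(cw_dims[[s]])
    p$conv_w[[s]] <- matrix(splits[[at + 1L]], d[1], d[2])
    p$conv_b[[s]] <- splits[[at + 2L]]
    p$bn_gamma[[s]] <- splits[[at + 3L]]
    p$bn_beta[[s]] <- splits[[at + 4L]]
    p$bn_rmean[[s]] <- splits[[at + 5L]]
    p$bn_rvar[[s]] <- splits[[at + 6L]]
    at <- at + 6L
  }
  p$fc_w <- splits[[at + 1L]]
  p$fc_b <- splits[[at + 2L]][1]
  mean_image <- matrix(splits[[at + 3L]], meta$input_hw[1], meta$input_hw[2])
  structure(list(spec = spec, params = p, mean_image = mean_image,
                 config = NULL, seed = meta$seed,
                 record = tibble::as_tibble(meta$record)),
            class = "moment_cnn")
}

#' Read/write a pipeline configuration (YAML)
#'
#' The configuration holds the synthetic-generator settings, ROI, training
#' schedule, root seed and output directory; unspecified fields take the
#' package defaults.
#'
#' @param path YAML path.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("%s: missing config", path))
  yaml::read_yaml(path)
}

#' @rdname read_pipeline_config
#' @param config configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
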