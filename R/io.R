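#' Read a frame stack from disk
#'
#' Multi-page TIFF stacks are read losslessly (integer sample values are
#' preserved). MP4/H.264 video is decoded to grayscale luma frames when a
#' system `ffmpeg` is available.
#'
#' @param path `.tif`/`.tiff` or `.mp4` file.
#' @return 3-D array `c(rows, cols, n_frames)`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- try(tiff::readTIFF(path, all = TRUE, as.is = TRUE), silent = TRUE)
    if (inherits(pages, "try-error"))
      stop("not a readable TIFF file: ", path)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3) p <- p[, , 1]
      storage.mode(p) <- "double"
      p
    })
    return(as_stack(pages))
  }
  if (ext == "mp4") {
    if (!has_h264_codec())
      stop("reading MP4 requires ffmpeg, which is not available; ",
           "convert the video to a TIFF stack instead")
    tmp <- tempfile("dec"); dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE))
    st <- system2("ffmpeg", c("-y", "-loglevel", "error", "-i", shQuote(path),
                              "-pix_fmt", "gray",
                              file.path(tmp, "f_%06d.pgm")))
    if (st != 0) stop("ffmpeg failed to decode ", path)
    files <- sort(list.files(tmp, full.names = TRUE))
    return(as_stack(lapply(files, read_pgm)))
  }
  stop("unsupported container '", ext, "'; expected TIFF or MP4")
}

read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readLines(con, 1)
  if (magic != "P5") stop("unsupported PGM variant")
  hdr <- c()
  while (length(hdr) < 3) {
    ln <- readLines(con, 1)
    if (grepl("^#", ln)) next
    hdr <- c(hdr, scan(text = ln, quiet = TRUE))
  }
  w <- hdr[1]; h <- hdr[2]
  v <- as.integer(readBin(con, "raw", w * h))
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a frame stack to disk
#'
#' TIFF output is lossless (16-bit integer samples); reading it back with
#' [read_stack()] is bit-identical for values in `[0, 65535]`.
#'
#' @param stack frame sequence (matrix, list, or 3-D array).
#' @param path output `.tif`/`.tiff` path.
#' @return The path, invisibly.
#' @export
write_stack <- function(stack, path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff"))
    stop("unsupported container '", ext, "'; stacks are written as TIFF")
  stack <- as_stack(stack)
  if (min(stack) < 0 || max(stack) > 65535)
    stop("stack values must lie in [0, 65535] for 16-bit TIFF output")
  pages <- lapply(stack_to_list(stack), function(m) round(m) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

ts_col_map <- c(id = "id", frame = "frame", x = "x [nm]", y = "y [nm]",
                sigma = "sigma [nm]", photons = "intensity [photon]",
                background = "offset [ADU]")

#' Read a localization table (ThunderSTORM CSV dialect)
#'
#' Accepts the header `id,frame,"x [nm]","y [nm]",...` with optional
#' `sigma [nm]`, `intensity [photon]` and `offset [ADU]` columns; the
#' mandatory columns are `frame`, `x [nm]` and `y [nm]`.
#'
#' @param path CSV file path.
#' @return Emitter table with `frame` (integer), `x`, `y` in nm and any
#'   optional columns present.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  for (need in c("frame", "x [nm]", "y [nm]"))
    if (!need %in% names(raw))
      stop("missing mandatory column '", need, "' in ", path)
  out <- data.frame(frame = as.integer(raw$frame),
                    x = as.numeric(raw[["x [nm]"]]),
                    y = as.numeric(raw[["y [nm]"]]))
  if ("id" %in% names(raw)) out <- cbind(id = raw$id, out)
  else out <- cbind(id = seq_len(nrow(out)), out)
  if ("intensity [photon]" %in% names(raw))
    out$photons <- as.numeric(raw[["intensity [photon]"]])
  if ("sigma [nm]" %in% names(raw))
    out$sigma <- as.numeric(raw[["sigma [nm]"]])
  if ("offset [ADU]" %in% names(raw))
    out$background <- as.numeric(raw[["offset [ADU]"]])
  class(out) <- c("emitter_table", "data.frame")
  out
}

#' Write a localization table (ThunderSTORM CSV dialect)
#'
#' Units are nm; values are written with full precision so a round trip
#' is lossless far below 1e-3 nm. Decimal points are always periods.
#'
#' @param table emitter table.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_table <- function(table, path) {
  cols <- intersect(names(ts_col_map), names(table))
  out <- table[, cols, drop = FALSE]
  names(out) <- ts_col_map[cols]
  old <- options(OutDec = ".", scipen = 100)
  on.exit(options(old))
  utils::write.csv(format(out, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' The YAML may contain `acquisition`, `detection`, `loss`, `training`,
#' `paths` and `seed` blocks; each block's fields are passed to the
#' corresponding constructor ([acquisition_config()],
#' [detection_config()], [loss_weights()], [train_config()]), so defaults
#' apply to anything omitted. The acquisition block accepts nested
#' `sensor` (a preset name or explicit fields) and `compression` blocks.
#'
#' @param path YAML file path.
#' @return Object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  acq_args <- raw$acquisition
  if (!is.null(acq_args$sensor)) {
    acq_args$sensor <- if (is.character(acq_args$sensor))
      sensor_preset(acq_args$sensor)
    else do.call(sensor_params, acq_args$sensor)
  }
  if (!is.null(acq_args$compression))
    acq_args$compression <- do.call(compression_config, acq_args$compression)
  structure(list(
    acquisition = do.call(acquisition_config, acq_args %||% list()),
    detection = do.call(detection_config, raw$detection %||% list()),
    loss = do.call(loss_weights, raw$loss %||% list()),
    training = do.call(train_config, raw$training %||% list()),
    paths = raw$paths %||% list(),
    seed = raw$seed %||% 1L), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a manifest describing an output artifact
#'
#' Records the seed, the generating configuration (with an MD5 hash of
#' its serialized form), package version and timestamp next to every
#' artifact, sufficient to regenerate it.
#'
#' @param path manifest YAML path.
#' @param config any configuration object (serialized into the manifest).
#' @param seed the seed used.
#' @param outputs named list/character of produced files.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, config, seed, outputs = list()) {
  tmp <- tempfile()
  saveRDS(config, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  yaml::write_yaml(list(
    seed = seed,
    config_md5 = hash,
    config = rapply(list(config), unclass, how = "replace")[[1]],
    outputs = outputs,
    package = as.character(utils::packageVersion("smlmgan")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), path)
  invisible(path)
}
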