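# File formats: photon streams (CSV and "FCSPHOT1" binary), correlation
# curves (CSV), multi-page grayscale TIFF stacks, ROI tables (CSV/JSON) and
# axial-offset reports (CSV/JSON).

.MAGIC <- c(charToRaw("FCSPHOT1"), as.raw(rep(0, 8))) # 16-byte header

.write_u64le <- function(con, x) {
  # R has no native uint64; split into two little-endian uint32 words.
  # Exact for values < 2^53 (nanosecond timestamps up to ~104 days).
  lo <- x %% 2^32
  hi <- x %/% 2^32
  as_i32 <- function(v) as.integer(ifelse(v >= 2^31, v - 2^32, v))
  words <- as.vector(rbind(as_i32(lo), as_i32(hi)))
  writeBin(words, con, size = 4L, endian = "little")
}

.read_u64le <- function(con, n) {
  words <- readBin(con, "integer", n = 2L * n, size = 4L, endian = "little")
  if (length(words) < 2L * n) {
    stop(sprintf("truncated binary stream: expected %d more 8-byte words", n),
         call. = FALSE)
  }
  words <- ifelse(words < 0, words + 2^32, words)
  words[seq(1, 2 * n, by = 2)] + words[seq(2, 2 * n, by = 2)] * 2^32
}

#' Write a photon stream to disk
#'
#' Two formats: `"csv"` (one timestamp in seconds per line, `#` comment
#' lines; the acquisition duration and channel are stored in header
#' comments) and `"binary"` (16-byte header — the ASCII magic `FCSPHOT1`
#' padded with 8 NUL bytes — then a little-endian uint64 photon count
#' followed by that many little-endian uint64 timestamps in nanoseconds).
#'
#' @param stream A [photon_stream()].
#' @param path Output file.
#' @param format `"csv"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_photon_stream <- function(stream, path, format = c("csv", "binary")) {
  stopifnot(inherits(stream, "photon_stream"))
  format <- match.arg(format)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("# photon stream, channel: %s", stream$channel_id),
      sprintf("# duration_s: %.12g", stream$duration),
      sprintf("%.12g", stream$timestamps)), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(.MAGIC, con)
    .write_u64le(con, length(stream$timestamps))
    if (length(stream$timestamps)) {
      .write_u64le(con, round(stream$timestamps * 1e9))
    }
  }
  invisible(path)
}

#' Read a photon stream
#'
#' @param path Input file (see [write_photon_stream()] for the formats).
#' @param format `"csv"` or `"binary"`; guessed from the file content when
#'   omitted (binary files start with the `FCSPHOT1` magic).
#' @param duration Acquisition span override, seconds. For CSV it defaults
#'   to the `# duration_s:` header comment; for binary (which carries no
#'   span) to the last timestamp.
#' @param channel_id Detector label for the returned stream.
#' @return A [photon_stream()].
#' @export
read_photon_stream <- function(path, format = NULL, duration = NULL,
                               channel_id = "ch1") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    head8 <- readBin(path, "raw", n = 8)
    format <- if (identical(head8, charToRaw("FCSPHOT1"))) "binary" else "csv"
  }
  if (format == "binary") {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", n = 16)
    if (length(magic) < 16 || !identical(magic[1:8], charToRaw("FCSPHOT1"))) {
      stop("bad magic in bytes 1-16: not an FCSPHOT1 stream", call. = FALSE)
    }
    n <- .read_u64le(con, 1)
    ts <- if (n > 0) .read_u64le(con, n) * 1e-9 else numeric(0)
  } else {
    lines <- readLines(path)
    dur_line <- grep("^#\\s*duration_s:", lines, value = TRUE)
    if (is.null(duration) && length(dur_line)) {
      duration <- as.numeric(sub("^#\\s*duration_s:\\s*", "", dur_line[1]))
    }
    data_lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    ts <- suppressWarnings(as.numeric(data_lines))
    if (anyNA(ts)) {
      bad <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))[
        which(is.na(ts))[1]]
      stop(sprintf("line %d is not a numeric timestamp", bad), call. = FALSE)
    }
  }
  if (length(ts) && is.unsorted(ts)) {
    stop("timestamps in ", path, " are not nondecreasing", call. = FALSE)
  }
  if (is.null(duration)) {
    duration <- if (length(ts)) max(ts) else 1
  }
  photon_stream(ts, duration = duration, channel_id = channel_id)
}

#' Write a correlation curve as CSV
#'
#' Header `lag_s,G,sigma`; lags stored with 15 significant digits so that
#' fits are reproducible from the file.
#'
#' @param curve A [correlation_curve()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_correlation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  d <- as.data.frame(curve)
  if (is.null(d$sigma)) d$sigma <- NA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("lag_s,G,sigma", con)
  writeLines(sprintf("%.15g,%.15g,%s", d$lag_s, d$G,
                     ifelse(is.na(d$sigma), "", sprintf("%.15g", d$sigma))),
             con)
  invisible(path)
}

#' Read a correlation curve from CSV
#'
#' @param path File with header `lag_s,G,sigma` (sigma column may be empty).
#' @return A [correlation_curve()].
#' @export
read_correlation_curve <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("lag_s", "G") %in% names(d))) {
    stop("curve CSV must have columns 'lag_s' and 'G'", call. = FALSE)
  }
  sigma <- if ("sigma" %in% names(d) && !all(is.na(d$sigma))) d$sigma else NULL
  correlation_curve(d$lag_s, d$G, sigma)
}

#' Write a stack as multi-page grayscale TIFF
#'
#' Integer pixel values in `[0, 65535]` are written as 16-bit grayscale, one
#' page per slice; the read/write roundtrip is bit exact.
#'
#' @param stack Array of dim `c(n_slices, height, width)` with values in
#'   `[0, 65535]`.
#' @param path Output `.tif` file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  .check_stack(stack)
  if (min(stack) < 0 || max(stack) > 65535) {
    stop("pixel values must lie in [0, 65535] for 16-bit TIFF", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(stack)[1]),
                  function(k) stack[k, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page grayscale TIFF stack
#'
#' @param path Input `.tif` file (8- or 16-bit grayscale).
#' @return Array of dim `c(n_slices, height, width)` of integer pixel
#'   values.
#' @export
read_stack <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop("not a readable TIFF file: ", path, call. = FALSE)
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      stop("failed to parse TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) != 2) {
    stop("multi-sample (RGB) TIFF is unsupported: split the channels into ",
         "single-channel grayscale stacks first", call. = FALSE)
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  stack <- array(0, dim = c(length(pages), h, w))
  for (k in seq_along(pages)) stack[k, , ] <- pages[[k]]
  stack
}

#' Read ROI definitions
#'
#' CSV with header `label,x,y,width,height` (0-based top-left corner), or a
#' JSON array of objects with those fields.
#'
#' @param path Input file; format chosen by the `.json` extension.
#' @return List of [roi()] objects.
#' @export
read_rois <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    d <- jsonlite::fromJSON(path)
  } else {
    d <- utils::read.csv(path)
  }
  need <- c("label", "x", "y", "width", "height")
  if (!all(need %in% names(d))) {
    stop("ROI table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(d)), function(i) {
    roi(d$x[i], d$y[i], d$width[i], d$height[i], d$label[i])
  })
}

#' Write ROI definitions as CSV
#'
#' @param rois List of [roi()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  d <- do.call(rbind, lapply(rois, function(r) {
    data.frame(label = r$label, x = r$x, y = r$y, width = r$width,
               height = r$height)
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write an axial-offset report
#'
#' CSV (per-ROI rows, then summary rows) or JSON, chosen by extension.
#'
#' @param report An [axial_offsets()] result.
#' @param path Output file (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_axial_report <- function(report, path) {
  stopifnot(inherits(report, "axial_offset_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(per_roi = report$per_roi,
           summary = as.list(report$summary),
           summary_abs = as.list(report$summary_abs),
           n_rois = report$n_rois),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    per <- report$per_roi
    summ <- data.frame(
      roi_label = c(paste0("summary_", names(report$summary)),
                    paste0("summary_abs_", names(report$summary_abs))),
      peak_slice_ch1 = NA, peak_slice_ch2 = NA,
      peak_slice_ch1_fiji = NA, peak_slice_ch2_fiji = NA,
      delta_z = c(unname(report$summary), unname(report$summary_abs)))
    utils::write.csv(rbind(per, summ), path, row.names = FALSE)
  }
  invisible(path)
}
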