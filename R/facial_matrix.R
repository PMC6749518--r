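#' Normalize an AU intensity level
#'
#' Maps level letters to the fixed reals of [intensity_map()]:
#' O = 0, A = 0.2, B = 0.4, C = 0.6, D = 0.8, E = 0.9.
#'
#' @param level Character vector of level letters.
#' @return Numeric vector of normalized intensities.
#' @export
#' @examples
#' normalize_intensity(c("O", "A", "E"))
normalize_intensity <- function(level) {
  v <- intensity_map()[level]
  if (anyNA(v)) {
    stop("unknown intensity level: ",
         paste(unique(level[is.na(v)]), collapse = ", "), call. = FALSE)
  }
  unname(v)
}

#' Create an empty facial matrix accumulator
#'
#' The facial matrix (FM) holds one 31-entry column of normalized AU
#' intensities per ingested frame, rows in catalog order. Frames are
#' appended with [fm_append()]; every 30 accumulated columns form a
#' window (one second of video at the default 30 fps) drained with
#' [fm_drain()].
#'
#' @param fps Frames per second of the source stream (default 30).
#' @return A `facial_matrix` object.
#' @export
facial_matrix <- function(fps = 30) {
  stopifnot(fps >= 1)
  structure(
    list(values = matrix(numeric(0), nrow = 31, ncol = 0,
                         dimnames = list(au_catalog(), NULL)),
         fps = fps, frames_ingested = 0L, windows_emitted = 0L),
    class = "facial_matrix")
}

#' @export
print.facial_matrix <- function(x, ...) {
  cat("Facial matrix: 31 AUs x", ncol(x$values), "pending column(s),",
      x$frames_ingested, "frame(s) ingested at", x$fps, "fps\n")
  invisible(x)
}

as_au_frame <- function(frame) {
  cat31 <- au_catalog()
  if (is.data.frame(frame)) frame <- unlist(frame[1, , drop = TRUE])
  lv <- frame[cat31]
  if (anyNA(lv) || anyNA(names(lv))) {
    missing <- setdiff(cat31, names(frame))
    stop("frame is missing AU(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lv
}

#' Append one AU frame to a facial matrix
#'
#' @param fm A [facial_matrix()].
#' @param frame Named character vector (or one-row data frame) giving the
#'   intensity level letter of every catalog AU.
#' @return The updated `facial_matrix` (functional update).
#' @export
fm_append <- function(fm, frame) {
  stopifnot(inherits(fm, "facial_matrix"))
  col <- normalize_intensity(as_au_frame(frame))
  fm$values <- cbind(fm$values, col)
  colnames(fm$values) <- NULL
  fm$frames_ingested <- fm$frames_ingested + 1L
  fm
}

#' Drain complete windows from a facial matrix
#'
#' Emits every complete, non-overlapping 31x30 window accumulated so far
#' (floor of pending columns / 30) and retains the residual columns for
#' the next call. Each window records its start frame and start time.
#'
#' @param fm A [facial_matrix()].
#' @return List with `windows` (list of `fm_window` objects) and `fm`
#'   (the drained accumulator).
#' @export
fm_drain <- function(fm) {
  stopifnot(inherits(fm, "facial_matrix"))
  n <- ncol(fm$values)
  k <- n %/% 30L
  windows <- vector("list", k)
  for (i in seq_len(k)) {
    start_frame <- fm$frames_ingested - n + (i - 1L) * 30L
    windows[[i]] <- fm_window(
      fm$values[, (i - 1L) * 30L + 1:30, drop = FALSE],
      start_frame = start_frame, fps = fm$fps)
  }
  fm$values <- fm$values[, if (k * 30L < n) (k * 30L + 1L):n else 0,
                         drop = FALSE]
  fm$windows_emitted <- fm$windows_emitted + k
  list(windows = windows, fm = fm)
}

#' Construct a 31x30 window
#'
#' @param values 31x30 numeric matrix of normalized intensities, rows in
#'   catalog order.
#' @param start_frame 0-based index of the window's first frame.
#' @param fps Frames per second.
#' @return An `fm_window` object.
#' @export
fm_window <- function(values, start_frame = 0L, fps = 30) {
  stopifnot(is.matrix(values), nrow(values) == 31, ncol(values) == 30)
  ok <- values %in% intensity_map()
  if (!all(ok)) stop("window values must come from the intensity map",
                     call. = FALSE)
  rownames(values) <- au_catalog()
  structure(list(values = values, start_frame = as.integer(start_frame),
                 start_time = start_frame / fps, fps = fps),
            class = "fm_window")
}

#' @export
print.fm_window <- function(x, ...) {
  cat(sprintf("31x30 window starting at frame %d (t = %.2f s)\n",
              x$start_frame, x$start_time))
  invisible(x)
}

#' Convert an AU stream to normalized matrix form
#'
#' Vectorized equivalent of appending every frame of a stream: returns the
#' full facial matrix of a stream data frame as a 31 x n numeric matrix.
#'
#' @param stream Data frame with `frame_index` plus the 31 catalog AU
#'   columns holding level letters.
#' @return 31 x n numeric matrix, rows named by AU.
#' @export
stream_matrix <- function(stream) {
  cat31 <- au_catalog()
  missing <- setdiff(cat31, names(stream))
  if (length(missing)) {
    stop("stream is missing AU column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- t(vapply(cat31, function(a) normalize_intensity(stream[[a]]),
                numeric(nrow(stream))))
  rownames(m) <- cat31
  m
}

#' Cut a stream into consecutive one-second windows
#'
#' @param stream AU stream data frame (see [stream_matrix()]).
#' @param fps Frames per second (window width is always 30 columns).
#' @return List of `fm_window` objects; residual frames (< 30) are dropped.
#' @export
stream_windows <- function(stream, fps = 30) {
  m <- stream_matrix(stream)
  k <- ncol(m) %/% 30L
  lapply(seq_len(k), function(i)
    fm_window(m[, (i - 1L) * 30L + 1:30, drop = FALSE],
              start_frame = (i - 1L) * 30L, fps = fps))
}

#' Flatten a window for the network input layer
#'
#' Column-major flattening (AU-contiguous per frame): the 30 frame columns
#' are concatenated, giving the fixed 930-vector consumed by the network.
#'
#' @param window An `fm_window` or a bare 31x30 matrix.
#' @return Numeric vector of length 930.
#' @export
flatten_window <- function(window) {
  v <- if (inherits(window, "fm_window")) window$values else window
  stopifnot(is.matrix(v), nrow(v) == 31, ncol(v) == 30)
  as.vector(v)
}
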