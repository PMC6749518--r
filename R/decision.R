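#' Aggregator configuration
#'
#' @param consecutive Number of consecutive identical per-second
#'   predictions required before the rule-based classifier commits to a
#'   final output (default 5).
#' @return List of class `rbc_config`.
#' @export
rbc_config <- function(consecutive = 5L) {
  stopifnot(consecutive >= 1, consecutive == as.integer(consecutive))
  structure(list(consecutive = as.integer(consecutive)),
            class = "rbc_config")
}

#' AU-signature shortcut to Extremely Severe
#'
#' For each scale, checks whether every one of its four signature AUs
#' (see [signature_rules()]) reaches intensity level D or E (normalized
#' value >= 0.8) somewhere inside the window. A scale whose full
#' signature is present is assigned Extremely Severe directly, bypassing
#' the network for that window. With `same_frame = TRUE` the four AUs
#' must co-occur at >= D within a single frame column rather than
#' anywhere in the window.
#'
#' @param window An `fm_window` or bare 31x30 matrix (rows in catalog
#'   order).
#' @param rules Signature sets, default [signature_rules()].
#' @param same_frame Require same-column co-occurrence (default FALSE).
#' @return Named logical vector over the three scales: `TRUE` where the
#'   override fires.
#' @export
signature_shortcut <- function(window, rules = signature_rules(),
                               same_frame = FALSE) {
  v <- if (inherits(window, "fm_window")) window$values else window
  stopifnot(is.matrix(v), nrow(v) == 31, ncol(v) == 30)
  rownames(v) <- au_catalog()
  vapply(dass_scales(), function(s) {
    hit <- v[rules[[s]], , drop = FALSE] >= 0.8
    if (same_frame) any(colSums(hit) == length(rules[[s]]))
    else all(rowSums(hit) > 0)
  }, logical(1))
}

#' Rule-based aggregation of per-second predictions
#'
#' Scans the ordered per-second band triples for the first run of at
#' least `cfg$consecutive` identical consecutive triples ("identical"
#' compares all three scales at once). The triple of the first qualifying
#' run is the final output; if no run qualifies the result is
#' `"Undefined"`. Elements after the first qualifying run cannot change
#' the outcome.
#'
#' @param per_second Data frame (or matrix) with columns `depression`,
#'   `anxiety`, `stress`, one row per second, in time order.
#' @param cfg An [rbc_config()].
#' @return Named character vector of the three final bands, or the single
#'   string `"Undefined"`.
#' @export
rbc_aggregate <- function(per_second, cfg = rbc_config()) {
  per_second <- as.data.frame(per_second)
  stopifnot(all(dass_scales() %in% names(per_second)))
  n <- nrow(per_second)
  if (n == 0) return("Undefined")
  key <- do.call(paste, c(per_second[dass_scales()], sep = "|"))
  r <- rle(key)
  hit <- which(r$lengths >= cfg$consecutive)
  if (!length(hit)) return("Undefined")
  run_starts <- cumsum(r$lengths) - r$lengths + 1L
  first <- run_starts[hit[1]]
  out <- unlist(per_second[first, dass_scales()])
  stats::setNames(as.character(out), dass_scales())
}

#' Run the full per-second decision pipeline on an AU stream
#'
#' Cuts the stream into one-second windows, produces one band triple per
#' second — the signature shortcut where it fires, the network's banded
#' activations otherwise — and aggregates the sequence with the
#' rule-based classifier. Streams shorter than one window yield
#' `"Undefined"` with a diagnostic attribute.
#'
#' @param stream AU stream data frame (`frame_index` + 31 level columns).
#' @param net Trained `fdassnn`.
#' @param rules Signature sets, or `NULL` to disable the shortcut.
#' @param cfg An [rbc_config()].
#' @param fps Frames per second.
#' @return List with `final` (band triple or `"Undefined"`), `trace`
#'   (data frame: `t`, the three bands, `path` = `"network"` or
#'   `"shortcut"`), and `seconds_to_decision` (`NA` if undefined).
#' @export
predict_stream <- function(stream, net, rules = signature_rules(),
                           cfg = rbc_config(), fps = 30) {
  windows <- stream_windows(stream, fps = fps)
  if (!length(windows)) {
    out <- list(final = "Undefined", trace = NULL,
                seconds_to_decision = NA_real_)
    attr(out, "diagnostic") <- "stream shorter than one 30-frame window"
    return(out)
  }
  preds <- predict(net, windows)
  trace <- preds[dass_scales()]
  trace$path <- "network"
  if (!is.null(rules)) {
    for (i in seq_along(windows)) {
      fired <- signature_shortcut(windows[[i]], rules)
      if (any(fired)) {
        trace[i, dass_scales()[fired]] <- "ExtremelySevere"
        trace$path[i] <- "shortcut"
      }
    }
  }
  trace <- cbind(t = seq_len(nrow(trace)) * 30 / fps, trace)
  final <- rbc_aggregate(trace, cfg)
  secs <- NA_real_
  if (!identical(final, "Undefined")) {
    key <- do.call(paste, c(trace[dass_scales()], sep = "|"))
    r <- rle(key)
    hit <- which(r$lengths >= cfg$consecutive)[1]
    secs <- (sum(r$lengths[seq_len(hit - 1)]) + cfg$consecutive) * 30 / fps
  }
  list(final = final, trace = trace, seconds_to_decision = secs)
}
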