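#' Read an AU intensity stream from CSV
#'
#' Expects a comma-separated, UTF-8 file with a header row: a
#' `frame_index` column (0-based, gap-free) plus the 31 catalog AU
#' columns holding level letters O/A/B/C/D/E.
#'
#' @param path CSV file path.
#' @return Validated AU stream data frame in file order.
#' @export
read_au_stream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  missing <- setdiff(c("frame_index", au_catalog()), names(df))
  if (length(missing)) {
    stop("stream file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(df), c("frame_index", au_catalog()))
  if (length(unknown)) {
    stop("stream file ", path, " has unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!identical(as.integer(df$frame_index),
                 seq_len(nrow(df)) - 1L)) {
    stop("frame_index must run 0..n-1 without gaps in ", path,
         call. = FALSE)
  }
  for (a in au_catalog()) {
    bad <- which(!df[[a]] %in% au_levels())
    if (length(bad)) {
      stop("invalid level \"", df[[a]][bad[1]], "\" for ", a,
           " at data row ", bad[1], " of ", path, call. = FALSE)
    }
  }
  df
}

#' Write an AU intensity stream to CSV
#'
#' @param stream AU stream data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_au_stream <- function(stream, path) {
  utils::write.csv(stream[c("frame_index", au_catalog())], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a questionnaire response
#'
#' Accepts either a CSV with columns `item_index` (1..42) and `score`
#' (0..3), or a JSON object `{"items": [... 42 scores ...]}`.
#'
#' @param path File path (`.json` treated as JSON, anything else as CSV).
#' @return Integer vector of 42 item scores ordered by item index.
#' @export
read_saq <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    scores <- as.integer(obj$items)
  } else {
    df <- utils::read.csv(path)
    if (!all(c("item_index", "score") %in% names(df))) {
      stop("SAQ CSV needs columns item_index and score", call. = FALSE)
    }
    if (!setequal(df$item_index, 1:42)) {
      stop("item_index must cover 1..42 exactly", call. = FALSE)
    }
    scores <- as.integer(df$score[order(df$item_index)])
  }
  validate_saq(scores, default_scale_assignment())
  scores
}

#' Save a network to a JSON artifact
#'
#' Serializes layer sizes, activations, the AU catalog, banding
#' thresholds and all weights as a versioned JSON document (text, exact
#' to full double precision).
#'
#' @param net An `fdassnn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(net, path) {
  stopifnot(inherits(net, "fdassnn"))
  obj <- list(
    format = "fdass-model", version = 1L,
    sizes = net$sizes,
    activations = c("tanh", "sigmoid", "sigmoid"),
    catalog = au_catalog(),
    banding = banding_thresholds(),
    seed = net$seed,
    W1 = net$W1, W2 = net$W2, W3 = net$W3, b3 = net$b3)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a network from a JSON artifact
#'
#' @param path Path written by [save_model()].
#' @return An `fdassnn`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fdass-model")) {
    stop(path, " is not a model artifact", call. = FALSE)
  }
  net <- structure(
    list(sizes = as.integer(obj$sizes),
         W1 = matrix(unlist(obj$W1), nrow = obj$sizes[2], byrow = FALSE),
         W2 = matrix(unlist(obj$W2), nrow = obj$sizes[3], byrow = FALSE),
         W3 = matrix(unlist(obj$W3), nrow = obj$sizes[4], byrow = FALSE),
         b3 = as.numeric(obj$b3),
         seed = obj$seed),
    class = "fdassnn")
  net
}
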