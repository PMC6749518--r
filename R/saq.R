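#' Default item-to-scale assignment for the 42-item questionnaire
#'
#' The DASS-42 instrument does not publish its item map here; the scorer
#' therefore takes the assignment as explicit configuration. This default
#' — items 1--14 depression, 15--28 anxiety, 29--42 stress — is a synthetic
#' assignment used by the data generator; real questionnaires must supply
#' the instrument's own map.
#'
#' @return Named list of three integer vectors of 14 item indices each.
#' @export
default_scale_assignment <- function() {
  list(depression = 1:14, anxiety = 15:28, stress = 29:42)
}

validate_saq <- function(item_scores, scale_assignment) {
  if (length(item_scores) != 42L) {
    stop("SAQ response must have exactly 42 item scores, got ",
         length(item_scores), call. = FALSE)
  }
  bad <- which(!(item_scores %in% 0:3) | is.na(item_scores))
  if (length(bad)) {
    stop("SAQ item ", bad[1], " has score ", item_scores[bad[1]],
         "; every score must be an integer in 0..3", call. = FALSE)
  }
  if (!setequal(names(scale_assignment), dass_scales())) {
    stop("scale_assignment must name exactly the scales ",
         paste(dass_scales(), collapse = ", "), call. = FALSE)
  }
  idx <- unlist(scale_assignment, use.names = FALSE)
  if (any(lengths(scale_assignment) != 14L) ||
      anyDuplicated(idx) || !setequal(idx, 1:42)) {
    stop("scale_assignment must partition items 1..42 into three ",
         "disjoint groups of 14", call. = FALSE)
  }
  invisible(TRUE)
}

#' Score one DASS scale from a 42-item questionnaire response
#'
#' Sums the 14 item scores (each 0--3) assigned to the requested scale,
#' giving a raw score in 0--42.
#'
#' @param item_scores Integer vector of 42 scores, each in 0..3, ordered by
#'   item index.
#' @param scale One of `"depression"`, `"anxiety"`, `"stress"`.
#' @param scale_assignment Partition of item indices into the three scales;
#'   see [default_scale_assignment()].
#' @return Integer raw score in 0..42.
#' @export
#' @examples
#' saq_score(rep(1L, 42), "stress")
saq_score <- function(item_scores, scale,
                      scale_assignment = default_scale_assignment()) {
  scale <- match.arg(scale, dass_scales())
  validate_saq(item_scores, scale_assignment)
  sum(item_scores[scale_assignment[[scale]]])
}

#' Map a raw scale score to its severity band
#'
#' Applies the published raw-score intervals (see [dass_band_table()]):
#' e.g. a depression score of 28 or more is Extremely Severe, an anxiety
#' score of at most 7 is Normal.
#'
#' @param scale One of the three scale names.
#' @param raw Integer raw score in 0..42.
#' @return Band name (character), one of [severity_bands()].
#' @export
#' @examples
#' band_raw_score("depression", 28)  # "ExtremelySevere"
#' band_raw_score("stress", 19)      # "Moderate"
band_raw_score <- function(scale, raw) {
  scale <- match.arg(scale, dass_scales())
  if (length(raw) != 1L || is.na(raw) || raw < 0 || raw > 42 ||
      raw != as.integer(raw)) {
    stop("raw score must be a single integer in 0..42, got ", raw,
         call. = FALSE)
  }
  edges <- dass_band_table()[[scale]]
  severity_bands()[findInterval(raw, edges)]
}

#' Score a full questionnaire response on all three scales
#'
#' @inheritParams saq_score
#' @return Data frame with columns `scale`, `raw`, `band`.
#' @export
score_saq <- function(item_scores,
                      scale_assignment = default_scale_assignment()) {
  validate_saq(item_scores, scale_assignment)
  raw <- vapply(dass_scales(), function(s)
    sum(item_scores[scale_assignment[[s]]]), numeric(1))
  data.frame(
    scale = dass_scales(),
    raw = as.integer(raw),
    band = vapply(dass_scales(), function(s)
      band_raw_score(s, raw[[s]]), character(1)),
    row.names = NULL
  )
}

#' Rank of a severity band
#'
#' @param band Character vector of band names.
#' @return Integer ranks 1 (Normal) .. 5 (ExtremelySevere).
#' @export
band_rank <- function(band) {
  r <- match(band, severity_bands())
  if (anyNA(r)) stop("unknown severity band: ",
                     paste(band[is.na(r)], collapse = ", "), call. = FALSE)
  r
}
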