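#' Block-detection configuration
#'
#' Fractional face-height bands used to validate the detected eye and
#' mouth rows: the eyes are expected between 2/20 and 9/20 of face height
#' and the mouth between 11/20 and 15/20.
#'
#' @param eye_band Numeric length-2 fraction interval for the eye row.
#' @param mouth_band Numeric length-2 fraction interval for the mouth row.
#' @return List with components `eye_band`, `mouth_band`.
#' @export
block_config <- function(eye_band = c(2, 9) / 20,
                         mouth_band = c(11, 15) / 20) {
  for (b in list(eye_band, mouth_band)) {
    if (length(b) != 2 || b[1] < 0 || b[2] > 1 || b[1] >= b[2]) {
      stop("band must satisfy 0 <= lo < hi <= 1", call. = FALSE)
    }
  }
  list(eye_band = eye_band, mouth_band = mouth_band)
}

validate_mask <- function(mask) {
  if (!is.matrix(mask) || nrow(mask) < 20 || ncol(mask) < 1) {
    stop("face mask must be a matrix with at least 20 rows and 1 column",
         call. = FALSE)
  }
  if (!all(mask %in% c(0, 1))) {
    stop("face mask must be binary (0/1)", call. = FALSE)
  }
  if (sum(mask) == 0) stop("face mask has no face pixels", call. = FALSE)
  invisible(TRUE)
}

#' Row profile of a binary face mask
#'
#' Counts the face (white) pixels in each row of the mask; the basis of
#' the eye/mouth block search.
#'
#' @param mask Binary 0/1 matrix, rows = image rows.
#' @return Integer vector of length `nrow(mask)`.
#' @export
row_white_profile <- function(mask) {
  validate_mask(mask)
  as.integer(rowSums(mask))
}

#' Locate eye and mouth blocks in a binary face mask
#'
#' Scans the row profile: the row with the most face pixels in the upper
#' half of the mask is taken as the median row of the eye block, and the
#' strongest row in the lower half as the median of the mouth block. Each
#' row is then validated against the configured fractional face-height
#' band. Rows are 0-based and fractions are computed as `row / H`; ties
#' in the argmax break to the smallest row. An empty half yields that
#' block flagged invalid rather than an error, so streaming callers can
#' skip the frame.
#'
#' @param mask Binary 0/1 matrix.
#' @param cfg Band configuration from [block_config()].
#' @return List with `eye_row`, `mouth_row` (0-based integer or `NA`),
#'   `eye_valid`, `mouth_valid` (logical).
#' @export
detect_blocks <- function(mask, cfg = block_config()) {
  profile <- row_white_profile(mask)
  h <- length(profile)
  upper <- which((seq_len(h) - 1) / h < 0.5)
  lower <- which((seq_len(h) - 1) / h >= 0.5)

  pick <- function(rows, band) {
    if (!length(rows) || all(profile[rows] == 0)) {
      return(list(row = NA_integer_, valid = FALSE))
    }
    r <- rows[which.max(profile[rows])] - 1L  # 0-based
    frac <- r / h
    list(row = r, valid = frac >= band[1] && frac <= band[2])
  }

  eye <- pick(upper, cfg$eye_band)
  mouth <- pick(lower, cfg$mouth_band)
  list(eye_row = eye$row, mouth_row = mouth$row,
       eye_valid = eye$valid, mouth_valid = mouth$valid)
}

#' Read a binary face mask from a CSV grid
#'
#' @param path CSV file of 0/1 values, no header.
#' @return Binary matrix.
#' @export
read_mask_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "numeric"
  validate_mask(m)
  m
}
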