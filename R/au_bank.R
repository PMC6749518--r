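#' Train the 31-classifier AU intensity bank
#'
#' Layer one of the pipeline: one independent six-class classifier per
#' catalog AU, each mapping a 72-dimensional nonrigid facial feature
#' vector to an intensity level O..E. The default classifier is a
#' max-margin machine with a linear kernel and one-vs-one multiclass
#' decomposition (LIBSVM via \pkg{e1071}), features standardized to the
#' training mean and variance. The kernel is pluggable; linear is the
#' default because each AU's evidence is a low-dimensional direction in
#' a feature space shared by 30 other AUs' signals, which an isotropic
#' radial kernel cannot downweight. An AU whose training labels contain
#' a single level degenerates to a constant predictor with a warning.
#'
#' @param features Numeric matrix, one row per sample, 72 columns.
#' @param labels Data frame or matrix of level letters, one column per
#'   catalog AU, rows aligned with `features`.
#' @param seed Integer seed (training order shuffle; the fit itself is
#'   deterministic).
#' @param kernel LIBSVM kernel (default `"linear"`).
#' @param cost,gamma LIBSVM cost and kernel width (gamma used by the
#'   non-linear kernels; default 1/72).
#' @return An `au_bank` object.
#' @export
train_au_bank <- function(features, labels, seed = 1, kernel = "linear",
                          cost = 1, gamma = 1 / ncol(features)) {
  features <- as.matrix(features)
  if (ncol(features) != 72) {
    stop("feature matrix must have 72 columns, got ", ncol(features),
         call. = FALSE)
  }
  labels <- as.data.frame(labels)
  missing <- setdiff(au_catalog(), names(labels))
  if (length(missing)) {
    stop("labels missing AU(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(features) != nrow(labels)) {
    stop("features and labels must have the same number of rows",
         call. = FALSE)
  }
  set.seed(seed)
  center <- colMeans(features)
  sds <- apply(features, 2, stats::sd)
  sds[sds == 0] <- 1
  Z <- scale(features, center = center, scale = sds)

  models <- lapply(au_catalog(), function(a) {
    y <- factor(labels[[a]], levels = au_levels())
    if (anyNA(y)) stop("invalid level letter in labels for ", a,
                       call. = FALSE)
    if (length(unique(y)) < 2) {
      warning("AU ", a, " has a single training level (",
              as.character(y[1]), "); using a constant predictor",
              call. = FALSE)
      return(list(constant = as.character(y[1])))
    }
    e1071::svm(x = Z, y = droplevels(y), kernel = kernel,
               cost = cost, gamma = gamma, scale = FALSE)
  })
  names(models) <- au_catalog()
  structure(list(models = models, center = center, sds = sds,
                 seed = seed), class = "au_bank")
}

#' @export
print.au_bank <- function(x, ...) {
  n_const <- sum(vapply(x$models, function(m) !is.null(m$constant),
                        logical(1)))
  cat("AU intensity classifier bank: 31 classifiers",
      if (n_const) sprintf("(%d constant)", n_const), "\n")
  invisible(x)
}

#' Classify feature vectors into AU intensity frames
#'
#' Runs every classifier of the bank on the supplied 72-dimensional
#' feature vectors and assembles one AU frame (all 31 levels) per sample.
#'
#' @param bank An [train_au_bank()] bank.
#' @param features Numeric vector of length 72 or matrix with 72 columns.
#' @return Data frame with `frame_index` and one level column per AU.
#' @export
classify_frames <- function(bank, features) {
  stopifnot(inherits(bank, "au_bank"))
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != 72) {
    stop("feature input must have length/width 72, got ", ncol(features),
         call. = FALSE)
  }
  Z <- scale(features, center = bank$center, scale = bank$sds)
  out <- data.frame(frame_index = seq_len(nrow(features)) - 1L)
  for (a in au_catalog()) {
    m <- bank$models[[a]]
    out[[a]] <- if (!is.null(m$constant)) rep(m$constant, nrow(Z))
    else as.character(predict(m, Z))
  }
  out
}
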