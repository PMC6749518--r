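#' Training configuration for the severity network
#'
#' Defaults are the published operating point: learning rate 0.2,
#' momentum 0.4, at most 7000 epochs, stop once the training AARE drops
#' below 0.02, with an 80:20 train/validation split of the supplied data.
#'
#' @param learning_rate Gradient-descent step size (> 0).
#' @param momentum Classical momentum coefficient in \[0, 1).
#' @param max_epochs Epoch cap.
#' @param target_error Training AARE below which training stops.
#' @param validation_fraction Fraction of samples held out for the
#'   validation curve (not used for weight updates).
#' @param batch `"full"` for full-batch gradient descent (default) or
#'   `"sample"` for per-pattern updates.
#' @param seed Integer seed controlling initialization and the split.
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.2, momentum = 0.4,
                         max_epochs = 7000, target_error = 0.02,
                         validation_fraction = 0.2,
                         batch = c("full", "sample"), seed = 1) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            max_epochs >= 1, target_error > 0,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 target_error = target_error,
                 validation_fraction = validation_fraction,
                 batch = match.arg(batch), seed = as.integer(seed)),
            class = "train_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Nguyen-Widrow network initialization
#'
#' Builds a feedforward network input -> hidden1 (tanh) -> hidden2
#' (sigmoid) -> output (sigmoid) with every neuron's incoming weight
#' vector scaled to magnitude `0.7 * h^(1/n)` (h neurons in the layer, n
#' inputs to it), directions drawn uniformly under the seed. Hidden-layer
#' biases are fixed at zero (and stay zero throughout training); the
#' output bias starts at zero but is trained.
#'
#' @param sizes Integer vector of layer sizes, default the severity
#'   network `c(930, 75, 65, 3)`. The disorder variant uses
#'   `c(930, 30, 25, 3)`.
#' @param seed Integer seed.
#' @return An `fdassnn` object with weight matrices `W1`, `W2`, `W3`
#'   (rows = neurons) and output bias `b3`.
#' @export
nguyen_widrow_init <- function(sizes = c(930, 75, 65, 3), seed = 1) {
  if (length(sizes) != 4 || any(sizes < 1)) {
    stop("sizes must be four positive layer sizes", call. = FALSE)
  }
  set.seed(seed)
  nw <- function(n_in, n_out) {
    W <- matrix(stats::runif(n_out * n_in, -0.5, 0.5), n_out, n_in)
    beta <- 0.7 * n_out^(1 / n_in)
    W * beta / sqrt(rowSums(W^2))
  }
  structure(
    list(sizes = as.integer(sizes),
         W1 = nw(sizes[1], sizes[2]),
         W2 = nw(sizes[2], sizes[3]),
         W3 = nw(sizes[3], sizes[4]),
         b3 = rep(0, sizes[4]),
         seed = as.integer(seed)),
    class = "fdassnn")
}

#' @export
print.fdassnn <- function(x, ...) {
  cat(sprintf("Feedforward DASS network %s (tanh / sigmoid / sigmoid)\n",
              paste(x$sizes, collapse = "-> ")))
  if (!is.null(x$trained)) {
    cat(sprintf("  trained: %d epoch(s), final AARE %.4f (%s)\n",
                x$trained$epochs, x$trained$final_aare, x$trained$stop))
  }
  invisible(x)
}

#' Forward pass
#'
#' @param net An [nguyen_widrow_init()] network.
#' @param x Input: a numeric vector of length `sizes[1]`, a matrix with
#'   one column per sample, or an `fm_window`.
#' @param keep_hidden Return hidden activations too (used by training).
#' @return Output activation matrix (`sizes[4]` x n), values in (0, 1);
#'   with `keep_hidden = TRUE`, a list `A1`, `A2`, `Y`.
#' @export
nn_forward <- function(net, x, keep_hidden = FALSE) {
  stopifnot(inherits(net, "fdassnn"))
  if (inherits(x, "fm_window")) x <- flatten_window(x)
  if (is.list(x)) x <- vapply(x, flatten_window, numeric(net$sizes[1]))
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) != net$sizes[1]) {
    stop("input has ", nrow(x), " rows; expected ", net$sizes[1],
         call. = FALSE)
  }
  A1 <- tanh(net$W1 %*% x)              # hidden biases fixed at 0
  A2 <- sigmoid(net$W2 %*% A1)
  Y <- sigmoid(net$W3 %*% A2 + net$b3)
  if (keep_hidden) list(A1 = A1, A2 = A2, Y = Y) else Y
}

#' Average absolute relative error
#'
#' The training loss and stopping criterion:
#' `mean(|desired - estimated| / estimated)`, the relative error taken
#' against the estimated output and averaged over all output components
#' and samples. Denominators are clamped at `eps` so near-zero estimates
#' cannot blow up the mean.
#'
#' @param estimated Numeric vector/matrix of network outputs.
#' @param desired Numeric vector/matrix of targets, same shape.
#' @param eps Denominator clamp (default 0.05).
#' @return Single non-negative number.
#' @export
#' @examples
#' aare(estimated = 0.5, desired = 0.6)  # |0.6 - 0.5| / 0.5 = 0.2
aare <- function(estimated, desired, eps = 0.05) {
  if (length(estimated) != length(desired) || !length(estimated)) {
    stop("estimated and desired must be equal, positive length",
         call. = FALSE)
  }
  mean(abs(desired - estimated) / pmax(estimated, eps))
}

# gradient of aare() w.r.t. all parameters, full batch
aare_gradient <- function(net, X, T_, eps = 0.05) {
  f <- nn_forward(net, X, keep_hidden = TRUE)
  Y <- f$Y
  M <- length(T_)
  s <- sign(T_ - Y)
  # d/dY |T - Y| / max(Y, eps): quotient rule where Y > eps, else linear
  dY <- ifelse(Y > eps, -s * T_ / Y^2, -s / eps) / M
  dZ3 <- dY * Y * (1 - Y)
  dA2 <- crossprod(net$W3, dZ3)
  dZ2 <- dA2 * f$A2 * (1 - f$A2)
  dA1 <- crossprod(net$W2, dZ2)
  dZ1 <- dA1 * (1 - f$A1^2)
  list(W1 = tcrossprod(dZ1, X), W2 = tcrossprod(dZ2, f$A1),
       W3 = tcrossprod(dZ3, f$A2), b3 = rowSums(dZ3),
       loss = mean(abs(T_ - Y) / pmax(Y, eps)))
}

#' Train the network by momentum backpropagation on the AARE
#'
#' Gradient descent on [aare()] with classical momentum
#' (`v <- momentum * v - rate * grad; w <- w + v`), hidden biases held at
#' zero every step. An 80:20 split (under the config seed) tracks a
#' validation curve; weight updates use the training portion only.
#' Training stops when the training AARE falls below `target_error` or at
#' the epoch cap.
#'
#' @param net Network from [nguyen_widrow_init()].
#' @param X Input matrix, one column per sample (length-`sizes[1]` rows),
#'   or a list of `fm_window`s.
#' @param targets Target matrix (`sizes[4]` x n) with entries in (0, 1\].
#' @param cfg A [train_config()].
#' @return The trained `fdassnn`, with a `history` element: data frame of
#'   per-epoch training and validation AARE, and `trained` metadata
#'   (`epochs`, `final_aare`, `stop` = `"error-target"` or `"epoch-cap"`).
#' @export
nn_train <- function(net, X, targets, cfg = train_config()) {
  stopifnot(inherits(net, "fdassnn"), inherits(cfg, "train_config"))
  if (is.list(X) && !is.matrix(X)) {
    X <- vapply(X, flatten_window, numeric(net$sizes[1]))
  }
  if (!is.matrix(targets)) targets <- matrix(targets, nrow = net$sizes[4])
  if (ncol(X) != ncol(targets) || ncol(X) < 1) {
    stop("X and targets must align on a non-empty sample set",
         call. = FALSE)
  }
  if (any(targets <= 0) || any(targets > 1)) {
    stop("targets must lie in (0, 1]; encode bands with band_midpoints()",
         call. = FALSE)
  }
  set.seed(cfg$seed)
  n <- ncol(X)
  n_val <- floor(cfg$validation_fraction * n)
  val_idx <- if (n_val > 0) sample(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[, tr_idx, drop = FALSE]; Ttr <- targets[, tr_idx, drop = FALSE]
  Xval <- X[, val_idx, drop = FALSE]; Tval <- targets[, val_idx, drop = FALSE]

  V <- list(W1 = net$W1 * 0, W2 = net$W2 * 0, W3 = net$W3 * 0,
            b3 = net$b3 * 0)
  tr_curve <- val_curve <- numeric(cfg$max_epochs)
  stop_reason <- "epoch-cap"
  ep <- 0L
  for (ep in seq_len(cfg$max_epochs)) {
    if (cfg$batch == "full") {
      g <- aare_gradient(net, Xtr, Ttr)
      loss <- g$loss
      for (nm in names(V)) {
        V[[nm]] <- cfg$momentum * V[[nm]] - cfg$learning_rate * g[[nm]]
        net[[nm]] <- net[[nm]] + V[[nm]]
      }
    } else {
      for (i in sample(ncol(Xtr))) {
        g <- aare_gradient(net, Xtr[, i, drop = FALSE],
                           Ttr[, i, drop = FALSE])
        for (nm in names(V)) {
          V[[nm]] <- cfg$momentum * V[[nm]] - cfg$learning_rate * g[[nm]]
          net[[nm]] <- net[[nm]] + V[[nm]]
        }
      }
      loss <- aare(nn_forward(net, Xtr), Ttr)
    }
    if (!is.finite(loss)) {
      stop("training diverged (non-finite AARE at epoch ", ep,
           "); try a smaller learning rate", call. = FALSE)
    }
    tr_curve[ep] <- loss
    val_curve[ep] <- if (length(val_idx))
      aare(nn_forward(net, Xval), Tval) else NA_real_
    if (loss < cfg$target_error) { stop_reason <- "error-target"; break }
  }
  net$history <- data.frame(epoch = seq_len(ep),
                            train_aare = tr_curve[seq_len(ep)],
                            val_aare = val_curve[seq_len(ep)])
  net$trained <- list(epochs = ep, final_aare = tr_curve[ep],
                      stop = stop_reason, config = cfg)
  net
}

#' Band a network output activation
#'
#' Maps an activation in \[0, 1\] to a severity band: \[0, 0.15) Normal,
#' \[0.15, 0.3) Mild, \[0.3, 0.6) Moderate, \[0.6, 0.8\] Severe and
#' strictly above 0.8 Extremely Severe.
#'
#' @param activation Numeric vector in \[0, 1\].
#' @return Character vector of band names.
#' @export
#' @examples
#' band_activation(c(0.45, 0.8, 0.85))
band_activation <- function(activation) {
  if (any(activation < 0 | activation > 1) || anyNA(activation)) {
    stop("activation must lie in [0, 1]", call. = FALSE)
  }
  th <- banding_thresholds()
  # lower-inclusive except the top: 0.8 is Severe, "over 0.8" is extreme
  idx <- findInterval(activation, th) + 1L
  idx[activation == th[4]] <- 4L
  severity_bands()[idx]
}

#' Predict severity bands for windows
#'
#' @param object Trained `fdassnn`.
#' @param windows List of `fm_window`s, a single window, or an input
#'   matrix (one column per flattened window).
#' @param ... Unused.
#' @return Data frame with one row per window: the three activations and
#'   the three band labels (`depression`, `anxiety`, `stress`).
#' @export
predict.fdassnn <- function(object, windows, ...) {
  if (inherits(windows, "fm_window")) windows <- list(windows)
  X <- if (is.matrix(windows)) windows else
    vapply(windows, flatten_window, numeric(object$sizes[1]))
  Y <- nn_forward(object, X)
  out <- data.frame(t(Y))
  names(out) <- paste0("act_", dass_scales())
  for (s in seq_along(dass_scales())) {
    out[[dass_scales()[s]]] <- band_activation(Y[s, ])
  }
  out
}

#' Binary disorder prediction (MDD / GAD / PTSD variant)
#'
#' The disorder variant of the network (hidden sizes 30 and 25) emits
#' three outputs thresholded at 0.5: 1 means the subject is predicted to
#' suffer from the disorder. An output of exactly 0.5 resolves to 0.
#'
#' @param net Disorder-variant `fdassnn` (hidden sizes 30, 25).
#' @param window An `fm_window`, flattened vector, or input matrix.
#' @return Integer matrix (3 x n) of 0/1 flags, rows `MDD`, `GAD`, `PTSD`.
#' @export
predict_disorders <- function(net, window) {
  if (!identical(net$sizes[2:3], c(30L, 25L))) {
    stop("disorder variant requires hidden sizes 30 and 25; got ",
         paste(net$sizes[2:3], collapse = ", "), call. = FALSE)
  }
  Y <- nn_forward(net, window)
  flags <- (Y > 0.5) + 0L
  rownames(flags) <- disorder_names()
  flags
}
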