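#' One-vs-rest confusion counts for a severity level
#'
#' For a chosen band, TP counts cases where that band was correctly
#' predicted, TN cases correctly predicted as some other band, FP cases
#' wrongly given the band and FN cases wrongly denied it.
#'
#' @param predictions,truths Character vectors of band names, aligned.
#' @param level The band evaluated one-vs-rest.
#' @return Named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_for_level <- function(predictions, truths, level) {
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have the same length", call. = FALSE)
  }
  p <- predictions == level
  t <- truths == level
  c(TP = sum(p & t), TN = sum(!p & !t),
    FP = sum(p & !t), FN = sum(!p & t))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' AC = (TP+TN)/(TP+TN+FP+FN), SE (true positive rate) = TP/(TP+FN),
#' SP (true negative rate) = TN/(TN+FP). A metric whose denominator is
#' zero is reported as `NA` (not applicable), never as 0.
#'
#' @param counts Named vector from [confusion_for_level()].
#' @return Named numeric vector `AC`, `SE`, `SP`.
#' @export
#' @examples
#' metrics(c(TP = 8, TN = 85, FP = 5, FN = 2))  # AC 0.93, SE 0.8
metrics <- function(counts) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)))
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  tot <- tp + tn + fp + fn
  c(AC = if (tot > 0) (tp + tn) / tot else NA_real_,
    SE = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    SP = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Leave-one-out protocol specification
#'
#' @param methodology `"intersubject"` (folds leave one subject out) or
#'   `"intrasubject"` (folds leave one session of a single subject out).
#' @param train_split,test_split `"DSC"` (emotion-induced samples),
#'   `"DSR"` (no emotion induced) or `"both"`.
#' @param train_emotions Optional subset of [basic_emotions()]; when set,
#'   only DSC samples of these emotions are used for training.
#' @return List of class `protocol_spec`.
#' @export
protocol_spec <- function(methodology = c("intersubject", "intrasubject"),
                          train_split = c("DSC", "DSR", "both"),
                          test_split = c("DSR", "DSC", "both"),
                          train_emotions = NULL) {
  if (!is.null(train_emotions)) {
    bad <- setdiff(train_emotions, basic_emotions())
    if (length(bad)) stop("unknown emotion(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(methodology = match.arg(methodology),
                 train_split = match.arg(train_split),
                 test_split = match.arg(test_split),
                 train_emotions = train_emotions),
            class = "protocol_spec")
}

#' Simulate the recordings of a cohort
#'
#' For every subject session, generates one controlled (DSC) stream per
#' requested emotion and `n_dsr` random-condition (DSR) streams, all
#' under per-sample seeds derived from `seed`.
#'
#' @param profiles Cohort data frame from [generate_cohort()].
#' @param cfg A [generator_config()].
#' @param emotions Emotions induced for the DSC samples.
#' @param n_dsr Number of DSR streams per session.
#' @param seed Integer seed.
#' @return List of samples; each has `id`, `subject`, `session`,
#'   `dataset`, `emotion` (`NA` for DSR), `bands`, `stream`.
#' @export
simulate_recordings <- function(profiles, cfg = generator_config(),
                                emotions = basic_emotions(), n_dsr = 2,
                                seed = 1) {
  samples <- list()
  k <- 0
  for (i in seq_len(nrow(profiles))) {
    row <- profiles[i, ]
    bands <- c(depression = row$depression, anxiety = row$anxiety,
               stress = row$stress)
    for (e in emotions) {
      k <- k + 1
      samples[[k]] <- list(id = k, subject = row$subject,
                           session = row$session, dataset = "DSC",
                           emotion = e, bands = bands,
                           stream = generate_au_stream(
                             bands, e, cfg, seed = seed * 100003L + k))
    }
    for (j in seq_len(n_dsr)) {
      k <- k + 1
      samples[[k]] <- list(id = k, subject = row$subject,
                           session = row$session, dataset = "DSR",
                           emotion = NA_character_, bands = bands,
                           stream = generate_au_stream(
                             bands, NULL, cfg, seed = seed * 100003L + k))
    }
  }
  samples
}

sample_in_split <- function(sample, split, emotions = NULL) {
  if (split != "both" && sample$dataset != split) return(FALSE)
  if (!is.null(emotions) && sample$dataset == "DSC" &&
      !sample$emotion %in% emotions) return(FALSE)
  TRUE
}

windows_and_targets <- function(samples, fps) {
  X <- list(); T_ <- list()
  for (s in samples) {
    w <- stream_windows(s$stream, fps = fps)
    X <- c(X, w)
    mids <- band_midpoints()[band_rank(s$bands[dass_scales()])]
    T_ <- c(T_, rep(list(mids), length(w)))
  }
  list(X = vapply(X, flatten_window, numeric(930)),
       targets = matrix(unlist(T_), nrow = 3),
       windows = X)
}

#' Run a leave-one-out evaluation protocol
#'
#' Implements the intrasubject (leave one session out, per subject) and
#' intersubject (leave one subject out) methodologies: in each fold a
#' severity network is trained on the training split's windows (targets
#' are the session bands encoded as midpoints) and every test sample is
#' predicted with the full per-second pipeline ([predict_stream()]).
#' Undefined aggregator outputs are excluded from the confusion counts
#' and reported as an undecided rate.
#'
#' @param samples Recordings from [simulate_recordings()].
#' @param spec A [protocol_spec()].
#' @param hidden Hidden-layer sizes of the per-fold network; the full
#'   published architecture (75, 65) is costly per fold, so protocol
#'   studies may use a reduced net.
#' @param cfg A [train_config()] for the per-fold training.
#' @param rules Signature rules for the shortcut, or `NULL` to disable.
#' @param fps Frames per second of the streams.
#' @param seed Integer seed.
#' @return List with `per_level` (data frame: scale, level, counts and
#'   AC/SE/SP), `overall` (per-scale multiclass accuracy of the final
#'   decisions and of the per-window band predictions), `advs` (average
#'   seconds of stream consumed before a decision; undecided streams
#'   count at full length), `undecided_rate`, and `manifest` (fold
#'   membership of every sample id, for leak auditing).
#' @export
run_protocol <- function(samples, spec = protocol_spec(),
                         hidden = c(12, 8), cfg = train_config(
                           max_epochs = 400, seed = 1),
                         rules = NULL, fps = 30, seed = 1) {
  subjects <- vapply(samples, `[[`, numeric(1), "subject")
  sessions <- vapply(samples, `[[`, numeric(1), "session")

  folds <- if (spec$methodology == "intersubject") {
    lapply(sort(unique(subjects)), function(s)
      list(test = which(subjects == s), train = which(subjects != s)))
  } else {
    out <- list()
    for (s in sort(unique(subjects))) {
      for (ses in sort(unique(sessions[subjects == s]))) {
        out[[length(out) + 1]] <- list(
          test = which(subjects == s & sessions == ses),
          train = which(subjects == s & sessions != ses))
      }
    }
    out
  }
  if (length(folds) < 2) stop("not enough folds for the protocol",
                              call. = FALSE)

  manifest <- list()
  truth <- pred <- list()
  win_records <- list()
  decision_secs <- numeric(0)
  n_undecided <- 0; n_decided <- 0

  for (fi in seq_along(folds)) {
    tr <- folds[[fi]]$train
    te <- folds[[fi]]$test
    tr <- tr[vapply(samples[tr], sample_in_split, logical(1),
                    spec$train_split, spec$train_emotions)]
    te <- te[vapply(samples[te], sample_in_split, logical(1),
                    spec$test_split)]
    if (!length(tr) || !length(te)) next
    manifest[[fi]] <- data.frame(
      fold = fi,
      id = c(vapply(samples[tr], `[[`, numeric(1), "id"),
             vapply(samples[te], `[[`, numeric(1), "id")),
      role = rep(c("train", "test"), c(length(tr), length(te))))

    wt <- windows_and_targets(samples[tr], fps)
    net <- nguyen_widrow_init(c(930, hidden, 3), seed = cfg$seed + fi)
    net <- nn_train(net, wt$X, wt$targets, cfg)

    for (s in samples[te]) {
      res <- predict_stream(s$stream, net, rules = rules, fps = fps)
      wp <- predict(net, stream_windows(s$stream, fps = fps))
      for (sc in dass_scales()) {
        win_records[[length(win_records) + 1]] <- data.frame(
          scale = sc, truth = s$bands[[sc]], pred = wp[[sc]])
      }
      if (identical(res$final, "Undefined")) {
        n_undecided <- n_undecided + 1
        decision_secs <- c(decision_secs,
                           nrow(s$stream) / fps)
      } else {
        n_decided <- n_decided + 1
        decision_secs <- c(decision_secs, res$seconds_to_decision)
        truth[[length(truth) + 1]] <- s$bands[dass_scales()]
        pred[[length(pred) + 1]] <- res$final[dass_scales()]
      }
    }
  }

  per_level <- NULL
  overall <- NULL
  if (n_decided > 0) {
    tm <- do.call(rbind, truth); pm <- do.call(rbind, pred)
    rows <- list()
    for (sc in seq_along(dass_scales())) {
      for (lv in severity_bands()) {
        cnt <- confusion_for_level(pm[, sc], tm[, sc], lv)
        rows[[length(rows) + 1]] <- data.frame(
          scale = dass_scales()[sc], level = lv, t(cnt), t(metrics(cnt)))
      }
    }
    per_level <- do.call(rbind, rows)
    overall <- data.frame(
      scale = dass_scales(),
      final_accuracy = vapply(seq_along(dass_scales()), function(sc)
        mean(pm[, sc] == tm[, sc]), numeric(1)))
  }
  wr <- do.call(rbind, win_records)
  window_accuracy <- vapply(dass_scales(), function(sc) {
    sub <- wr[wr$scale == sc, ]
    mean(sub$pred == sub$truth)
  }, numeric(1))
  list(per_level = per_level, overall = overall,
       window_accuracy = window_accuracy,
       advs = mean(decision_secs),
       undecided_rate = n_undecided / max(1, n_undecided + n_decided),
       manifest = do.call(rbind, manifest))
}
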