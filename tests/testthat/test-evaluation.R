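test_that("confusion counts match the one-vs-rest convention", {
  truths <- c("Normal", "Normal", "Mild")
  preds <- c("Normal", "Mild", "Mild")
  cnt <- confusion_for_level(preds, truths, "Normal")
  expect_equal(cnt, c(TP = 1L, TN = 1L, FP = 0L, FN = 1L))
  # perfect predictions: no false calls
  cnt2 <- confusion_for_level(truths, truths, "Mild")
  expect_equal(cnt2[["FP"]] + cnt2[["FN"]], 0L)
  expect_error(confusion_for_level("Normal", truths, "Normal"), "length")
})

test_that("metrics follow the printed formulas with NA guards", {
  m <- metrics(c(TP = 8, TN = 85, FP = 5, FN = 2))
  expect_equal(m[["AC"]], 0.93)
  expect_equal(m[["SE"]], 0.8)
  expect_equal(m[["SP"]], 85 / 90)
  perfect <- metrics(c(TP = 5, TN = 10, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1))
  # absent positives: sensitivity is not applicable, never zero
  m2 <- metrics(c(TP = 0, TN = 10, FP = 0, FN = 0))
  expect_true(is.na(m2[["SE"]]))
  expect_equal(m2[["AC"]], 1)
})

test_that("metrics-of-confusion equals exhaustive enumeration", {
  bands3 <- severity_bands()[1:3]
  brute <- function(pred, truth, lv) {
    tp <- tn <- fp <- fn <- 0L
    for (i in seq_along(pred)) {
      if (pred[i] == lv && truth[i] == lv) tp <- tp + 1L
      else if (pred[i] != lv && truth[i] != lv) tn <- tn + 1L
      else if (pred[i] == lv) fp <- fp + 1L
      else fn <- fn + 1L
    }
    c(TP = tp, TN = tn, FP = fp, FN = fn)
  }
  for (len in 1:4) {
    combos <- expand.grid(rep(list(seq_along(bands3)), 2 * len))
    for (r in seq_len(nrow(combos))) {
      idx <- as.integer(combos[r, ])
      truth <- bands3[idx[1:len]]
      pred <- bands3[idx[(len + 1):(2 * len)]]
      for (lv in bands3) {
        expect_identical(confusion_for_level(pred, truth, lv),
                         brute(pred, truth, lv))
      }
      # partition property: counts always sum to the number of cases
      cnt <- confusion_for_level(pred, truth, bands3[1])
      expect_equal(sum(cnt), len)
    }
  }
  # lengths 5 and 6: random draws against the same oracle
  set.seed(13)
  for (rep in 1:200) {
    len <- sample(5:6, 1)
    truth <- sample(bands3, len, TRUE)
    pred <- sample(bands3, len, TRUE)
    for (lv in bands3) {
      expect_identical(confusion_for_level(pred, truth, lv),
                       brute(pred, truth, lv))
    }
  }
})

small_protocol_samples <- function(n_subjects = 4, duration = 6,
                                   noiseless = TRUE, seed = 1,
                                   emotions = c("sadness", "happiness"),
                                   n_dsr = 1, n_sessions = 1) {
  co <- generate_cohort(n_subjects, n_sessions = n_sessions,
                        disorder_fraction = c(MDD = 0, GAD = 0, PTSD = 0),
                        seed = seed)
  simulate_recordings(co, generator_config(duration = duration,
                                           noiseless = noiseless),
                      emotions = emotions, n_dsr = n_dsr, seed = seed)
}

test_that("leave-one-out folds never leak the test subject", {
  samples <- small_protocol_samples(n_subjects = 4, seed = 2)
  res <- run_protocol(samples, protocol_spec("intersubject", "both",
                                             "both"),
                      hidden = c(6, 4),
                      cfg = train_config(max_epochs = 30, seed = 2))
  man <- res$manifest
  subj_of <- vapply(samples, `[[`, numeric(1), "subject")
  for (f in unique(man$fold)) {
    tr_subj <- subj_of[man$id[man$fold == f & man$role == "train"]]
    te_subj <- subj_of[man$id[man$fold == f & man$role == "test"]]
    expect_length(intersect(tr_subj, te_subj), 0)
  }
})

test_that("noiseless streams are classified perfectly by the protocol", {
  # five band triples covering every rank on every scale, each triple
  # carried by two subjects so a left-out subject's signal pattern is
  # always represented in training
  bands <- severity_bands()
  tri <- cbind(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 1), c(3, 4, 5, 1, 2))
  profiles <- data.frame(
    subject = 1:10, session = 1,
    depression = bands[tri[rep(1:5, each = 2), 1]],
    anxiety = bands[tri[rep(1:5, each = 2), 2]],
    stress = bands[tri[rep(1:5, each = 2), 3]],
    disorder = "none", sex = "F")
  samples <- simulate_recordings(
    profiles, generator_config(duration = 5, noiseless = TRUE),
    emotions = character(0), n_dsr = 1, seed = 4)
  res <- run_protocol(samples,
                      protocol_spec("intersubject", "both", "both"),
                      hidden = c(75, 65),
                      cfg = train_config(seed = 4))
  expect_true(all(res$window_accuracy == 1))
  expect_true(all(res$overall$final_accuracy == 1))
  expect_equal(res$undecided_rate, 0)
  expect_true(all(res$per_level$AC == 1, na.rm = TRUE))
  expect_equal(res$advs, 5)
})

test_that("label shuffling drives window accuracy to chance", {
  samples <- small_protocol_samples(n_subjects = 6, duration = 5,
                                    noiseless = TRUE, seed = 5,
                                    emotions = "sadness", n_dsr = 1)
  # break the band-stream link by permuting the recorded bands
  set.seed(55)
  perm <- sample(length(samples))
  for (i in seq_along(samples)) {
    samples[[i]]$bands <- samples[[perm[i]]]$bands
  }
  res <- run_protocol(samples,
                      protocol_spec("intersubject", "both", "both"),
                      hidden = c(8, 6),
                      cfg = train_config(max_epochs = 150, seed = 5))
  acc <- mean(res$window_accuracy)
  expect_lt(abs(acc - 0.2), 0.18)  # binomial slack at small n
})

test_that("intrasubject folds hold out one session at a time", {
  samples <- small_protocol_samples(n_subjects = 2, n_sessions = 3,
                                    duration = 5, seed = 6,
                                    emotions = "sadness", n_dsr = 1)
  res <- run_protocol(samples,
                      protocol_spec("intrasubject", "both", "both"),
                      hidden = c(6, 4),
                      cfg = train_config(max_epochs = 40, seed = 6))
  man <- res$manifest
  key <- function(ids) unique(paste(
    vapply(samples[ids], `[[`, numeric(1), "subject"),
    vapply(samples[ids], `[[`, numeric(1), "session")))
  for (f in unique(man$fold)) {
    tr <- man$id[man$fold == f & man$role == "train"]
    te <- man$id[man$fold == f & man$role == "test"]
    expect_length(intersect(key(tr), key(te)), 0)
    # train folds stay within the test subject
    expect_equal(unique(vapply(samples[tr], `[[`, numeric(1), "subject")),
                 unique(vapply(samples[te], `[[`, numeric(1), "subject")))
  }
})
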