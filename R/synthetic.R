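#' Synthetic stream generator configuration
#'
#' Parameters of the synthetic affect-stream model. Severity expresses
#' itself as episodic bursts of the scale's four signature AUs at level D
#' or E: in each one-second window an episode occurs with probability
#' `episode_prob[rank]` and lasts `round(fps * episode_frac[rank])`
#' frames, so both the chance and the within-window prevalence of the
#' signature grow with severity rank and a single window carries rank
#' information. Induced emotions activate their classical FACS prototype
#' AUs (capped at level C) independently of severity. An emotion
#' associated with a scale (see [emotion_associations()]) elicits that
#' scale's expression, making its episodes fully reliable
#' (`episode_prob -> 1`); a non-associated induced emotion dominates the
#' face and masks the scale's expression, multiplying `episode_prob` by
#' `emotion_mask`. This is what makes emotion-matched training data
#' informative and unmatched training data misleading. Baseline activity
#' turns any AU on at low intensity with probability `baseline_prob` per
#' frame. `noiseless = TRUE` removes all stochastic elements: episodes
#' deterministic (absent at Normal), level E, fixed placement, no
#' baseline.
#'
#' @param fps Frames per second (default 30).
#' @param duration Stream length in seconds (default 60).
#' @param baseline_prob Per-frame, per-AU baseline activation probability.
#' @param episode_prob Probability per second of a signature episode, by
#'   severity rank 1..5.
#' @param episode_frac Fraction of the second covered by an episode, by
#'   rank.
#' @param emotion_prob Probability per second of an emotion-prototype
#'   burst when an emotion is induced.
#' @param emotion_mask Factor applied to `episode_prob` of scales not
#'   associated with the induced emotion.
#' @param level_jitter Probability that an episode runs at level D rather
#'   than E.
#' @param noiseless Strip all randomness from the severity signal.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(fps = 30, duration = 60,
                             baseline_prob = 0.05,
                             episode_prob = c(0.02, 0.8, 0.9, 0.95, 0.99),
                             episode_frac = c(0.1, 0.15, 0.35, 0.6, 0.9),
                             emotion_prob = 0.6,
                             emotion_mask = 0.25,
                             level_jitter = 0.5,
                             noiseless = FALSE) {
  stopifnot(fps >= 1, duration >= 1,
            all(episode_prob >= 0 & episode_prob <= 1),
            length(episode_prob) == 5, length(episode_frac) == 5,
            baseline_prob >= 0, baseline_prob <= 1,
            emotion_mask >= 0, emotion_mask <= 1)
  structure(list(fps = fps, duration = duration,
                 baseline_prob = baseline_prob,
                 episode_prob = episode_prob,
                 episode_frac = episode_frac,
                 emotion_prob = emotion_prob,
                 emotion_mask = emotion_mask,
                 level_jitter = level_jitter,
                 noiseless = noiseless),
            class = "generator_config")
}

#' Generate a synthetic subject cohort
#'
#' Draws per-scale severity bands from the requested marginal
#' distribution and flags a fraction of subjects with one (never more)
#' of MDD, GAD or PTSD; a disorder forces the matched scale (depression,
#' anxiety, stress respectively) to Severe or Extremely Severe. With
#' `n_sessions > 1`, later sessions evolve by a per-scale random walk of
#' one band step with probability 0.4, emulating a mean drift of 0.8
#' levels over two sessions; a disorder subject's matched scale never
#' drops below Severe.
#'
#' @param n_subjects Number of subjects.
#' @param band_dist Probabilities of the five bands (recycled per scale);
#'   must sum to 1.
#' @param n_sessions Sessions per subject (default 1).
#' @param disorder_fraction Named fractions of subjects with each
#'   disorder; defaults emulate 20/19/17 cases in a 128-subject cohort.
#' @param seed Integer seed.
#' @return Data frame with one row per subject x session: `subject`,
#'   `session`, `depression`, `anxiety`, `stress` (band names),
#'   `disorder` (`"none"` or a disorder name), `sex` (unused tag).
#' @export
generate_cohort <- function(n_subjects, band_dist = rep(0.2, 5),
                            n_sessions = 1,
                            disorder_fraction = c(MDD = 20, GAD = 19,
                                                  PTSD = 17) / 128,
                            seed = 1) {
  if (n_subjects < 1) stop("need at least one subject", call. = FALSE)
  if (abs(sum(band_dist) - 1) > 1e-8 || any(band_dist < 0)) {
    stop("band_dist must be a probability distribution over 5 bands",
         call. = FALSE)
  }
  set.seed(seed)
  bands <- severity_bands()
  n_dis <- round(disorder_fraction * n_subjects)
  disorder <- rep("none", n_subjects)
  pool <- sample(n_subjects)
  k <- 0
  for (d in names(n_dis)) {
    take <- seq_len(n_dis[[d]]) + k
    disorder[pool[take[take <= n_subjects]]] <- d
    k <- k + n_dis[[d]]
  }
  base <- matrix(sample(5, 3 * n_subjects, replace = TRUE,
                        prob = band_dist), ncol = 3)
  colnames(base) <- dass_scales()
  for (i in seq_len(n_subjects)) {
    if (disorder[i] != "none") {
      s <- disorder_scale_map()[[disorder[i]]]
      base[i, s] <- sample(4:5, 1)
    }
  }
  rows <- list()
  for (i in seq_len(n_subjects)) {
    cur <- base[i, ]
    for (ses in seq_len(n_sessions)) {
      if (ses > 1) {
        # +/-1 each w.p. 0.4: mean absolute drift of 0.8 bands per session
        step <- sample(c(-1, 0, 1), 3, replace = TRUE,
                       prob = c(0.4, 0.2, 0.4))
        cur <- pmin(pmax(cur + step, 1), 5)
        if (disorder[i] != "none") {
          s <- disorder_scale_map()[[disorder[i]]]
          cur[s] <- max(cur[s], 4)
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject = i, session = ses,
        depression = bands[cur["depression"]],
        anxiety = bands[cur["anxiety"]],
        stress = bands[cur["stress"]],
        disorder = disorder[i],
        sex = c("F", "M")[(i %% 2) + 1])
    }
  }
  do.call(rbind, rows)
}

# integer level codes 0 (O) .. 5 (E) used internally by the generator
code_to_letter <- function(code) au_levels()[code + 1L]

#' Generate a synthetic AU intensity stream
#'
#' Builds a `duration x fps`-frame stream for one subject session whose
#' per-scale severity bands drive signature-AU episodes as described in
#' [generator_config()]. An induced emotion adds its prototype-AU bursts
#' and makes the episodes of its associated scales fully reliable.
#'
#' @param bands Named character vector of the three scale bands (as in a
#'   [generate_cohort()] row).
#' @param emotion One of [basic_emotions()], or `NULL` for a
#'   no-emotion-induced (random-condition) stream.
#' @param cfg A [generator_config()].
#' @param seed Integer seed.
#' @return AU stream data frame: `frame_index` plus 31 level columns.
#' @export
generate_au_stream <- function(bands, emotion = NULL,
                               cfg = generator_config(), seed = 1) {
  if (!is.null(emotion) && !emotion %in% basic_emotions()) {
    stop("unknown emotion: ", emotion, call. = FALSE)
  }
  set.seed(seed)
  fps <- cfg$fps
  n <- cfg$duration * fps
  cat31 <- au_catalog()
  codes <- matrix(0L, nrow = 31, ncol = n, dimnames = list(cat31, NULL))

  # baseline activity (off in noiseless mode)
  if (!cfg$noiseless && cfg$baseline_prob > 0) {
    on <- matrix(stats::runif(31 * n) < cfg$baseline_prob, 31, n)
    lv <- matrix(sample(1:5, 31 * n, replace = TRUE,
                        prob = c(0.5, 0.3, 0.15, 0.04, 0.01)), 31, n)
    codes[on] <- pmax(codes[on], lv[on])
  }

  rules <- signature_rules()
  assoc <- emotion_associations()
  for (s in dass_scales()) {
    r <- band_rank(bands[[s]])
    ep <- cfg$episode_prob[r]
    if (cfg$noiseless) ep <- if (r == 1) 0 else 1
    if (!is.null(emotion)) {
      # a matched emotion elicits the expression; an unmatched one
      # dominates the face and masks it
      if (emotion %in% assoc[[s]]) { if (r > 1) ep <- 1 }
      else ep <- ep * cfg$emotion_mask
    }
    dur <- round(fps * cfg$episode_frac[r])
    rows <- match(rules[[s]], cat31)
    for (sec in seq_len(cfg$duration)) {
      if (stats::runif(1) >= ep) next
      d <- if (cfg$noiseless) dur else
        max(1L, dur + sample(-2:2, 1))
      d <- min(d, fps)
      start <- if (cfg$noiseless) 1L else sample(fps - d + 1L, 1)
      cols <- (sec - 1L) * fps + start + seq_len(d) - 1L
      lev <- if (cfg$noiseless) 5L else
        if (stats::runif(1) < cfg$level_jitter) 4L else 5L
      codes[rows, cols] <- pmax(codes[rows, cols], lev)
    }
  }

  if (!is.null(emotion)) {
    proto <- match(intersect(emotion_prototypes()[[emotion]], cat31), cat31)
    for (sec in seq_len(cfg$duration)) {
      if (stats::runif(1) >= cfg$emotion_prob) next
      d <- max(1L, round(fps * 0.3) + sample(-2:2, 1))
      start <- sample(fps - d + 1L, 1)
      cols <- (sec - 1L) * fps + start + seq_len(d) - 1L
      lev <- sample(2:3, 1)   # emotion bursts run at level B or C
      codes[proto, cols] <- pmax(codes[proto, cols], lev)
    }
  }

  out <- data.frame(frame_index = seq_len(n) - 1L)
  for (i in seq_along(cat31)) out[[cat31[i]]] <- code_to_letter(codes[i, ])
  out
}

#' Generate prevalence-coded training windows
#'
#' Produces 31x30 windows whose band targets are a deterministic monotone
#' function of the signature-AU window means: for each scale a severity
#' rank is drawn uniformly and its four signature AUs are set to level E
#' in 0 / 7 / 15 / 22 / 30 of the 30 columns (rank 1..5). Depression
#' fills columns from the left and stress from the right, so the AUs the
#' two scales share carry the union of their bursts while each scale's
#' private AU stays exact. Targets are the band midpoints
#' ([band_midpoints()]). With `noise_sd > 0`, Gaussian perturbation
#' (clipped to \[0, 0.9\] and snapped back to the intensity grid) is
#' applied.
#'
#' @param n Number of windows.
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of optional level noise (default 0,
#'   i.e. noiseless).
#' @return List with `windows` (list of `fm_window`), `targets` (3 x n
#'   matrix of midpoint activations) and `bands` (data frame of the
#'   generating band names).
#' @export
generate_training_windows <- function(n, seed = 1, noise_sd = 0) {
  set.seed(seed)
  cat31 <- au_catalog()
  rules <- signature_rules()
  nburst <- c(0L, 7L, 15L, 22L, 30L)
  mids <- band_midpoints()
  grid <- unname(intensity_map())
  windows <- vector("list", n)
  targets <- matrix(0, 3, n)
  ranks <- matrix(sample(5, 3 * n, replace = TRUE), nrow = 3)
  fill <- list(depression = function(k) seq_len(k),
               anxiety = function(k) seq_len(k),
               stress = function(k) 31L - seq_len(k))
  for (i in seq_len(n)) {
    w <- matrix(0, 31, 30, dimnames = list(cat31, NULL))
    for (si in seq_along(dass_scales())) {
      s <- dass_scales()[si]
      k <- nburst[ranks[si, i]]
      if (k > 0) {
        cols <- fill[[s]](k)
        w[rules[[s]], cols] <- pmax(w[rules[[s]], cols], 0.9)
      }
      targets[si, i] <- mids[ranks[si, i]]
    }
    if (noise_sd > 0) {
      w <- w + matrix(stats::rnorm(31 * 30, sd = noise_sd), 31, 30)
      w[] <- grid[pmax(1, apply(abs(outer(as.vector(w), grid, "-")),
                                1, which.min))]
    }
    windows[[i]] <- fm_window(w, start_frame = 0L)
  }
  list(windows = windows, targets = targets,
       bands = data.frame(depression = severity_bands()[ranks[1, ]],
                          anxiety = severity_bands()[ranks[2, ]],
                          stress = severity_bands()[ranks[3, ]]))
}

#' Generate a 72-dimensional feature vector for an AU frame
#'
#' Stand-in for the appearance-model stage: class-conditional Gaussian
#' clusters in feature space. Coordinates j and 31 + j (j = 1..31) both
#' carry AU j's intensity as `separation * rank(level)` plus unit
#' Gaussian noise — a redundant two-coordinate encoding, as appearance
#' parameters never isolate one muscle in one coordinate — and the last
#' ten coordinates are pure noise. Larger separation makes
#' nearest-centroid (and SVM) decoding of all 31 levels arbitrarily
#' accurate.
#'
#' @param frames AU stream data frame (or single frame) of level letters.
#' @param separation Cluster separation in noise-sd units (default 6).
#' @param seed Integer seed.
#' @return Numeric matrix, one row per frame, 72 columns `f01..f72`.
#' @export
generate_feature_vectors <- function(frames, separation = 6, seed = 1) {
  set.seed(seed)
  if (!is.data.frame(frames)) frames <- as.data.frame(as.list(frames))
  cat31 <- au_catalog()
  n <- nrow(frames)
  X <- matrix(stats::rnorm(n * 72), n, 72)
  for (j in seq_along(cat31)) {
    lv <- match(frames[[cat31[j]]], au_levels()) - 1L
    if (anyNA(lv)) stop("invalid level in frames for ", cat31[j],
                        call. = FALSE)
    X[, j] <- X[, j] + separation * lv
    X[, 31 + j] <- X[, 31 + j] + separation * lv
  }
  colnames(X) <- sprintf("f%02d", 1:72)
  X
}

#' Generate a synthetic binary face mask
#'
#' Elliptical face region whose row profile peaks exactly at the
#' requested eye and mouth row fractions (those rows are widened to the
#' full mask width), plus optional salt noise, for exercising the block
#' detector.
#'
#' @param H,W Mask height and width (H >= 20).
#' @param eye_row_frac,mouth_row_frac Row positions as fractions of H;
#'   eye must be above mouth.
#' @param noise Probability of flipping a background pixel to white.
#' @param seed Integer seed.
#' @return Binary H x W matrix.
#' @export
generate_face_mask <- function(H = 200, W = 150, eye_row_frac = 0.3,
                               mouth_row_frac = 0.65, noise = 0,
                               seed = 1) {
  if (!(eye_row_frac > 0 && eye_row_frac < mouth_row_frac &&
        mouth_row_frac < 1)) {
    stop("need 0 < eye_row_frac < mouth_row_frac < 1", call. = FALSE)
  }
  stopifnot(H >= 20, W >= 5)
  set.seed(seed)
  mask <- matrix(0, H, W)
  cy <- H / 2; cx <- W / 2
  for (r in seq_len(H)) {
    # ellipse half-width at this row, capped below full width
    hw <- (W / 2 - 2) * sqrt(pmax(0, 1 - ((r - cy) / (H / 2))^2))
    if (hw > 0.5) {
      mask[r, max(1, round(cx - hw)):min(W, round(cx + hw))] <- 1
    }
  }
  eye_row <- round(eye_row_frac * H) + 1L     # profile peak rows (1-based)
  mouth_row <- round(mouth_row_frac * H) + 1L
  mask[eye_row, ] <- 1
  mask[mouth_row, ] <- 1
  if (noise > 0) {
    flip <- matrix(stats::runif(H * W) < noise, H, W) & mask == 0
    mask[flip] <- 1
  }
  mask
}

#' Generate a questionnaire response consistent with target bands
#'
#' Draws a raw score uniformly inside each scale's band interval and
#' distributes it over that scale's 14 items (each capped at 3), so the
#' generated response always re-bands to the generating profile.
#'
#' @param bands Named character vector of the three scale bands.
#' @param scale_assignment Item map, default [default_scale_assignment()].
#' @param seed Integer seed.
#' @return Integer vector of 42 item scores.
#' @export
generate_saq <- function(bands, scale_assignment = default_scale_assignment(),
                         seed = 1) {
  set.seed(seed)
  item_scores <- integer(42)
  for (s in dass_scales()) {
    edges <- dass_band_table()[[s]]
    r <- band_rank(bands[[s]])
    lo <- edges[r]
    hi <- if (r < 5) edges[r + 1] - 1 else 42
    raw <- sample(lo:hi, 1)
    items <- scale_assignment[[s]]
    sc <- integer(14)
    for (u in seq_len(raw)) {
      open <- which(sc < 3)  # capacity always exists since raw <= 42
      pick <- open[sample.int(length(open), 1)]
      sc[pick] <- sc[pick] + 1L
    }
    item_scores[items] <- sc
  }
  item_scores
}
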