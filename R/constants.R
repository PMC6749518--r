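#' The 31-AU catalog
#'
#' The canonical ordered set of FACS action units analyzed by the pipeline:
#' upper face (AU1, AU2, AU4, AU5, AU6, AU7, AU43, AU45), lower face
#' (AU8--AU20, AU22--AU28) and the cheek units (AU33, AU34, AU35). AU41,
#' AU42 and AU46 are excluded because they are not coded with intensity
#' levels. The catalog order (ascending AU number) fixes the row order of
#' every facial matrix and the column order of every AU stream.
#'
#' @return Character vector of length 31, e.g. `"AU1"`, `"AU2"`, ...
#' @export
#' @examples
#' au_catalog()
au_catalog <- function() {
  paste0("AU", sort(c(1, 2, 4, 5, 6, 7, 43, 45,      # upper face
                      8:20, 22:28,                   # lower face
                      33, 34, 35)))                  # cheeks
}

#' AU intensity levels
#'
#' FACS codes each action unit's intensity on an ordinal scale:
#' O (not active), A (trace), B (slight), C (marked or pronounced),
#' D (severe or extreme), E (maximum).
#'
#' @return Character vector `c("O","A","B","C","D","E")` in increasing order.
#' @export
au_levels <- function() c("O", "A", "B", "C", "D", "E")

#' Severity band names
#'
#' The five DASS severity bands in increasing order.
#'
#' @return Character vector of the five band names.
#' @export
severity_bands <- function() {
  c("Normal", "Mild", "Moderate", "Severe", "ExtremelySevere")
}

#' Intensity normalization map
#'
#' The fixed mapping from AU intensity level to the real value stored in
#' the facial matrix: O = 0, A = 0.2, B = 0.4, C = 0.6, D = 0.8, E = 0.9.
#' The top step is deliberately non-uniform (D = 0.8, E = 0.9) and is kept
#' exactly as specified rather than rescaled.
#'
#' @return Named numeric vector keyed by level letter.
#' @export
#' @examples
#' intensity_map()[["C"]]  # 0.6
intensity_map <- function() {
  c(O = 0, A = 0.2, B = 0.4, C = 0.6, D = 0.8, E = 0.9)
}

#' Raw-score band table for the DASS-42 scales
#'
#' Lower band edges of the five severity bands on the raw 0--42 scale
#' score: depression 0/10/14/21/28, anxiety 0/8/10/15/20, stress
#' 0/15/19/26/34. A raw score belongs to the highest band whose lower
#' edge it reaches.
#'
#' @return Named list with one integer vector of five lower edges per scale.
#' @export
dass_band_table <- function() {
  list(
    depression = c(0, 10, 14, 21, 28),
    anxiety    = c(0,  8, 10, 15, 20),
    stress     = c(0, 15, 19, 26, 34)
  )
}

#' DASS scale names
#' @return `c("depression", "anxiety", "stress")`
#' @export
dass_scales <- function() c("depression", "anxiety", "stress")

#' Activation banding thresholds
#'
#' Thresholds on a network output activation in \[0,1\] separating the five
#' severity bands: \[0, 0.15) Normal, \[0.15, 0.3) Mild, \[0.3, 0.6)
#' Moderate, \[0.6, 0.8\] Severe, (0.8, 1\] Extremely Severe. The printed
#' intervals share endpoints; the implementation resolves them lower-
#' inclusive except that 0.8 belongs to Severe ("over 0.8" is strict).
#'
#' @return Numeric vector `c(0.15, 0.3, 0.6, 0.8)`.
#' @export
banding_thresholds <- function() c(0.15, 0.3, 0.6, 0.8)

#' Band-midpoint activation encoding
#'
#' The activation value used to encode each severity band as a network
#' training target: the midpoint of its banding interval (Normal 0.075,
#' Mild 0.225, Moderate 0.45, Severe 0.7, ExtremelySevere 0.9). Midpoints
#' are strictly positive, so the relative-error loss never divides by a
#' zero target.
#'
#' @return Named numeric vector keyed by band name.
#' @export
band_midpoints <- function() {
  stats::setNames(c(0.075, 0.225, 0.45, 0.7, 0.9), severity_bands())
}

#' AU-signature rules for the Extremely Severe shortcut
#'
#' Per scale, the four action units whose joint presence at intensity
#' level D or E inside one window triggers an immediate Extremely Severe
#' prediction for that scale, bypassing the network: depression
#' \{AU6, AU12, AU15, AU26\}, anxiety \{AU2, AU9, AU25, AU45\}, stress
#' \{AU1, AU6, AU12, AU15\}.
#'
#' @return Named list of character vectors of AU ids, one per scale.
#' @export
signature_rules <- function() {
  list(
    depression = c("AU6", "AU12", "AU15", "AU26"),
    anxiety    = c("AU2", "AU9", "AU25", "AU45"),
    stress     = c("AU1", "AU6", "AU12", "AU15")
  )
}

#' Emotion-to-scale associations
#'
#' Which induced basic emotions carry the most severity information for
#' each DASS scale: happiness and sadness for depression, surprise and
#' disgust for anxiety, sadness and disgust for stress. The synthetic
#' generator builds these associations into its streams; the evaluation
#' protocol can restrict training to the associated emotions.
#'
#' @return Named list of character vectors of emotion names, one per scale.
#' @export
emotion_associations <- function() {
  list(
    depression = c("happiness", "sadness"),
    anxiety    = c("surprise", "disgust"),
    stress     = c("sadness", "disgust")
  )
}

#' The six basic emotions
#' @return Character vector of the six inducible emotions.
#' @export
basic_emotions <- function() {
  c("sadness", "fear", "happiness", "anger", "surprise", "disgust")
}

# Classical FACS prototypes of the six basic emotions: the AUs an induced
# emotion activates on top of the severity-driven signal.
emotion_prototypes <- function() {
  list(
    happiness = c("AU6", "AU12"),
    sadness   = c("AU1", "AU4", "AU15"),
    surprise  = c("AU1", "AU2", "AU5", "AU26"),
    disgust   = c("AU9", "AU15", "AU16"),
    fear      = c("AU1", "AU2", "AU4", "AU5", "AU20", "AU26"),
    anger     = c("AU4", "AU5", "AU7", "AU23")
  )
}

#' Disorder names of the binary variant network
#' @return `c("MDD", "GAD", "PTSD")`
#' @export
disorder_names <- function() c("MDD", "GAD", "PTSD")

# scale each disorder expresses through (MDD -> depression, GAD -> anxiety,
# PTSD -> stress in the generator's default policy)
disorder_scale_map <- function() {
  c(MDD = "depression", GAD = "anxiety", PTSD = "stress")
}
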