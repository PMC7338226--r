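#' The twelve emotion types
#'
#' The closed answer set used throughout: the twelve OCC emotion types the
#' agent can generate and that respondents choose from. Order matches the
#' published emotion-choice tables and is used for all matrix/CSV exports.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' emotion_types()
emotion_types <- function() {
  c("distress", "joy", "fear", "hope", "pride", "shame",
    "admiration", "reproach", "gratification", "gratitude",
    "remorse", "anger")
}

#' Moral / non-moral emotion partition
#'
#' Moral emotions are those elicited by compliance with, or violation of,
#' moral standards (one's own or another's); the remaining four are
#' goal/likelihood based. The two sets are disjoint and cover all twelve
#' types. This operational partition is the one under which the published
#' group means are internally consistent (the score definitions name a few
#' labels, e.g. "contempt", that are not in the twelve-type answer set).
#'
#' @return Character vector of emotion types.
#' @export
#' @examples
#' moral_emotions()
moral_emotions <- function() {
  c("admiration", "reproach", "gratification", "gratitude",
    "pride", "shame", "anger", "remorse")
}

#' @rdname moral_emotions
#' @export
nonmoral_emotions <- function() {
  c("joy", "distress", "fear", "hope")
}

#' Valence of an emotion type
#'
#' Joy, hope, pride, admiration, gratification and gratitude count as
#' positive; distress, fear, shame, reproach, remorse and anger as negative.
#' Used when netting anticipated emotions into the expected emotional reward.
#'
#' @param type Character vector of emotion types.
#' @return Numeric vector of +1 / -1.
#' @export
emotion_valence <- function(type) {
  pos <- c("joy", "hope", "pride", "admiration", "gratification", "gratitude")
  check_emotions(type)
  ifelse(type %in% pos, 1, -1)
}

# compound type -> the two component appraisal-variable signatures
compound_components <- function() {
  list(
    gratification = c("desirability", "praiseworthiness.self"),
    gratitude     = c("desirability", "praiseworthiness.other"),
    remorse       = c("undesirability", "blameworthiness.self"),
    anger         = c("undesirability", "blameworthiness.other")
  )
}

check_emotions <- function(x) {
  bad <- setdiff(x, emotion_types())
  if (length(bad)) {
    stop("unknown emotion label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Expected emotional reward of a set of emotions
#'
#' Sum of intensities of positive-valence emotions minus the sum for
#' negative-valence ones.
#'
#' @param emotions An emotion data frame as returned by [derive_affect()]
#'   (columns `type` and `intensity`).
#' @return A single number.
#' @export
eer <- function(emotions) {
  if (is.null(emotions) || nrow(emotions) == 0) return(0)
  sum(emotion_valence(emotions$type) * emotions$intensity)
}
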