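#' Affect-derivation configuration
#'
#' Tunable parameters of the appraisal machinery. All numeric choices the
#' underlying theory leaves open are surfaced here rather than hard-coded.
#'
#' @param coemit_compounds When a compound emotion fires (gratification,
#'   gratitude, remorse, anger), also emit its two component emotions
#'   (default) or suppress them. Scenario files may override per scenario.
#' @param theta_hope Likelihood at or above which hope is generated.
#' @param theta_fear Likelihood at or below which fear is generated.
#' @param l_ref Reference plan length for the effort factor
#'   `min(1, length / l_ref)`.
#' @param w_eer Weight of the expected emotional reward in plan utility.
#' @return A list of class `affect_config`.
#' @export
affect_config <- function(coemit_compounds = TRUE, theta_hope = 0.7,
                          theta_fear = 0.3, l_ref = 5, w_eer = 1) {
  stopifnot(is.logical(coemit_compounds), length(coemit_compounds) == 1L,
            theta_hope >= 0, theta_hope <= 1,
            theta_fear >= 0, theta_fear <= 1, theta_fear <= theta_hope,
            l_ref >= 1, is.numeric(w_eer), length(w_eer) == 1L)
  structure(list(coemit_compounds = coemit_compounds,
                 theta_hope = theta_hope, theta_fear = theta_fear,
                 l_ref = l_ref, w_eer = w_eer),
            class = "affect_config")
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in intersect(names(override), names(base))) base[[nm]] <- override[[nm]]
  do.call(affect_config, unclass(base))
}

#' Effort factor of a plan
#'
#' Longer plans demand more effort and scale emotion intensity upward, capped
#' at 1: `min(1, length / l_ref)`.
#'
#' @param length Plan length (number of steps), a positive integer.
#' @param l_ref Reference length (default 5).
#' @return A real in (0, 1].
#' @export
effort_factor <- function(length, l_ref = 5) {
  stopifnot(length >= 1)
  pmin(1, length / l_ref)
}

#' Emotion intensity
#'
#' Intensity is the product of the importance of the goal or value involved,
#' the probability of success of the plan, and the effort factor.
#'
#' @param importance Importance of the goal (or priority of the value), in
#'   \[0, 1\].
#' @param probability Probability of success (1 for realized outcomes).
#' @param effort_factor Effort factor in \[0, 1\], see [effort_factor()].
#' @return A real in \[0, 1\].
#' @export
#' @examples
#' emotion_intensity(0.9, 0.8, 0.2)
emotion_intensity <- function(importance, probability, effort_factor) {
  for (a in list(importance = importance, probability = probability,
                 effort_factor = effort_factor)) {
    if (!is.numeric(a) || any(is.na(a)) || any(a < 0) || any(a > 1)) {
      stop("emotion_intensity arguments must lie in [0, 1]", call. = FALSE)
    }
  }
  importance * probability * effort_factor
}

#' Derive emotions from appraisal variables
#'
#' Applies the affect-derivation rule table:
#' * desirability -> joy; undesirability -> distress;
#' * praiseworthiness -> pride (self-caused) or admiration (other-caused);
#' * blameworthiness -> shame (self-caused) or reproach (other-caused);
#' * likelihood >= `theta_hope` -> hope; <= `theta_fear` -> fear;
#' * compound emotions when both component variables are present *with the
#'   same cause*: gratification (desirability + self-praiseworthiness),
#'   gratitude (desirability + other-praiseworthiness), remorse
#'   (undesirability + self-blameworthiness), anger (undesirability +
#'   other-blameworthiness). Compound intensity is the mean of its two
#'   components. Under `coemit_compounds = FALSE` the component emotions of
#'   a fired compound are suppressed.
#'
#' @param vars An [appraisal_vars()] data frame.
#' @param config An [affect_config()].
#' @param anticipatory Logical flag stamped on the resulting emotions.
#' @return Emotion data frame (`type`, `intensity`, `cause`, `anticipatory`,
#'   `components`).
#' @export
derive_affect <- function(vars, config = affect_config(), anticipatory = FALSE) {
  if (is.null(vars) || nrow(vars) == 0L) return(empty_emotions())
  out <- empty_emotions()
  consumed <- rep(FALSE, nrow(vars))   # components of fired compounds

  simple_type <- function(v) {
    switch(v$kind,
      desirability   = "joy",
      undesirability = "distress",
      praiseworthiness = if (v$responsibility == "self") "pride" else "admiration",
      blameworthiness  = if (v$responsibility == "self") "shame" else "reproach",
      likelihood = {
        if (v$intensity >= config$theta_hope) "hope"
        else if (v$intensity <= config$theta_fear) "fear"
        else NA_character_
      })
  }

  sig <- function(v) {
    if (v$kind %in% c("praiseworthiness", "blameworthiness")) {
      paste(v$kind, v$responsibility, sep = ".")
    } else v$kind
  }

  # compounds: scan cause groups for component pairs
  for (cs in unique(vars$cause)) {
    idx <- which(vars$cause == cs)
    sigs <- vapply(idx, function(i) sig(vars[i, ]), character(1))
    for (ctype in names(compound_components())) {
      comp <- compound_components()[[ctype]]
      i1 <- idx[sigs == comp[1]]
      i2 <- idx[sigs == comp[2]]
      for (a in i1) for (b in i2) {
        inten <- mean(c(vars$intensity[a], vars$intensity[b]))
        out <- rbind(out, emotion_row(ctype, inten, cs, anticipatory,
                                      paste(comp, collapse = "+")))
        consumed[c(a, b)] <- TRUE
      }
    }
  }

  for (i in seq_len(nrow(vars))) {
    if (consumed[i] && !config$coemit_compounds) next
    v <- vars[i, ]
    ty <- simple_type(v)
    if (is.na(ty)) next
    out <- rbind(out, emotion_row(ty, v$intensity, v$cause, anticipatory))
  }
  rownames(out) <- NULL
  out
}
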