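#' Propositions and world states
#'
#' The condition language is deliberately minimal: ground propositions of the
#' form `name(arg1, arg2, ...)` (or a bare `name` for 0-ary facts), and
#' conditions that are disjunctions of conjunctions of such propositions.
#' There is no negation and there are no variables; this is the smallest
#' language sufficient to encode the packaged scenarios.
#'
#' @param name Predicate name (lower-case identifier).
#' @param args Character vector of argument identifiers (possibly empty).
#' @return `proposition()` returns a `proposition` object; `prop_string()`
#'   its canonical string form.
#' @export
#' @examples
#' p <- proposition("has_key", "wallace")
#' prop_string(p)
proposition <- function(name, args = character()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("proposition name must be a non-empty string", call. = FALSE)
  }
  if (!grepl("^[a-z_][a-z0-9_]*$", name)) {
    stop("invalid predicate name: ", name, call. = FALSE)
  }
  args <- as.character(args)
  if (length(args) && any(!grepl("^[a-z0-9_]+$", args))) {
    stop("proposition arguments must be ground identifiers: ",
         paste(args, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, args = args), class = "proposition")
}

#' @rdname proposition
#' @param x A `proposition` or a canonical fact string.
#' @export
prop_string <- function(x) {
  if (inherits(x, "proposition")) {
    if (length(x$args) == 0L) return(x$name)
    return(paste0(x$name, "(", paste(x$args, collapse = ","), ")"))
  }
  as.character(x)
}

#' @rdname proposition
#' @export
parse_prop <- function(x) {
  x <- gsub(" ", "", as.character(x))
  m <- regmatches(x, regexec("^([a-z_][a-z0-9_]*)(?:\\(([a-z0-9_,]*)\\))?$", x))[[1]]
  if (length(m) == 0L) stop("cannot parse proposition: '", x, "'", call. = FALSE)
  args <- if (is.na(m[3]) || m[3] == "") character() else strsplit(m[3], ",")[[1]]
  proposition(m[2], args)
}

prop_name <- function(fact) parse_prop(fact)$name

#' @rdname proposition
#' @param facts Character vector of fact strings (or list of propositions).
#' @export
world_state <- function(facts = character()) {
  facts <- vapply(facts, prop_string, character(1), USE.NAMES = FALSE)
  invisible(lapply(facts, parse_prop))           # validates
  structure(sort(unique(facts)), class = "world_state")
}

world_add <- function(world, facts) world_state(c(unclass(world), facts))

world_del <- function(world, facts) {
  facts <- vapply(facts, prop_string, character(1), USE.NAMES = FALSE)
  missing <- setdiff(facts, world)
  if (length(missing)) {
    warning("deleting fact(s) not in world: ", paste(missing, collapse = ", "),
            call. = FALSE)
  }
  world_state(setdiff(unclass(world), facts))
}

# Conditions ------------------------------------------------------------

# A condition set is a list of conjunctions; each conjunction is a character
# vector of fact strings. A bare string is promoted to a singleton
# conjunction. The set holds if any conjunction has all its facts in the
# world; an empty set never holds.
normalize_conditions <- function(x) {
  if (is.null(x) || length(x) == 0L) return(list())
  if (is.character(x)) x <- as.list(x)
  lapply(x, function(cj) {
    cj <- vapply(unlist(cj, use.names = FALSE), prop_string, character(1),
                 USE.NAMES = FALSE)
    invisible(lapply(cj, parse_prop))
    cj
  })
}

condition_holds <- function(conds, world) {
  if (length(conds) == 0L) return(FALSE)
  any(vapply(conds, function(cj) all(cj %in% world), logical(1)))
}

# which conjunction (if any) is satisfied; NULL if none
satisfied_conjunction <- function(conds, world) {
  for (cj in conds) if (all(cj %in% world)) return(cj)
  NULL
}

condition_predicates <- function(conds) {
  unique(unlist(lapply(conds, function(cj) vapply(cj, prop_name, character(1)))))
}

# Goals, values, actions, plans ------------------------------------------

#' Construct a goal
#'
#' A goal carries an importance of success and of failure (both in (0, 1]),
#' and three condition sets: it is adopted when an adoption condition holds,
#' achieved when a success condition holds, failed when a failure condition
#' holds. Goals created to restore a value at stake have
#' `origin = "value_restoration"` and reference the value; such goals are
#' achieved when the value is back in balance.
#'
#' @param id Goal identifier.
#' @param importance_of_success,importance_of_failure Reals in (0, 1].
#' @param adoption,success,failure Condition sets (list of conjunctions;
#'   each conjunction a character vector of fact strings).
#' @param status One of `"inactive"`, `"active"`, `"achieved"`, `"failed"`,
#'   `"dropped"`.
#' @param origin `"intrinsic"` or `"value_restoration"`.
#' @param value_id For restoration goals, the id of the value restored.
#' @return A `goal` object.
#' @export
goal <- function(id, importance_of_success, importance_of_failure,
                 adoption = list(), success = list(), failure = list(),
                 status = "inactive", origin = "intrinsic", value_id = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  check_unit_open(importance_of_success, "importance_of_success")
  check_unit_open(importance_of_failure, "importance_of_failure")
  status <- match.arg(status, c("inactive", "active", "achieved", "failed", "dropped"))
  origin <- match.arg(origin, c("intrinsic", "value_restoration"))
  if (origin == "value_restoration" && is.null(value_id)) {
    stop("value_restoration goal must reference a value", call. = FALSE)
  }
  structure(list(
    id = id,
    importance_of_success = importance_of_success,
    importance_of_failure = importance_of_failure,
    adoption = normalize_conditions(adoption),
    success = normalize_conditions(success),
    failure = normalize_conditions(failure),
    status = status, origin = origin, value_id = value_id
  ), class = "goal")
}

# legal status moves: inactive -> active -> {achieved, failed, dropped}
goal_status_ok <- function(from, to) {
  if (from == to) return(TRUE)
  switch(from,
    inactive = to == "active",
    active   = to %in% c("achieved", "failed", "dropped"),
    FALSE)
}

set_goal_status <- function(g, to) {
  if (!goal_status_ok(g$status, to)) {
    stop("illegal goal status transition ", g$status, " -> ", to,
         " for goal ", g$id, call. = FALSE)
  }
  g$status <- to
  g
}

#' Construct a moral value
#'
#' A value has a priority in (0, 1] and a set of violation conditions; it is
#' *at stake* while one of them holds in the world, which both spawns a
#' restoration goal and drives moral appraisal (praise/blame).
#'
#' @param id Value identifier.
#' @param priority Real in (0, 1].
#' @param violation Condition set.
#' @param at_stake Logical.
#' @return A `moral_value` object.
#' @export
moral_value <- function(id, priority, violation = list(), at_stake = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  check_unit_open(priority, "priority")
  structure(list(
    id = id, priority = priority,
    violation = normalize_conditions(violation),
    at_stake = isTRUE(at_stake)
  ), class = "moral_value")
}

#' Construct an action
#'
#' STRIPS-style carrier for plan steps: preconditions (a conjunction of
#' facts) and add/delete effects, applied atomically.
#'
#' @param id Action identifier.
#' @param actor Character id of the acting agent.
#' @param preconditions Character vector of fact strings.
#' @param effects List of `list(op = "add"|"del", fact = <string>)`.
#' @return An `action` object.
#' @export
action <- function(id, actor, preconditions = character(), effects = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(actor), length(actor) == 1L)
  preconditions <- vapply(preconditions, prop_string, character(1), USE.NAMES = FALSE)
  effects <- lapply(effects, function(e) {
    if (is.null(e$op) || !e$op %in% c("add", "del") || is.null(e$fact)) {
      stop("effect must be list(op = 'add'|'del', fact = ...)", call. = FALSE)
    }
    list(op = e$op, fact = prop_string(e$fact))
  })
  structure(list(id = id, actor = actor, preconditions = preconditions,
                 effects = effects), class = "action")
}

#' Construct a plan
#'
#' An ordered sequence of actions in service of one goal, with an authored
#' probability of success. Plans are authored in the scenario file; the
#' package does not synthesize them. `failure_effects` are applied instead
#' of the step effects when the scripted outcome is a failure.
#'
#' @param id Plan identifier.
#' @param goal_id Id of the goal the plan serves (use `restore:<value-id>`
#'   to attach a plan to the auto-generated restoration goal of a value).
#' @param steps List of [action()]s.
#' @param probability_of_success Real in (0, 1].
#' @param failure_effects Effects applied on scripted failure.
#' @return A `plan` object; `$length` equals the number of steps.
#' @export
plan <- function(id, goal_id, steps, probability_of_success,
                 failure_effects = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(goal_id), length(goal_id) == 1L)
  check_unit_open(probability_of_success, "probability_of_success")
  if (length(steps) < 1L || !all(vapply(steps, inherits, logical(1), "action"))) {
    stop("plan steps must be a non-empty list of actions", call. = FALSE)
  }
  structure(list(id = id, goal_id = goal_id, steps = steps,
                 probability_of_success = probability_of_success,
                 length = length(steps),
                 failure_effects = lapply(failure_effects, function(e)
                   list(op = e$op, fact = prop_string(e$fact))),
                 executed = FALSE), class = "mea_plan")
}

#' Construct an agent
#'
#' @param id Character id.
#' @param goals List of [goal()]s (ids unique).
#' @param values List of [moral_value()]s (ids unique).
#' @param plans Plan library, a list of [plan()]s.
#' @param emotional_state Emotion data frame (usually empty at start).
#' @return An `agent` object.
#' @export
agent <- function(id, goals = list(), values = list(), plans = list(),
                  emotional_state = empty_emotions()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  gid <- vapply(goals, `[[`, character(1), "id")
  vid <- vapply(values, `[[`, character(1), "id")
  if (anyDuplicated(gid)) stop("duplicate goal ids in agent ", id, call. = FALSE)
  if (anyDuplicated(vid)) stop("duplicate value ids in agent ", id, call. = FALSE)
  for (g in goals) {
    if (g$origin == "value_restoration" && !g$value_id %in% vid) {
      stop("restoration goal ", g$id, " references unknown value ", g$value_id,
           call. = FALSE)
    }
  }
  names(goals) <- gid
  names(values) <- vid
  if (length(plans)) names(plans) <- vapply(plans, `[[`, character(1), "id")
  structure(list(id = id, goals = goals, values = values, plans = plans,
                 emotional_state = emotional_state), class = "agent")
}

# Appraisal variables and emotions ---------------------------------------

#' Appraisal variables
#'
#' Variables are kept in a data frame with one row per variable:
#' `kind` (desirability, undesirability, praiseworthiness, blameworthiness,
#' likelihood), `intensity` in \[0, 1\], `responsibility` (self/other/none),
#' `source` (goal or value id) and `cause` (action/event id). Praise and
#' blame always carry responsibility self or other; a responsibility of
#' `none` marks goal/likelihood variables from non-intentional events.
#'
#' @param kind,intensity,responsibility,source,cause Vectors, recycled to a
#'   common length.
#' @return A data frame of class `appraisal_vars`.
#' @export
appraisal_vars <- function(kind = character(), intensity = numeric(),
                           responsibility = character(), source = character(),
                           cause = character()) {
  kinds <- c("desirability", "undesirability", "praiseworthiness",
             "blameworthiness", "likelihood")
  bad <- setdiff(kind, kinds)
  if (length(bad)) stop("unknown appraisal-variable kind: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(intensity < 0 | intensity > 1)) {
    stop("appraisal intensity must lie in [0, 1]", call. = FALSE)
  }
  if (length(kind)) {
    moral <- kind %in% c("praiseworthiness", "blameworthiness")
    if (any(moral & !responsibility %in% c("self", "other"))) {
      stop("praise/blameworthiness must carry responsibility self or other",
           call. = FALSE)
    }
  }
  out <- data.frame(kind = as.character(kind),
                    intensity = as.numeric(intensity),
                    responsibility = as.character(responsibility),
                    source = as.character(source),
                    cause = as.character(cause),
                    stringsAsFactors = FALSE)
  class(out) <- c("appraisal_vars", "data.frame")
  out
}

empty_emotions <- function() {
  data.frame(type = character(), intensity = numeric(), cause = character(),
             anticipatory = logical(), components = character(),
             stringsAsFactors = FALSE)
}

emotion_row <- function(type, intensity, cause, anticipatory, components = "") {
  data.frame(type = type, intensity = intensity, cause = cause,
             anticipatory = anticipatory, components = components,
             stringsAsFactors = FALSE)
}

check_unit_open <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x > 1) {
    stop(what, " must be a real in (0, 1], got ", format(x), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.world_state <- function(x, ...) {
  cat("<world state:", length(x), "facts>\n")
  if (length(x)) cat(" ", paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.agent <- function(x, ...) {
  cat("<agent ", x$id, ": ", length(x$goals), " goals, ", length(x$values),
      " values, ", length(x$plans), " plans>\n", sep = "")
  invisible(x)
}
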