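#' Value monitoring
#'
#' A value is at stake while one of its violation conditions holds in the
#' world. Optionally checks every condition against a set of declared
#' predicates (scenario files declare theirs; see [load_scenario()]).
#'
#' @param world A [world_state()].
#' @param values List of [moral_value()]s.
#' @param declared Optional character vector of declared predicate names;
#'   a condition mentioning any other predicate raises a validation error.
#' @return Character vector of ids of the values at stake.
#' @export
#' @examples
#' w <- world_state("stole(chocolate)")
#' v <- moral_value("honesty", 0.9, violation = list("stole(chocolate)"))
#' monitor_values(w, list(v))
monitor_values <- function(world, values, declared = NULL) {
  if (!is.null(declared)) {
    for (v in values) {
      bad <- setdiff(condition_predicates(v$violation), declared)
      if (length(bad)) {
        stop("value '", v$id, "' references undeclared predicate(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  ids <- vapply(values, `[[`, character(1), "id")
  hit <- vapply(values, function(v) condition_holds(v$violation, world), logical(1))
  ids[hit]
}

# update at_stake flags in place
refresh_value_flags <- function(ag, world) {
  at <- monitor_values(world, ag$values)
  for (vid in names(ag$values)) ag$values[[vid]]$at_stake <- vid %in% at
  ag
}

#' Goal formation
#'
#' Activates every inactive goal whose adoption condition holds in the
#' world, and creates (and activates) a restoration goal for each value at
#' stake that does not already have one. Restoration goals inherit
#' importance of success and of failure from the value's priority, carry the
#' id `restore_<value-id>`, and are achieved once the value is back in
#' balance. Goals already achieved or failed are never re-activated.
#'
#' @param ag An [agent()].
#' @param world A [world_state()].
#' @return The updated agent; use [active_goals()] to list its active goals.
#' @export
form_goals <- function(ag, world) {
  for (gid in names(ag$goals)) {
    g <- ag$goals[[gid]]
    if (g$status == "inactive" && condition_holds(g$adoption, world)) {
      ag$goals[[gid]] <- set_goal_status(g, "active")
    }
  }
  for (vid in names(ag$values)) {
    v <- ag$values[[vid]]
    if (!v$at_stake) next
    rid <- paste0("restore_", vid)
    existing <- vapply(ag$goals, function(g)
      g$origin == "value_restoration" && identical(g$value_id, vid) &&
        g$status == "active", logical(1))
    if (any(existing)) next
    while (rid %in% names(ag$goals)) rid <- paste0(rid, "_r")
    rg <- goal(rid, v$priority, v$priority,
               adoption = v$violation, status = "inactive",
               origin = "value_restoration", value_id = vid)
    rg <- set_goal_status(rg, "active")
    ag$goals[[rid]] <- rg
  }
  ag
}

#' @rdname form_goals
#' @export
active_goals <- function(ag) {
  Filter(function(g) g$status == "active", ag$goals)
}

# Delta computation ------------------------------------------------------

# execlog: list of entries list(plan_id, actor, plan_len, added, removed)
find_cause <- function(trigger, execlog) {
  if (length(trigger)) {
    for (e in execlog) {
      if (any(trigger %in% c(e$added, e$removed))) {
        return(list(id = e$plan_id, actor = e$actor, plan_len = e$plan_len))
      }
    }
  }
  list(id = "event", actor = NA_character_, plan_len = NA_integer_)
}

delta_event <- function(type, id, importance, cause) {
  list(type = type, id = id, importance = importance, cause = cause)
}

# status changes of one agent's goals and values across a world transition
compute_delta <- function(ag, old_world, new_world, execlog) {
  events <- list()
  push <- function(e) events[[length(events) + 1L]] <<- e

  for (gid in names(ag$goals)) {
    g <- ag$goals[[gid]]
    if (g$status != "active") next
    if (g$origin == "value_restoration") {
      v <- ag$values[[g$value_id]]
      if (!condition_holds(v$violation, new_world)) {
        sc <- satisfied_conjunction(v$violation, old_world)
        trig <- intersect(sc, setdiff(old_world, new_world))
        push(delta_event("goal_achieved", gid, g$importance_of_success,
                         find_cause(trig, execlog)))
      }
      next
    }
    sc <- satisfied_conjunction(g$success, new_world)
    if (!is.null(sc)) {
      trig <- intersect(sc, setdiff(new_world, old_world))
      push(delta_event("goal_achieved", gid, g$importance_of_success,
                       find_cause(trig, execlog)))
    } else {
      fc <- satisfied_conjunction(g$failure, new_world)
      if (!is.null(fc)) {
        trig <- intersect(fc, setdiff(new_world, old_world))
        push(delta_event("goal_failed", gid, g$importance_of_failure,
                         find_cause(trig, execlog)))
      }
    }
  }

  for (vid in names(ag$values)) {
    v <- ag$values[[vid]]
    now <- condition_holds(v$violation, new_world)
    if (!v$at_stake && now) {
      sc <- satisfied_conjunction(v$violation, new_world)
      trig <- intersect(sc, setdiff(new_world, old_world))
      push(delta_event("value_violated", vid, v$priority, find_cause(trig, execlog)))
    } else if (v$at_stake && !now) {
      sc <- satisfied_conjunction(v$violation, old_world)
      trig <- intersect(sc, setdiff(old_world, new_world))
      push(delta_event("value_restored", vid, v$priority, find_cause(trig, execlog)))
    }
  }
  events
}

#' Appraise a set of status changes
#'
#' Maps goal/value status changes (a delta, as produced by the Monitoring
#' phase) to appraisal variables: goal achieved -> desirability, goal failed
#' -> undesirability, value put at stake -> blameworthiness, value restored
#' -> praiseworthiness. Responsibility is `self` when the causing action's
#' actor is the appraising agent, `other` when another agent acted, and
#' `none` (for the goal-based variables) when no intentional action caused
#' the change. Intensity is `importance * probability * effort_factor` with
#' the effort factor derived from the causing plan's length.
#'
#' @param delta List of status-change events, each
#'   `list(type, id, importance, cause = list(id, actor, plan_len))`; types
#'   are `goal_achieved`, `goal_failed`, `value_violated`, `value_restored`.
#' @param ag The appraising [agent()].
#' @param config An [affect_config()].
#' @param probability Probability factor (1 for realized outcomes; a plan's
#'   probability of success during anticipatory appraisal).
#' @return An [appraisal_vars()] data frame.
#' @export
appraise_outcome <- function(delta, ag, config = affect_config(),
                             probability = 1) {
  if (length(delta) == 0L) return(appraisal_vars())
  rows <- lapply(delta, function(ev) {
    f <- if (is.na(ev$cause$plan_len %||% NA)) 1 else
      effort_factor(ev$cause$plan_len, config$l_ref)
    inten <- emotion_intensity(ev$importance, probability, f)
    actor <- ev$cause$actor
    kind <- switch(ev$type,
      goal_achieved  = "desirability",
      goal_failed    = "undesirability",
      value_violated = "blameworthiness",
      value_restored = "praiseworthiness",
      stop("unknown delta event type: ", ev$type, call. = FALSE))
    moral <- kind %in% c("praiseworthiness", "blameworthiness")
    resp <- if (is.na(actor)) {
      if (moral) "other" else "none"
    } else if (identical(actor, ag$id)) "self" else "other"
    appraisal_vars(kind, inten, resp, ev$id, ev$cause$id)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Anticipatory appraisal and plan selection ------------------------------

resolve_goal_id <- function(p, ag) {
  gid <- p$goal_id
  if (startsWith(gid, "restore:")) gid <- paste0("restore_", sub("^restore:", "", gid))
  if (!gid %in% names(ag$goals)) {
    stop("plan ", p$id, " references unknown goal ", gid, " of agent ", ag$id,
         call. = FALSE)
  }
  gid
}

#' Anticipatory appraisal of a plan
#'
#' Simulates the plan's effects on a copy of the world, appraises the
#' resulting goal/value status changes, derives anticipatory emotions
#' (including hope/fear from a likelihood variable whose intensity is the
#' plan's probability of success), and combines everything into a utility:
#' `p * IoS - (1 - p) * IoF + w * EER`, where IoS/IoF are the importances of
#' the plan's goal and EER is the net expected emotional reward. A plan
#' whose steps are not applicable in sequence is evaluated with probability
#' treated as 0, and a warning is recorded on the evaluation.
#'
#' @param p A [plan()] of an active goal.
#' @param ag The deliberating [agent()].
#' @param world Current [world_state()].
#' @param config An [affect_config()].
#' @return A `plan_evaluation`: `plan_id`, `goal_id`, `anticipated`
#'   (emotions with `anticipatory = TRUE`), `eer`, `utility`, `probability`,
#'   `warnings`.
#' @export
anticipatory_appraisal <- function(p, ag, world, config = affect_config()) {
  gid <- resolve_goal_id(p, ag)
  g <- ag$goals[[gid]]
  w2 <- world
  applicable <- TRUE
  warnings <- character()
  added <- removed <- character()
  for (st in p$steps) {
    if (!all(st$preconditions %in% w2)) {
      applicable <- FALSE
      warnings <- c(warnings, paste0("step ", st$id, " inapplicable"))
      break
    }
    for (e in st$effects) {
      if (e$op == "add") { w2 <- world_add(w2, e$fact); added <- c(added, e$fact) }
      else { w2 <- suppressWarnings(world_del(w2, e$fact)); removed <- c(removed, e$fact) }
    }
  }
  prob <- if (applicable) p$probability_of_success else 0
  execlog <- list(list(plan_id = p$id, actor = p$steps[[1]]$actor,
                       plan_len = p$length, added = added, removed = removed))
  delta <- compute_delta(ag, world, w2, execlog)
  vars <- appraise_outcome(delta, ag, config, probability = prob)
  vars <- rbind(vars, appraisal_vars("likelihood", prob, "none", gid, p$id))
  emo <- derive_affect(vars, config, anticipatory = TRUE)
  e <- eer(emo)
  util <- prob * g$importance_of_success -
    (1 - prob) * g$importance_of_failure + config$w_eer * e
  structure(list(plan_id = p$id, goal_id = gid, anticipated = emo,
                 eer = e, utility = util, probability = prob,
                 warnings = warnings),
            class = "plan_evaluation")
}

#' Plan selection
#'
#' Commits to the evaluation with maximal utility; exact ties are broken by
#' lexicographic plan id, making deliberation fully deterministic.
#'
#' @param evaluations Non-empty list of `plan_evaluation`s.
#' @return The selected plan id.
#' @export
select_plan <- function(evaluations) {
  if (length(evaluations) == 0L) {
    stop("no plans to select from", call. = FALSE)
  }
  ids <- vapply(evaluations, `[[`, character(1), "plan_id")
  u <- vapply(evaluations, `[[`, numeric(1), "utility")
  best <- u == max(u)
  unname(sort(ids[best])[1])
}

# Execution + monitoring -------------------------------------------------

#' Execute a plan and monitor its effects
#'
#' Applies the chosen plan to the world under a scripted outcome: on
#' success, every step's effects are applied in order (a delete of a fact
#' not in the world is a no-op with a warning); on failure, the plan's
#' authored failure effects are applied instead. Goal and value statuses
#' are then updated against the new world; if a plan fails and its goal has
#' no other unexecuted plan in the library, the goal fails. Returns the new
#' world together with the status-change delta, ready for emotional
#' appraisal.
#'
#' @param ag The acting [agent()].
#' @param world Current [world_state()].
#' @param chosen A [plan()] from the agent's library.
#' @param outcome_success Logical, the scripted outcome.
#' @param config An [affect_config()].
#' @return List with elements `agent`, `world`, `delta`, `log`.
#' @export
execute_and_monitor <- function(ag, world, chosen, outcome_success = TRUE,
                                config = affect_config()) {
  old <- world
  added <- removed <- character()
  effects <- if (outcome_success) {
    do.call(c, lapply(chosen$steps, `[[`, "effects"))
  } else {
    chosen$failure_effects
  }
  for (e in effects %||% list()) {
    if (e$op == "add") { world <- world_add(world, e$fact); added <- c(added, e$fact) }
    else { world <- world_del(world, e$fact); removed <- c(removed, e$fact) }
  }
  execlog <- list(list(plan_id = chosen$id, actor = chosen$steps[[1]]$actor,
                       plan_len = chosen$length, added = added,
                       removed = removed))
  delta <- compute_delta(ag, old, world, execlog)

  gid <- resolve_goal_id(chosen, ag)
  if (!outcome_success && ag$goals[[gid]]$status == "active" &&
      !any(vapply(delta, function(ev)
        ev$type %in% c("goal_failed", "goal_achieved") && ev$id == gid,
        logical(1)))) {
    others <- Filter(function(p) !p$executed && p$id != chosen$id &&
                       resolve_goal_id(p, ag) == gid, ag$plans)
    if (length(others) == 0L) {
      delta[[length(delta) + 1L]] <- delta_event(
        "goal_failed", gid, ag$goals[[gid]]$importance_of_failure,
        list(id = chosen$id, actor = chosen$steps[[1]]$actor,
             plan_len = chosen$length))
    }
  }

  ag <- apply_delta_status(ag, delta, world)
  if (chosen$id %in% names(ag$plans)) ag$plans[[chosen$id]]$executed <- TRUE
  list(agent = ag, world = world, delta = delta, log = execlog)
}

apply_delta_status <- function(ag, delta, world) {
  for (ev in delta) {
    if (ev$type == "goal_achieved") ag$goals[[ev$id]] <- set_goal_status(ag$goals[[ev$id]], "achieved")
    if (ev$type == "goal_failed")   ag$goals[[ev$id]] <- set_goal_status(ag$goals[[ev$id]], "failed")
  }
  refresh_value_flags(ag, world)
}
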