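# The six-phase reasoning cycle, run over all characters of a scenario.

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

resolve_outcome <- function(script, plan, rng_state) {
  mode <- script$mode %||% "scripted"
  if (mode == "bernoulli") {
    return(stats::runif(1) < plan$probability_of_success)
  }
  out <- script$outcomes[[plan$id]] %||% "success"
  identical(out, "success")
}

#' Run the reasoning cycle over a scenario
#'
#' Executes, for up to `max_cycles` cycles, the six-phase schema — Value
#' Monitoring, Goal Formation, Emotional Anticipatory Appraisal, Execution,
#' Monitoring, Emotional Appraisal — for every character of the scenario
#' against a shared world. Outcomes of plan execution are scripted in the
#' scenario (deterministic by default); with `script$mode = "bernoulli"`
#' they are sampled with the plan's probability of success under `seed`.
#' The run terminates early once no character has an active goal.
#'
#' @param scenario A scenario as returned by [load_scenario()].
#' @param config An [affect_config()]; scenario-level overrides are applied
#'   on top of it.
#' @param max_cycles Maximum number of cycles (defaults to the scenario
#'   script's `max_cycles`, or 1).
#' @param seed Seed for sampled outcomes (ignored for scripted outcomes).
#' @return A `mea_trace` object: per-cycle phase records, final agents and
#'   world, the selected plan per character, and a termination status.
#' @export
run_scenario <- function(scenario, config = affect_config(), max_cycles = NULL,
                         seed = NULL) {
  config <- merge_config(config, scenario$config)
  script <- scenario$script %||% list()
  max_cycles <- max_cycles %||% script$max_cycles %||% 1L
  stopifnot(max_cycles >= 1)
  world <- scenario$world
  agents <- scenario$characters
  selected <- stats::setNames(vector("list", length(agents)), names(agents))
  cycles <- list()
  status <- "completed"

  with_local_seed(seed, {
    for (cy in seq_len(max_cycles)) {
      rec <- list()

      # 1. Value Monitoring
      vm <- list()
      for (aid in names(agents)) {
        agents[[aid]] <- refresh_value_flags(agents[[aid]], world)
        vm[[aid]] <- names(Filter(function(v) v$at_stake, agents[[aid]]$values))
      }
      rec$value_monitoring <- vm

      # 2. Goal Formation
      gf <- list()
      for (aid in names(agents)) {
        before <- names(active_goals(agents[[aid]]))
        agents[[aid]] <- form_goals(agents[[aid]], world)
        gf[[aid]] <- setdiff(names(active_goals(agents[[aid]])), before)
      }
      rec$goal_formation <- gf

      # 3. Emotional Anticipatory Appraisal (+ plan choice)
      aa <- list()
      chosen <- list()
      for (aid in names(agents)) {
        ag <- agents[[aid]]
        cand <- Filter(function(p) {
          !p$executed && {
            gid <- tryCatch(resolve_goal_id(p, ag), error = function(e) NA)
            !is.na(gid) && ag$goals[[gid]]$status == "active"
          }
        }, ag$plans)
        evals <- lapply(cand, anticipatory_appraisal, ag = ag, world = world,
                        config = config)
        pick <- if (length(evals)) select_plan(evals) else NULL
        aa[[aid]] <- list(evaluations = evals, chosen = pick)
        if (!is.null(pick)) {
          chosen[[aid]] <- ag$plans[[pick]]
          if (is.null(selected[[aid]])) selected[[aid]] <- pick
        }
      }
      rec$anticipatory_appraisal <- aa

      # 4. Execution (all acting characters, declaration order)
      old_world <- world
      execlog <- list()
      exec_rec <- list()
      for (aid in names(chosen)) {
        p <- chosen[[aid]]
        ok <- resolve_outcome(script, p)
        added <- removed <- character()
        effects <- if (ok) do.call(c, lapply(p$steps, `[[`, "effects")) else
          p$failure_effects
        for (e in effects %||% list()) {
          if (e$op == "add") {
            world <- world_add(world, e$fact); added <- c(added, e$fact)
          } else {
            world <- world_del(world, e$fact); removed <- c(removed, e$fact)
          }
        }
        execlog[[length(execlog) + 1L]] <-
          list(plan_id = p$id, actor = p$steps[[1]]$actor, plan_len = p$length,
               added = added, removed = removed)
        exec_rec[[length(exec_rec) + 1L]] <-
          list(agent = aid, plan = p$id, outcome = if (ok) "success" else "failure",
               added = added, removed = removed)
        agents[[aid]]$plans[[p$id]]$executed <- TRUE
      }
      rec$execution <- exec_rec

      # 5. Monitoring: per-agent status deltas over the shared transition
      deltas <- list()
      for (aid in names(agents)) {
        ag <- agents[[aid]]
        delta <- compute_delta(ag, old_world, world, execlog)
        if (aid %in% names(chosen)) {
          p <- chosen[[aid]]
          out_fail <- any(vapply(exec_rec, function(x)
            x$agent == aid && x$outcome == "failure", logical(1)))
          gid <- resolve_goal_id(p, ag)
          if (out_fail && ag$goals[[gid]]$status == "active" &&
              !any(vapply(delta, function(ev) ev$id == gid &&
                            ev$type %in% c("goal_achieved", "goal_failed"),
                          logical(1)))) {
            others <- Filter(function(q) !q$executed &&
                               resolve_goal_id(q, ag) == gid, ag$plans)
            if (length(others) == 0L) {
              delta[[length(delta) + 1L]] <- delta_event(
                "goal_failed", gid, ag$goals[[gid]]$importance_of_failure,
                list(id = p$id, actor = p$steps[[1]]$actor, plan_len = p$length))
            }
          }
        }
        deltas[[aid]] <- delta
        agents[[aid]] <- apply_delta_status(ag, delta, world)
      }
      rec$monitoring <- deltas

      # 6. Emotional Appraisal
      ea <- list()
      for (aid in names(agents)) {
        vars <- appraise_outcome(deltas[[aid]], agents[[aid]], config,
                                 probability = 1)
        emo <- derive_affect(vars, config, anticipatory = FALSE)
        agents[[aid]]$emotional_state <- emo
        ea[[aid]] <- emo
      }
      rec$emotional_appraisal <- ea

      cycles[[cy]] <- rec
      any_active <- any(vapply(agents, function(a)
        length(active_goals(a)) > 0L, logical(1)))
      if (!any_active) { status <- "completed"; break }
      if (cy == max_cycles) status <- "max_cycles_reached"
    }
  })

  structure(list(scenario_id = scenario$id %||% NA_character_,
                 cycles = cycles, agents = agents, world = world,
                 selected = selected, status = status),
            class = "mea_trace")
}

#' Run the reasoning cycle for a single agent
#'
#' Convenience wrapper around [run_scenario()] for a lone agent in a world.
#'
#' @param ag An [agent()].
#' @param world A [world_state()].
#' @param script Outcome script: `list(outcomes = list(<plan> = "success" |
#'   "failure"), mode = "scripted" | "bernoulli", max_cycles = ...)`.
#' @param max_cycles Maximum cycles (default 1).
#' @param config An [affect_config()].
#' @param seed Seed for `bernoulli` outcome sampling.
#' @return A `mea_trace`.
#' @export
run_cycle <- function(ag, world, script = list(), max_cycles = 1L,
                      config = affect_config(), seed = NULL) {
  scen <- list(id = paste0("adhoc_", ag$id),
               characters = stats::setNames(list(ag), ag$id),
               world = world, script = script, config = NULL)
  run_scenario(scen, config = config, max_cycles = max_cycles, seed = seed)
}

#' Final emotions of a character in a trace
#'
#' @param trace A `mea_trace`.
#' @param character_id Character id.
#' @return Sorted character vector of emotion types with intensity > 0 in
#'   the character's final Emotional Appraisal.
#' @export
final_emotions <- function(trace, character_id) {
  if (!character_id %in% names(trace$agents)) {
    stop("unknown character: ", character_id, call. = FALSE)
  }
  emo <- trace$agents[[character_id]]$emotional_state
  sort(unique(emo$type[emo$intensity > 0]))
}

#' @export
print.mea_trace <- function(x, ...) {
  cat("<trace ", x$scenario_id, ": ", length(x$cycles), " cycle(s), ",
      x$status, ">\n", sep = "")
  for (aid in names(x$agents)) {
    sel <- x$selected[[aid]]
    emo <- final_emotions(x, aid)
    cat("  ", aid, ": plan=", if (is.null(sel)) "-" else sel,
        " emotions={", paste(emo, collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

# line-delimited structured export: one JSON record per phase per cycle
#' Write a trace as line-delimited JSON
#'
#' One record per phase per cycle, plus a final summary record; a plain-text
#' log is written alongside when `log_path` is given.
#'
#' @param trace A `mea_trace`.
#' @param path Output path for the `.jsonl` records.
#' @param log_path Optional path for a human-readable log.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, log_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  phases <- c("value_monitoring", "goal_formation", "anticipatory_appraisal",
              "execution", "monitoring", "emotional_appraisal")
  for (cy in seq_along(trace$cycles)) {
    for (ph in phases) {
      rec <- list(cycle = cy, phase = ph, record = trace$cycles[[cy]][[ph]])
      writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                               digits = NA, force = TRUE)), con)
    }
  }
  summary_rec <- list(scenario = trace$scenario_id, status = trace$status,
                      selected = trace$selected,
                      emotions = lapply(stats::setNames(names(trace$agents),
                                                        names(trace$agents)),
                                        function(a) final_emotions(trace, a)))
  writeLines(as.character(jsonlite::toJSON(summary_rec, auto_unbox = TRUE,
                                           digits = NA, force = TRUE)), con)
  if (!is.null(log_path)) {
    txt <- utils::capture.output(print(trace))
    writeLines(txt, log_path)
  }
  invisible(path)
}
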