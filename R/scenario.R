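# Scenario files: YAML (or JSON) encodings of the narrative scenarios,
# with characters' goal/value structures, plan libraries, outcome script
# and the model's ground-truth predictions.

#' Packaged scenario files
#'
#' Seven scenarios ship with the package: three from the Actor Studio test
#' (`wallace`, `at_school`, `difficult_choice`) and four from the Audience
#' Studio test (`hamlet`, `montecristo`, `therese_raquin`, `bragelonne`).
#'
#' @param id Optional scenario id; when omitted all paths are returned.
#' @return Named character vector of file paths.
#' @export
scenario_files <- function(id = NULL) {
  dir <- system.file("extdata", "scenarios", package = "meagent")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  names(files) <- sub("\\.yaml$", "", basename(files))
  if (is.null(id)) return(files)
  if (!id %in% names(files)) stop("no packaged scenario '", id, "'", call. = FALSE)
  files[[id]]
}

scenario_error <- function(errors) {
  stop("scenario validation failed:\n  - ",
       paste(errors, collapse = "\n  - "), call. = FALSE)
}

as_effects <- function(x, where, errors) {
  out <- list()
  for (e in x %||% list()) {
    nm <- names(e)
    if (length(e) != 1L || !nm %in% c("add", "del")) {
      errors$push(paste0(where, ": effect must be a single add:/del: entry"))
      next
    }
    out[[length(out) + 1L]] <- list(op = nm, fact = as.character(e[[1]]))
  }
  out
}

#' Load and validate a scenario file
#'
#' Reads a YAML (or JSON) scenario definition, builds the character agents,
#' and validates the whole structure: declared predicates must cover every
#' proposition used, plan goal references must resolve (including
#' `restore:<value>` references to auto-generated restoration goals), actor
#' scenarios must give the protagonist exactly two plans and name a
#' predicted plan among them, and predicted emotion sets must be subsets of
#' the twelve-type answer set. All violations are reported together.
#'
#' @param path Path to the scenario file.
#' @return A `scenario` object: `id`, `study`, `world`, `characters` (named
#'   list of [agent()]s), `protagonist`, `script`, `config`, `predicted`.
#' @export
#' @examples
#' sc <- load_scenario(scenario_files("wallace"))
#' sc$predicted$plan
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path) else
    yaml::read_yaml(path)
  if (is.null(raw) || length(raw) == 0L) {
    scenario_error("empty scenario file")
  }
  errs <- new.env(); errs$list <- character()
  errs$push <- function(msg) errs$list <- c(errs$list, msg)

  for (f in c("id", "study", "characters", "world")) {
    if (is.null(raw[[f]])) errs$push(paste0("missing field '", f, "'"))
  }
  if (length(errs$list)) scenario_error(errs$list)
  if (!raw$study %in% c("actor", "audience")) {
    errs$push("study must be 'actor' or 'audience'")
  }

  world <- tryCatch(world_state(unlist(raw$world)),
                    error = function(e) { errs$push(paste0("world: ", conditionMessage(e))); world_state() })

  characters <- list()
  protagonist <- NULL
  char_ids <- vapply(raw$characters, function(ch) ch$id %||% "", character(1))
  for (ch in raw$characters) {
    cid <- ch$id %||% ""
    if (!nzchar(cid)) { errs$push("character without id"); next }
    goals <- lapply(ch$goals %||% list(), function(g) {
      tryCatch(
        goal(g$id, g$importance_of_success, g$importance_of_failure,
             adoption = g$adoption, success = g$success, failure = g$failure),
        error = function(e) {
          errs$push(paste0(cid, "/goal ", g$id %||% "?", ": ", conditionMessage(e)))
          NULL
        })
    })
    values <- lapply(ch$values %||% list(), function(v) {
      tryCatch(moral_value(v$id, v$priority, violation = v$violation),
               error = function(e) {
                 errs$push(paste0(cid, "/value ", v$id %||% "?", ": ",
                                  conditionMessage(e)))
                 NULL
               })
    })
    plans <- lapply(ch$plans %||% list(), function(p) {
      steps <- lapply(p$steps %||% list(), function(st) {
        tryCatch(
          action(st$id, st$actor %||% cid,
                 preconditions = unlist(st$preconditions) %||% character(),
                 effects = as_effects(st$effects,
                                      paste0(cid, "/plan ", p$id %||% "?"), errs)),
          error = function(e) {
            errs$push(paste0(cid, "/plan ", p$id %||% "?", "/step: ",
                             conditionMessage(e)))
            NULL
          })
      })
      if (any(vapply(steps, is.null, logical(1)))) return(NULL)
      tryCatch(plan(p$id, p$goal, steps, p$probability_of_success,
                    failure_effects = as_effects(p$failure_effects,
                                                 paste0(cid, "/plan ", p$id %||% "?"),
                                                 errs)),
               error = function(e) {
                 errs$push(paste0(cid, "/plan ", p$id %||% "?", ": ",
                                  conditionMessage(e)))
                 NULL
               })
    })
    if (length(errs$list) == 0L) {
      characters[[cid]] <- agent(cid, goals = goals, values = values,
                                 plans = plans)
      # plan goal references must resolve to a goal or restore:<value>
      for (p in plans) {
        gid <- p$goal_id
        if (startsWith(gid, "restore:")) {
          vid <- sub("^restore:", "", gid)
          if (!vid %in% names(characters[[cid]]$values)) {
            errs$push(paste0(cid, "/plan ", p$id,
                             ": restore target references unknown value ", vid))
          }
        } else if (!gid %in% names(characters[[cid]]$goals)) {
          errs$push(paste0(cid, "/plan ", p$id, ": unknown goal ", gid))
        }
        for (st in p$steps) {
          if (!st$actor %in% char_ids) {
            errs$push(paste0(cid, "/plan ", p$id, ": actor '", st$actor,
                             "' is not a declared character"))
          }
        }
      }
    }
    if (isTRUE(ch$protagonist)) protagonist <- cid
  }
  if (length(errs$list)) scenario_error(errs$list)

  # predicate coverage
  declared <- unlist(raw$predicates) %||% character()
  used <- character()
  used <- c(used, vapply(unclass(world), prop_name, character(1)))
  for (ag in characters) {
    for (g in ag$goals) used <- c(used, condition_predicates(c(g$adoption, g$success, g$failure)))
    for (v in ag$values) used <- c(used, condition_predicates(v$violation))
    for (p in ag$plans) {
      for (st in p$steps) {
        used <- c(used, vapply(st$preconditions, prop_name, character(1)),
                  vapply(st$effects, function(e) prop_name(e$fact), character(1)))
      }
      used <- c(used, vapply(p$failure_effects, function(e) prop_name(e$fact),
                             character(1)))
    }
  }
  if (length(declared)) {
    bad <- setdiff(unique(used), declared)
    if (length(bad)) {
      errs$push(paste0("undeclared predicate(s): ", paste(bad, collapse = ", ")))
    }
  }

  predicted <- raw$predicted %||% list()
  if (!is.null(predicted$emotions)) {
    for (cid in names(predicted$emotions)) {
      if (!cid %in% names(characters)) {
        errs$push(paste0("predicted emotions for unknown character ", cid))
        next
      }
      bad <- setdiff(unlist(predicted$emotions[[cid]]), emotion_types())
      if (length(bad)) {
        errs$push(paste0("predicted emotions for ", cid,
                         " outside answer set: ", paste(bad, collapse = ", ")))
      }
    }
  }

  if (raw$study == "actor") {
    if (is.null(protagonist)) {
      errs$push("actor scenario must mark a protagonist")
    } else {
      np <- length(characters[[protagonist]]$plans)
      if (np != 2L) {
        errs$push(paste0("actor scenario protagonist must have exactly 2 plans, has ", np))
      }
      if (is.null(predicted$plan)) {
        errs$push("actor scenario must name a predicted plan")
      } else if (!is.null(protagonist) &&
                 !predicted$plan %in% names(characters[[protagonist]]$plans)) {
        errs$push(paste0("predicted plan ", predicted$plan,
                         " is not in the protagonist's library"))
      }
    }
  }
  if (length(errs$list)) scenario_error(errs$list)

  structure(list(
    id = raw$id, study = raw$study, title = raw$title %||% raw$id,
    config = raw$config, world = world, characters = characters,
    protagonist = protagonist, script = raw$script %||% list(max_cycles = 1L),
    predicted = list(
      plan = predicted$plan,
      emotions = lapply(predicted$emotions %||% list(), function(x) sort(unlist(x))),
      provisional = unlist(predicted$provisional) %||% character()),
    predicates = declared
  ), class = "scenario")
}

# serialize back to the YAML schema (used for round-trip checks/authoring)
scenario_as_list <- function(sc) {
  cond_out <- function(conds) lapply(conds, function(cj)
    if (length(cj) == 1L) cj else as.list(cj))
  eff_out <- function(effects) lapply(effects, function(e)
    stats::setNames(list(e$fact), e$op))
  chars <- lapply(names(sc$characters), function(cid) {
    ag <- sc$characters[[cid]]
    out <- list(id = cid)
    if (identical(cid, sc$protagonist)) out$protagonist <- TRUE
    out$goals <- lapply(unname(ag$goals), function(g) {
      gl <- list(id = g$id,
                 importance_of_success = g$importance_of_success,
                 importance_of_failure = g$importance_of_failure)
      if (length(g$adoption)) gl$adoption <- cond_out(g$adoption)
      if (length(g$success)) gl$success <- cond_out(g$success)
      if (length(g$failure)) gl$failure <- cond_out(g$failure)
      gl
    })
    out$values <- lapply(unname(ag$values), function(v)
      list(id = v$id, priority = v$priority,
           violation = cond_out(v$violation)))
    out$plans <- lapply(unname(ag$plans), function(p) {
      pl <- list(id = p$id, goal = p$goal_id,
                 probability_of_success = p$probability_of_success,
                 steps = lapply(p$steps, function(st) {
                   s <- list(id = st$id, actor = st$actor)
                   if (length(st$preconditions)) s$preconditions <- as.list(st$preconditions)
                   s$effects <- eff_out(st$effects)
                   s
                 }))
      if (length(p$failure_effects)) pl$failure_effects <- eff_out(p$failure_effects)
      pl
    })
    out
  })
  out <- list(id = sc$id, study = sc$study, title = sc$title)
  if (!is.null(sc$config)) out$config <- sc$config
  if (length(sc$predicates)) out$predicates <- as.list(sc$predicates)
  out$world <- as.list(unclass(sc$world))
  out$characters <- chars
  out$script <- sc$script
  pred <- list()
  if (!is.null(sc$predicted$plan)) pred$plan <- sc$predicted$plan
  if (length(sc$predicted$emotions)) pred$emotions <-
    lapply(sc$predicted$emotions, as.list)
  if (length(sc$predicted$provisional)) pred$provisional <-
    as.list(sc$predicted$provisional)
  if (length(pred)) out$predicted <- pred
  out
}

#' @rdname load_scenario
#' @param sc A `scenario` object.
#' @export
write_scenario <- function(sc, path) {
  yaml::write_yaml(scenario_as_list(sc), path)
  invisible(path)
}

#' Behavior predicted by the agent model
#'
#' Runs the scenario and returns the plan the protagonist commits to. Only
#' meaningful for Actor Studio scenarios, where two alternative plans were
#' presented to respondents.
#'
#' @param sc A `scenario`.
#' @param config Optional [affect_config()] overrides.
#' @return The selected plan id.
#' @export
predicted_behavior <- function(sc, config = affect_config()) {
  if (!identical(sc$study, "actor")) {
    stop("predicted_behavior is defined for actor scenarios only", call. = FALSE)
  }
  tr <- run_scenario(sc, config = config)
  tr$selected[[sc$protagonist]]
}

#' Emotions predicted by the agent model
#'
#' Runs the scenario and returns the emotion types (any intensity > 0) in
#' the character's final Emotional Appraisal.
#'
#' @param sc A `scenario`.
#' @param character_id A character id from the scenario.
#' @param config Optional [affect_config()] overrides.
#' @return Sorted character vector of emotion types.
#' @export
predicted_emotions <- function(sc, character_id, config = affect_config()) {
  if (!character_id %in% names(sc$characters)) {
    stop("unknown character '", character_id, "' in scenario ", sc$id,
         call. = FALSE)
  }
  tr <- run_scenario(sc, config = config)
  final_emotions(tr, character_id)
}

#' Ground-truth predictions packaged with the scenarios
#'
#' The published prediction marks: the plan predicted for each Actor
#' scenario, the predicted emotion set of each Actor protagonist, and the
#' predicted emotion set of each Audience main character. Other-character
#' predictions for the Audience scenarios are included but flagged
#' provisional (the source table's layout is partly ambiguous); they are
#' not used as acceptance references.
#'
#' @return A list with components `actor_plans`, `actor_emotions`,
#'   `audience_main`, `audience_other_provisional`.
#' @export
ground_truth <- function() {
  list(
    actor_plans = list(
      wallace = "giving_key",
      at_school = "revenging",
      difficult_choice = "staying"),
    actor_emotions = list(
      wallace = "shame",
      at_school = sort(c("joy", "pride", "shame", "gratification")),
      difficult_choice = sort(c("distress", "joy", "shame", "remorse"))),
    audience_main = list(
      hamlet = sort(c("reproach", "anger", "distress")),
      montecristo = sort(c("joy", "gratification", "pride")),
      therese_raquin = sort(c("remorse", "distress", "shame")),
      bragelonne = "gratification"),
    audience_other_provisional = list(
      hamlet = "shame",
      montecristo = "distress",
      therese_raquin = sort(c("remorse", "distress", "shame")),
      bragelonne = "gratitude")
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario ", x$id, " (", x$study, "): ", length(x$characters),
      " character(s)>\n", sep = "")
  invisible(x)
}
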