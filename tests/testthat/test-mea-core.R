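# The agent core: value monitoring, goal formation, appraisal, affect
# derivation, deliberation and the six-phase cycle.

test_that("value monitoring flags exactly the violated values", {
  w <- world_state("stole(chocolate)")
  honesty <- moral_value("honesty", 0.9, violation = list("stole(chocolate)"))
  expect_equal(monitor_values(w, list(honesty)), "honesty")
  expect_equal(monitor_values(world_state(), list(honesty)), character(0))
  expect_error(
    monitor_values(w, list(honesty), declared = c("gave", "refused")),
    "undeclared predicate")
})

test_that("value monitoring agrees with a brute-force condition evaluator", {
  set.seed(42)
  for (i in 1:200) {
    inst <- random_world_and_values()
    got <- monitor_values(inst$world, inst$values)
    # oracle: loop over every conjunction and every fact explicitly
    expected <- character()
    for (v in inst$values) {
      hit <- FALSE
      for (cj in v$violation) {
        all_in <- TRUE
        for (f in cj) if (!f %in% unclass(inst$world)) all_in <- FALSE
        if (all_in) hit <- TRUE
      }
      if (hit) expected <- c(expected, v$id)
    }
    expect_equal(got, expected)
  }
})

test_that("goal formation adopts on adoption conditions and spawns restoration goals", {
  ag <- candy_agent()
  w <- candy_world()
  ag2 <- form_goals(meagent:::refresh_value_flags(ag, w), w)
  expect_equal(names(active_goals(ag2)), "eat_candy")

  # nothing holds -> nothing active
  ag3 <- form_goals(meagent:::refresh_value_flags(ag, world_state()), world_state())
  expect_length(active_goals(ag3), 0)

  # honesty at stake -> restoration goal inheriting the 0.9 priority
  w2 <- world_state(c("has(other,candy)", "stole(eva)"))
  ag4 <- candy_agent(honesty_priority = 0.9)
  ag4 <- form_goals(meagent:::refresh_value_flags(ag4, w2), w2)
  rg <- ag4$goals[["restore_honesty"]]
  expect_equal(rg$status, "active")
  expect_equal(rg$origin, "value_restoration")
  expect_equal(rg$importance_of_success, 0.9)
  expect_equal(rg$importance_of_failure, 0.9)

  # achieved goals are never re-activated
  ag5 <- agent("a", goals = list(goal("done", 0.5, 0.5,
                                      adoption = list("has(other,candy)"),
                                      status = "achieved")))
  expect_length(active_goals(form_goals(ag5, w)), 0)
})

test_that("goal status transitions are guarded", {
  g <- goal("g", 0.5, 0.5)
  expect_error(meagent:::set_goal_status(g, "achieved"), "illegal")
  g <- meagent:::set_goal_status(g, "active")
  expect_equal(meagent:::set_goal_status(g, "failed")$status, "failed")
})

test_that("emotion intensity is the guarded multiplicative product", {
  expect_equal(emotion_intensity(0, 0.7, 0.9), 0)
  expect_equal(emotion_intensity(1, 1, 1), 1)
  expect_error(emotion_intensity(1.2, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(emotion_intensity(0.5, -0.1, 0.5), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:50) {
    x <- runif(3); d <- sample(3, 1); bump <- runif(1, 0, 1 - x[d])
    y <- x; y[d] <- y[d] + bump
    expect_gte(emotion_intensity(y[1], y[2], y[3]),
               emotion_intensity(x[1], x[2], x[3]))
  }
})

test_that("appraisal maps status changes to the right variables", {
  ag <- candy_ready()
  cause <- list(id = "steal", actor = "eva", plan_len = 1L)
  d <- list(meagent:::delta_event("goal_achieved", "eat_candy", 0.8, cause),
            meagent:::delta_event("value_violated", "honesty", 0.95, cause))
  vars <- appraise_outcome(d, ag)
  expect_equal(vars$kind, c("desirability", "blameworthiness"))
  expect_equal(vars$responsibility, c("self", "self"))
  expect_equal(vars$intensity, c(0.8, 0.95) * effort_factor(1))

  other <- list(id = "spying", actor = "npc", plan_len = 1L)
  vb <- appraise_outcome(list(
    meagent:::delta_event("value_violated", "honesty", 0.5, other)), ag)
  expect_equal(vb$responsibility, "other")

  expect_equal(nrow(appraise_outcome(list(), ag)), 0)
})

test_that("affect derivation equals the enumerated rule-table oracle", {
  sigs_all <- c("desirability", "undesirability", "praiseworthiness.self",
                "praiseworthiness.other", "blameworthiness.self",
                "blameworthiness.other")
  mk_var <- function(sig, cause = "c1") {
    parts <- strsplit(sig, ".", fixed = TRUE)[[1]]
    appraisal_vars(parts[1], 0.5,
                   if (length(parts) == 2) parts[2] else "none", "src", cause)
  }
  for (coemit in c(TRUE, FALSE)) {
    cfg <- affect_config(coemit_compounds = coemit)
    for (mask in 0:(2^6 - 1)) {
      sigs <- sigs_all[bitwAnd(mask, 2^(0:5)) > 0]
      for (lik in list(NULL, 0.9, 0.5, 0.1)) {
        vars <- do.call(rbind, c(lapply(sigs, mk_var), list(
          if (!is.null(lik)) appraisal_vars("likelihood", lik, "none", "g", "c1"))))
        got <- derive_affect(vars, cfg)
        expect_equal(sort(unique(got$type)),
                     oracle_affect_types(sigs, lik, coemit),
                     info = paste(coemit, mask, lik %||% "-"))
      }
    }
  }
})

test_that("compound emotions need both components with a shared cause", {
  v1 <- appraisal_vars("undesirability", 0.4, "none", "g", "actA")
  v2 <- appraisal_vars("blameworthiness", 0.6, "other", "v", "actA")
  got <- derive_affect(rbind(v1, v2))
  anger <- got[got$type == "anger", ]
  expect_equal(nrow(anger), 1)
  expect_equal(anger$intensity, 0.5)          # mean of the two components
  expect_equal(anger$components, "undesirability+blameworthiness.other")
  # distinct causes: no compound
  v2b <- appraisal_vars("blameworthiness", 0.6, "other", "v", "actB")
  expect_false("anger" %in% derive_affect(rbind(v1, v2b))$type)
  expect_equal(nrow(derive_affect(appraisal_vars())), 0)
})

test_that("EER changes sign when all valences are flipped", {
  flip <- c(joy = "distress", distress = "joy", hope = "fear", fear = "hope",
            pride = "shame", shame = "pride", admiration = "reproach",
            reproach = "admiration", gratification = "remorse",
            remorse = "gratification", gratitude = "anger",
            anger = "gratitude")
  set.seed(11)
  for (i in 1:25) {
    types <- sample(emotion_types(), sample(1:6, 1))
    emo <- data.frame(type = types, intensity = runif(length(types)))
    flipped <- data.frame(type = unname(flip[emo$type]), intensity = emo$intensity)
    expect_equal(eer(flipped), -eer(emo))
  }
  expect_equal(eer(NULL), 0)
})

test_that("anticipatory appraisal ranks the candy plans by moral priority", {
  # honesty dear to the agent: the expected shame keeps her from stealing
  hi <- candy_ready(honesty_priority = 0.95)
  w <- candy_world()
  u_hi <- sapply(hi$plans, function(p) anticipatory_appraisal(p, hi, w)$utility)
  expect_gt(u_hi[["ask"]], u_hi[["steal"]])
  expect_equal(select_plan(lapply(hi$plans, anticipatory_appraisal,
                                  ag = hi, world = w)), "ask")

  # honesty negligible and stealing at least as likely: she steals
  lo <- candy_ready(honesty_priority = 0.1)
  u_lo <- sapply(lo$plans, function(p) anticipatory_appraisal(p, lo, w)$utility)
  expect_gt(u_lo[["steal"]], u_lo[["ask"]])

  # anticipated emotions are flagged anticipatory and include the shame
  ev <- anticipatory_appraisal(lo$plans[["steal"]], lo, w)
  expect_true(all(ev$anticipated$anticipatory))
  expect_true("shame" %in% ev$anticipated$type)
})

test_that("a plan with no consequences this cycle has utility p*IoS - (1-p)*IoF", {
  ag <- agent("a",
              goals = list(goal("far_goal", 0.8, 0.5,
                                adoption = list("start"),
                                success = list("finish"))),
              plans = list(plan("step1", "far_goal",
                                list(action("move", "a",
                                            preconditions = "start",
                                            effects = list(list(op = "add",
                                                                fact = "midway")))),
                                0.5)))   # mid likelihood: no hope, no fear
  w <- world_state("start")
  ag <- form_goals(ag, w)
  ev <- anticipatory_appraisal(ag$plans[[1]], ag, w)
  expect_equal(ev$eer, 0)
  expect_equal(ev$utility, 0.5 * 0.8 - 0.5 * 0.5)
})

test_that("inapplicable plans are evaluated with probability 0 and a warning record", {
  ag <- candy_ready()
  ev <- anticipatory_appraisal(ag$plans[["ask"]], ag, world_state())
  expect_equal(ev$probability, 0)
  expect_match(ev$warnings, "inapplicable")
})

test_that("plan selection is argmax with lexicographic tie-break", {
  mk <- function(id, u) structure(list(plan_id = id, utility = u),
                                  class = "plan_evaluation")
  expect_equal(select_plan(list(mk("p1", 0.4), mk("p2", 0.1))), "p1")
  expect_equal(select_plan(list(mk("b", 0.3), mk("a", 0.3))), "a")
  expect_error(select_plan(list()), "no plans")
  set.seed(3)
  for (i in 1:100) {
    ids <- replicate(sample(2:6, 1),
                     paste0(sample(letters, 4, TRUE), collapse = ""))
    u <- sample(seq(0, 1, 0.25), length(ids), TRUE)   # ties likely
    evs <- mapply(mk, ids, u, SIMPLIFY = FALSE)
    ord <- order(-u, ids)                              # brute-force oracle
    expect_equal(select_plan(evs), ids[ord][1])
  }
})

test_that("execution applies effects and monitoring updates statuses", {
  ag <- candy_ready(honesty_priority = 0.9)
  w <- candy_world()
  res <- execute_and_monitor(ag, w, ag$plans[["steal"]], TRUE)
  expect_true(all(c("has(eva,candy)", "stole(eva)") %in% res$world))
  expect_false("has(other,candy)" %in% res$world)
  expect_equal(res$agent$goals[["eat_candy"]]$status, "achieved")
  expect_true(res$agent$values[["honesty"]]$at_stake)
  types <- vapply(res$delta, `[[`, character(1), "type")
  expect_setequal(types, c("goal_achieved", "value_violated"))

  # a no-op plan leaves the world unchanged with an empty delta
  ag2 <- candy_ready()
  noop <- plan("wait", "eat_candy",
               list(action("idle", "eva")), 1.0)
  res2 <- execute_and_monitor(ag2, w, noop, TRUE)
  expect_equal(res2$world, w)
  expect_length(res2$delta, 0)

  # deleting a fact not in the world is a logged no-op
  bad <- plan("odd", "eat_candy",
              list(action("odd_step", "eva",
                          effects = list(list(op = "del", fact = "ghost")))), 1.0)
  expect_warning(execute_and_monitor(candy_ready(), w, bad, TRUE),
                 "not in world")
})

test_that("a scripted failure of the only plan fails its goal, appraised as undesirable", {
  ag <- candy_ready()
  ag$plans[["steal"]] <- NULL                 # asking is the only option
  w <- candy_world()
  res <- execute_and_monitor(ag, w, ag$plans[["ask"]], FALSE)
  expect_true("refused(other)" %in% res$world)
  expect_equal(res$agent$goals[["eat_candy"]]$status, "failed")
  vars <- appraise_outcome(res$delta, res$agent)
  expect_true("undesirability" %in% vars$kind)
  expect_true("distress" %in% derive_affect(vars)$type)
})

test_that("the cycle runs its six phases in order and is deterministic", {
  sc <- load_scenario(scenario_files("wallace"))
  tr1 <- run_scenario(sc)
  tr2 <- run_scenario(sc)
  expect_identical(tr1, tr2)
  expect_equal(names(tr1$cycles[[1]]),
               c("value_monitoring", "goal_formation", "anticipatory_appraisal",
                 "execution", "monitoring", "emotional_appraisal"))

  # steal-and-feel: shame mixed with the satisfaction of the achieved goal
  ag <- candy_ready(honesty_priority = 0.1)
  tr <- run_cycle(ag, candy_world(),
                  script = list(outcomes = list(steal = "success")))
  expect_equal(tr$selected[["eva"]], "steal")
  expect_true(all(c("joy", "shame") %in% final_emotions(tr, "eva")))

  # an agent with no goals: one cycle of empty phases
  idle <- agent("zoe")
  tr0 <- run_cycle(idle, world_state())
  expect_length(tr0$cycles, 1)
  expect_length(tr0$cycles[[1]]$execution, 0)
  expect_equal(final_emotions(tr0, "zoe"), character(0))
  expect_equal(tr0$status, "completed")

  # unresolved goals are cut by max_cycles with a status flag
  stuck <- agent("ada", goals = list(goal("g", 0.5, 0.5,
                                          adoption = list("start"))))
  trs <- run_cycle(stuck, world_state("start"), max_cycles = 3)
  expect_equal(trs$status, "max_cycles_reached")
  expect_length(trs$cycles, 3)
})

test_that("sampled outcomes are reproducible under a seed", {
  ag <- candy_ready(honesty_priority = 0.1, p_steal = 0.5, p_ask = 0.45)
  tr1 <- run_cycle(ag, candy_world(), script = list(mode = "bernoulli"),
                   seed = 99)
  tr2 <- run_cycle(ag, candy_world(), script = list(mode = "bernoulli"),
                   seed = 99)
  expect_identical(tr1, tr2)
})

test_that("raising a violated value's priority never raises the violating plan's utility", {
  w <- candy_world()
  grid <- seq(0.05, 1, by = 0.05)
  u <- vapply(grid, function(pr) {
    ag <- candy_ready(honesty_priority = pr)
    anticipatory_appraisal(ag$plans[["steal"]], ag, w)$utility
  }, numeric(1))
  expect_true(all(diff(u) <= 1e-12))
})

test_that("trace export is structured, line-delimited and byte-stable", {
  sc <- load_scenario(scenario_files("wallace"))
  tr <- run_scenario(sc)
  f1 <- tempfile(fileext = ".jsonl"); f2 <- tempfile(fileext = ".jsonl")
  write_trace(tr, f1)
  write_trace(tr, f2)
  expect_identical(readLines(f1), readLines(f2))
  recs <- lapply(readLines(f1), jsonlite::fromJSON)
  expect_equal(vapply(recs[1:6], `[[`, character(1), "phase"),
               c("value_monitoring", "goal_formation", "anticipatory_appraisal",
                 "execution", "monitoring", "emotional_appraisal"))
})
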