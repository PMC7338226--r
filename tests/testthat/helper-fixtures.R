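# Fixtures built in code: the candy dilemma (an agent who can ask for or
# steal a chocolate candy) and small random generators for property tests.

candy_agent <- function(honesty_priority = 0.95, ios = 0.8, iof = 0.6,
                        p_ask = 0.85, p_steal = 0.9) {
  agent(
    "eva",
    goals = list(goal("eat_candy", ios, iof,
                      adoption = list("has(other,candy)"),
                      success = list("has(eva,candy)"))),
    values = list(moral_value("honesty", honesty_priority,
                              violation = list("stole(eva)"))),
    plans = list(
      plan("ask", "eat_candy",
           list(action("ask_for_candy", "eva",
                       preconditions = "has(other,candy)",
                       effects = list(list(op = "add", fact = "has(eva,candy)"),
                                      list(op = "del", fact = "has(other,candy)")))),
           p_ask,
           failure_effects = list(list(op = "add", fact = "refused(other)"))),
      plan("steal", "eat_candy",
           list(action("steal_candy", "eva",
                       preconditions = "has(other,candy)",
                       effects = list(list(op = "add", fact = "has(eva,candy)"),
                                      list(op = "add", fact = "stole(eva)"),
                                      list(op = "del", fact = "has(other,candy)")))),
           p_steal)))
}

candy_world <- function() world_state("has(other,candy)")

# prepare the candy agent for deliberation (values monitored, goals formed)
candy_ready <- function(...) {
  ag <- candy_agent(...)
  w <- candy_world()
  ag <- meagent:::refresh_value_flags(ag, w)
  form_goals(ag, w)
}

random_world_and_values <- function(preds = paste0("p", 1:5),
                                    objs = c("a", "b")) {
  facts <- as.vector(outer(preds, objs, function(p, o) paste0(p, "(", o, ")")))
  w <- world_state(sample(facts, sample(0:6, 1)))
  vals <- lapply(seq_len(sample(1:4, 1)), function(i) {
    n_conj <- sample(1:2, 1)
    conds <- lapply(seq_len(n_conj), function(j)
      sample(facts, sample(1:2, 1)))
    moral_value(paste0("v", i), stats::runif(1, 0.05, 1), violation = conds)
  })
  list(world = w, values = vals)
}

# independent rule-table oracle for affect derivation (test-side twin)
oracle_affect_types <- function(sigs, likelihood = NULL, coemit = TRUE,
                                theta_hope = 0.7, theta_fear = 0.3) {
  simple <- c(desirability = "joy", undesirability = "distress",
              praiseworthiness.self = "pride",
              praiseworthiness.other = "admiration",
              blameworthiness.self = "shame",
              blameworthiness.other = "reproach")
  comp <- list(gratification = c("desirability", "praiseworthiness.self"),
               gratitude = c("desirability", "praiseworthiness.other"),
               remorse = c("undesirability", "blameworthiness.self"),
               anger = c("undesirability", "blameworthiness.other"))
  out <- character()
  fired_parts <- character()
  for (ct in names(comp)) {
    if (all(comp[[ct]] %in% sigs)) {
      out <- c(out, ct)
      fired_parts <- c(fired_parts, comp[[ct]])
    }
  }
  for (s in sigs) {
    if (!coemit && s %in% fired_parts) next
    out <- c(out, unname(simple[s]))
  }
  if (!is.null(likelihood)) {
    if (likelihood >= theta_hope) out <- c(out, "hope")
    else if (likelihood <= theta_fear) out <- c(out, "fear")
  }
  sort(unique(out))
}

load_all_scenarios <- function() {
  lapply(scenario_files(), load_scenario)
}
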