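test_that("the rushing fixture ends with the agent leaving the conversation", {
  run <- run_script(packaged(), example_script("rushing"))
  st <- is_terminated(run$session)
  expect_true(st$terminated)
  expect_identical(st$cause, "agent_goodbye")
  tr <- tidy(run$session)
  expect_identical(tr$text[nrow(tr)], "Bye!")
  expect_false(run$truncated)
})

test_that("a single greeting script gets one agent response and no termination", {
  run <- run_script(packaged(), bdi_script("hello-only", utter("Hi!")))
  tr <- tidy(run$session)
  expect_identical(sum(tr$speaker == "agent"), 1L)
  expect_false(is_terminated(run$session)$terminated)
})

test_that("the adherent fixture reaches the confidant desire and completes its actions", {
  run <- run_script(packaged(), example_script("adherent"))
  expect_identical(run$session$snapshot$intention, "D4")
  expect_true(all(c("A6", "A7", "A8") %in% run$session$snapshot$completed_actions))
  expect_identical(is_terminated(run$session)$cause, "trainee_goodbye")
})

test_that("scripts that outlive the session are truncated with a recorded warning", {
  sc <- packaged()
  extra <- bdi_script("over-long",
    utter("What do you wish would happen?"),
    utter("Have you told your teacher about the bullying?"),
    utter("No, we can't call your school."),   # agent says Bye! here
    utter("Wait, are you still there?"))
  run <- run_script(sc, extra)
  expect_true(run$truncated)
  expect_match(run$warnings, "truncated")
  # the report still exists and covers all beliefs
  expect_identical(nrow(run$report$beliefs), 17L)
})

test_that("the average end belief is the mean of the final belief values", {
  sc <- load_toy()
  run <- run_script(sc, bdi_script("noop", wait(1)))
  expect_identical(average_end_belief(run), 0.5)  # all beliefs still at 0.5

  run_rush <- run_script(packaged(), example_script("rushing"))
  # oracle: reconstructed start values plus the published net changes
  start <- c(0.5, 0.5, 0.5, 0.4, 0.4, 0.5, 0.5, 0.5, 0.5, 0.5,
             0.5, 0.0, 0.5, 0.5, 0.5, 0.0, 0.5)
  delta <- c(0, 0, 0, 0.1, 0.1, 0, -0.1, -0.2, 0, 0, 0, 1, 0, 0, 0, 1, 0)
  expect_equal(average_end_belief(run_rush), mean(start + delta))
})

test_that("an adherent conversation outscores a rushing one", {
  sc <- packaged()
  m_adh <- average_end_belief(run_script(sc, example_script("adherent")))
  m_rush <- average_end_belief(run_script(sc, example_script("rushing")))
  expect_true(m_adh > m_rush)
})

test_that("batch runs give one deterministic row per script", {
  sc <- packaged()
  tab <- batch_run(sc, list(example_script("rushing"), example_script("adherent")))
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$script, c("rushing", "adherent"))
  expect_identical(sort(unique(tab$cause)), c("agent_goodbye", "trainee_goodbye"))
  expect_true(all(sprintf("delta_B%02d", 1:17) %in% names(tab)))
  expect_equal(tab$mean_end_belief_0_10, 10 * tab$mean_end_belief)

  twice <- batch_run(sc, list(example_script("rushing"), example_script("rushing")))
  expect_identical(twice[1, ], twice[2, ])
  # the summary is CSV-serialisable
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  expect_identical(nrow(utils::read.csv(path)), 2L)
})

test_that("replaying the same script twice is bit-identical", {
  sc <- packaged()
  r1 <- run_script(sc, example_script("rushing"))
  r2 <- run_script(sc, example_script("rushing"))
  expect_identical(tidy(r1$session), tidy(r2$session))
  expect_identical(r1$session$snapshot, r2$session$snapshot)
  expect_identical(render_report(r1$report, "json"),
                   render_report(r2$report, "json"))
})

test_that("an extra bare rejection never improves the ability beliefs", {
  sc <- packaged()
  base <- example_script("rushing")
  ev <- base$events
  set.seed(11)
  for (i in 1:10) {
    pos <- sample(seq_along(ev), 1)
    ev2 <- append(ev, list(utter("We cannot do that.")), after = pos - 1)
    run0 <- run_script(sc, base)
    run1 <- run_script(sc, do.call(bdi_script, c(list("with-reject"), ev2)))
    expect_true(run1$session$snapshot$beliefs[["B07"]] <=
                  run0$session$snapshot$beliefs[["B07"]] + 1e-12)
    expect_true(run1$session$snapshot$beliefs[["B08"]] <=
                  run0$session$snapshot$beliefs[["B08"]] + 1e-12)
  }
})

test_that("script files and constructors reject malformed input", {
  expect_error(bdi_script("empty"), class = "bdichat_config_error")
  expect_error(wait(-1), class = "bdichat_config_error")
  expect_error(bdi_script("bad", "not an event"), class = "bdichat_config_error")
  sc_path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "s", events = list(list(jump = 3))), sc_path)
  expect_error(read_script(sc_path), class = "bdichat_config_error")
})

test_that("any short script terminates or runs out of things to say", {
  # liveness at desk scale: random 30-turn scripts never loop the agent
  sc <- packaged()
  phrases <- c("Hi!", "That sounds really difficult for you.",
               "What do you wish would happen?", "We cannot do that.",
               "Have you told your teacher about the bullying?",
               "Are you safe right now?", "zzz unknown zzz")
  set.seed(99)
  for (i in 1:10) {
    ev <- purrr::map(sample(phrases, 30, replace = TRUE), utter)
    run <- run_script(sc, do.call(bdi_script, c(list("rand"), ev)))
    tr <- tidy(run$session)
    n_actions <- length(run$session$snapshot$completed_actions)
    st <- is_terminated(run$session)
    # either the session ended, or every response past the action budget
    # is a fallback (no action is ever re-emitted)
    expect_true(st$terminated || n_actions <= nrow(sc$actions))
    agent_texts <- tr$text[tr$speaker == "agent"]
    action_texts <- vapply(sc$actions$templates, `[`, character(1), 1)
    expect_true(all(table(agent_texts[agent_texts %in% action_texts]) <= 1))
  }
})
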