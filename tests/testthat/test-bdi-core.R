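test_that("clamp_unit pins values to the unit interval and rejects non-finite input", {
  expect_identical(clamp_unit(1.2), 1)
  expect_identical(clamp_unit(-0.1), 0)
  expect_identical(clamp_unit(0.5), 0.5)
  expect_identical(clamp_unit(c(-3, 0, 1, 7)), c(0, 0, 1, 1))
  expect_error(clamp_unit(NaN), class = "bdichat_invalid_value")
  expect_error(clamp_unit(Inf), class = "bdichat_invalid_value")
})

test_that("a greeting raises only the trust-in-trainee belief from the start state", {
  sc <- packaged()
  snap <- new_snapshot(sc)
  out <- apply_intent(snap, "greeting", sc$rules)
  expect_equal(out$beliefs[["B04"]], snap$beliefs[["B04"]] + 0.1)
  expect_equal(out$beliefs[setdiff(names(out$beliefs), "B04")],
               snap$beliefs[setdiff(names(snap$beliefs), "B04")])
})

test_that("the fallback label and unknown intents leave the snapshot unchanged", {
  sc <- packaged()
  snap <- new_snapshot(sc)
  expect_identical(apply_intent(snap, "unrecognized", sc$rules), snap)
  expect_identical(apply_intent(snap, "no_such_intent", sc$rules), snap)
})

test_that("repeated empathy clamps the understanding belief at 1", {
  sc <- packaged()
  snap <- snapshot_with(sc, B05 = 0.95)
  once <- apply_intent(snap, "show_empathy", sc$rules)
  expect_equal(once$beliefs[["B05"]], 1)
  twice <- apply_intent(once, "show_empathy", sc$rules)
  expect_equal(twice$beliefs[["B05"]], 1)
})

test_that("guarded rules fire only while their guard holds", {
  sc <- load_toy(function(raw) {
    raw$rules[[1]]$guard <- list(belief = "b1", op = "<=", value = 0.6)
    raw
  })
  snap <- new_snapshot(sc)
  s1 <- apply_intent(snap, "greeting", sc$rules)   # 0.5 -> 0.6, guard held
  expect_equal(s1$beliefs[["b1"]], 0.6)
  s2 <- apply_intent(s1, "greeting", sc$rules)     # guard still holds at 0.6
  expect_equal(s2$beliefs[["b1"]], 0.7)
  s3 <- apply_intent(s2, "greeting", sc$rules)     # guard now fails
  expect_equal(s3$beliefs[["b1"]], 0.7)
})

test_that("desire activation follows the worked conversation's waypoints", {
  sc <- packaged()
  snap <- new_snapshot(sc)
  expect_identical(evaluate_desires(snap, sc$desires), "D1")
  # asking about the wish drives B12 to 1 and activates the wish desire
  wish <- apply_intent(snap, "ask_wish", sc$rules)
  expect_true("D3" %in% evaluate_desires(wish, sc$desires))
  # losing faith in the trainee's ability activates the end-conversation desire
  low <- snapshot_with(sc, B07 = 0.4, B08 = 0.3)
  expect_true("D2" %in% evaluate_desires(low, sc$desires))
  low2 <- snapshot_with(sc, B05 = 0.2, B06 = 0.3)
  expect_true("D2" %in% evaluate_desires(low2, sc$desires))
})

test_that("the intention is the highest-priority active desire, deterministically", {
  sc <- packaged()
  expect_identical(select_intention("D1", sc$desires), "D1")
  expect_identical(select_intention(c("D1", "D3"), sc$desires), "D3")
  expect_identical(select_intention(c("D2", "D3"), sc$desires), "D2")
  expect_identical(select_intention(c("D1", "D2", "D3", "D4", "D5"), sc$desires), "D2")
  # repeated calls agree regardless of input order
  for (i in 1:20) {
    act <- sample(sc$desires$id, 3)
    expect_identical(select_intention(act, sc$desires),
                     select_intention(rev(act), sc$desires))
  }
  expect_error(select_intention(character(0), sc$desires),
               class = "bdichat_empty_intention")
})

test_that("actions are worked through in order and exhaust to the NA sentinel", {
  sc <- packaged()
  snap <- new_snapshot(sc)
  expect_identical(next_action(snap, "D1", sc$actions), "A1")
  snap$completed_actions <- "A1"
  expect_identical(next_action(snap, "D1", sc$actions), "A2")
  snap$completed_actions <- "A4"
  expect_identical(next_action(snap, "D2", sc$actions), NA_character_)
})

test_that("executing an action returns its template, completes it, and flags termination", {
  sc <- packaged()
  snap <- new_snapshot(sc)
  res <- execute_action(snap, "A4", sc)
  expect_identical(res$response, "Bye!")
  expect_true(res$terminal)
  expect_true("A4" %in% res$snapshot$completed_actions)

  res1 <- execute_action(snap, "A1", sc)
  expect_false(res1$terminal)
  expect_true("A1" %in% res1$snapshot$completed_actions)
  expect_match(res1$response, "bullied")
  # repeats are disabled in the packaged scenario
  expect_error(execute_action(res1$snapshot, "A1", sc),
               class = "bdichat_action_repeat")
  expect_error(execute_action(snap, "A99", sc), class = "bdichat_config_error")
})

test_that("completed actions are never lost across the reasoning cycle", {
  sc <- packaged()
  session <- new_session(sc)
  seen <- character(0)
  for (txt in c("Hi!", "That sounds really difficult for you.",
                "What do you wish would happen?", "blah blah")) {
    handle_turn(session, txt)
    expect_true(all(seen %in% session$snapshot$completed_actions))
    seen <- session$snapshot$completed_actions
  }
})

test_that("belief values stay inside [0, 1] under random intent sequences", {
  sc <- packaged()
  labels <- intent_taxonomy()
  set.seed(42)
  for (i in 1:300) {
    snap <- new_snapshot(sc)
    for (intent in sample(labels, 12, replace = TRUE)) {
      snap <- apply_intent(snap, intent, sc$rules)
    }
    expect_true(all(snap$beliefs >= 0 & snap$beliefs <= 1))
  }
})

test_that("desire evaluation agrees with a brute-force condition check on a 0.1 grid", {
  sc <- load_toy()
  grid <- seq(0, 1, by = 0.1)
  for (v1 in grid) for (v2 in grid) for (v3 in grid) {
    snap <- new_snapshot(sc)
    snap$beliefs <- c(b1 = v1, b2 = v2, b3 = v3)
    got <- evaluate_desires(snap, sc$desires)
    # independent oracle: the condition written out directly
    expected <- if ((v1 >= 0.6 && v2 <= 0.3) || v3 >= 0.9) "DX" else "DD"
    expect_identical(got, expected)
  }
})
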