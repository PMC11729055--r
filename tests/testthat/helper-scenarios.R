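# Toy scenarios built programmatically (written to a tempfile and loaded
# through the public reader, so every test also exercises the file path).

toy_scenario_list <- function() {
  list(
    name = "toy",
    idle_threshold_seconds = 10,
    fallback = list(no_understanding = "??", farewell = "bye then"),
    lexicon = list(
      case_insensitive = TRUE,
      patterns = list(
        list(pattern = "hello", intent = "greeting"),
        list(pattern = "poor you", intent = "show_empathy"),
        list(pattern = "wish", intent = "ask_wish"),
        list(pattern = "bye", intent = "goodbye"))),
    beliefs = list(
      list(id = "b1", description = "first", phase = "2", group = "G",
           initial = 0.5, desirable = 1),
      list(id = "b2", description = "second", phase = "3", group = "G",
           initial = 0.5, desirable = 1),
      list(id = "b3", description = "third", phase = "All", group = "G",
           initial = 0.5, desirable = -1)),
    desires = list(
      list(id = "DD", description = "default goal", phase = "2",
           priority = 2, default = TRUE),
      list(id = "DX", description = "conditional goal", phase = "3",
           priority = 1,
           condition = list(any = list(
             list(all = list(
               list(belief = "b1", op = ">=", value = 0.6),
               list(belief = "b2", op = "<=", value = 0.3))),
             list(belief = "b3", op = ">=", value = 0.9))))),
    actions = list(
      list(id = "a1", desire = "DD", name = "first move",
           templates = list("dd says one")),
      list(id = "a2", desire = "DD", name = "second move",
           templates = list("dd says two")),
      list(id = "ax", desire = "DX", name = "x move",
           templates = list("dx says hi"))),
    rules = list(
      list(intent = "greeting",
           effects = list(list(belief = "b1", delta = 0.1))),
      list(intent = "show_empathy",
           effects = list(list(belief = "b2", delta = -0.1))),
      list(intent = "ask_wish",
           effects = list(list(belief = "b3", delta = 0.1)))))
}

# write a scenario list to a temp YAML and load it
load_toy <- function(edit = identity) {
  raw <- edit(toy_scenario_list())
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  yaml::write_yaml(raw, path)
  read_scenario(path)
}

# same, but return the raw validation outcome (errors expected)
expect_toy_error <- function(edit, pattern) {
  raw <- edit(toy_scenario_list())
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  yaml::write_yaml(raw, path)
  expect_error(read_scenario(path), pattern, class = "bdichat_config_error")
}

# a snapshot of the packaged scenario with chosen belief overrides
snapshot_with <- function(scenario, ...) {
  snap <- new_snapshot(scenario)
  over <- c(...)
  snap$beliefs[names(over)] <- over
  snap
}

packaged <- local({
  sc <- NULL
  function() {
    if (is.null(sc)) sc <<- example_scenario()
    sc
  }
})
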