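Package: bdichat
Title: Belief-Desire-Intention Conversational Agent for Counselling Practice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a bullied child contacting a helpline chat so that
    counsellor trainees can practise the Five Phase Model of helpline
    counselling. The simulated child is a belief-desire-intention (BDI)
    agent: seventeen unit-interval beliefs are shifted by rules triggered
    by the trainee's recognised intents, threshold conditions over the
    beliefs activate conversational desires, and the highest-priority
    active desire selects the agent's next scripted action. Includes a
    deterministic keyword intent recogniser behind a pluggable contract,
    a scenario file format with validation, idle self-initiation on a
    logical clock, post-session feedback reports of belief changes, and a
    replay harness for scripted trainee conversations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
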