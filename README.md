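# bdichat

A belief–desire–intention (BDI) conversational agent that simulates a
bullied child contacting a helpline chat, so that counsellor trainees can
practise the **Five Phase Model** of helpline counselling — (1) build
rapport, (2) clarify the child's story, (3) set the session goal, (4) work
toward the goal, (5) round off — and receive feedback on how their
conversational choices moved the child's beliefs.

## The model

The simulated child holds 17 graded beliefs $B_{01},\dots,B_{17}$, each a
value on $[0,1]$ (weak to strong): statements about itself ("thinks it is
in control"), about the trainee ("thinks the trainee can be trusted",
"...understands it", "...can solve its problem"), about the conversation
("thinks the trainee is asking about its wish"), and about a confidant in
its own network ("thinks its teacher can help it").

Each trainee message is classified into a single intent from a closed
taxonomy (greeting, show_empathy, ask_wish, ask_confidant,
reject_request_without_alternative, ...). Rules map intents to signed
belief updates,

$$ B_i \leftarrow \mathrm{clip}_{[0,1]}\!\left(B_i + \delta_{i,\text{intent}}\right), $$

optionally gated by a guard condition. Threshold conditions over the
beliefs activate **desires** — conversational goals such as "wants to talk
about its problem" (the default, $D_1$) or "wants to end the conversation"
($D_2$, activated when the child loses faith in the trainee, e.g.
$B_{07} \le 0.4 \wedge B_{08} \le 0.3$). The active desire with the best
priority rank becomes the **intention**, and the agent replies with the
intention's next incomplete **action** from an ordered list (introduce the
problem, give details, describe the emotional impact, ..., say "Bye!").
If the trainee is silent for 10 seconds the agent self-initiates with the
same next-action rule. After the session, a feedback report lists every
belief's start value, end value, and delta, annotated with the Five Phase
Model phase it informs: positive deltas (for all beliefs except "the
trainee wants to end the conversation") mean the child ended the session
in a better place.

Everything is deterministic and configuration-driven: the scenario file
holds the beliefs, desires, actions, rules, thresholds, and response
templates; the engine is generic.

## Worked example

The packaged `rushing` fixture replays a trainee who greets, empathises
once, then jumps straight to the child's wish and rejects its request
("can you call my school?") without offering an alternative:

```r
library(bdichat)
scenario <- example_scenario()
run <- run_script(scenario, example_script("rushing"))
glance(run)
#> # A tibble: 1 × 7
#>   script  trainee_turns terminated cause         mean_end_belief mean_end_belief_0_10 truncated
#>   <chr>           <int> <lgl>      <chr>                   <dbl>                <dbl> <lgl>
#> 1 rushing             5 TRUE       agent_goodbye           0.541                 5.41 FALSE
```

The child loses faith in the trainee's ability to help and ends the
conversation itself (`agent_goodbye`, the agent's last message is
"Bye!"). The feedback report shows which beliefs moved:

```r
dplyr::filter(tidy(run$report), delta != 0)
#> # A tibble: 6 × 8
#>   id    description                                    phase
#>   <chr> <chr>                                          <chr>
#> 1 B04   Thinks the trainee can be trusted              2
#> 2 B05   Thinks the trainee understands it              All
#> 3 B07   Thinks the trainee can help it                 3
#> 4 B08   Thinks the trainee can solve its problem       3
#> 5 B12   Thinks the trainee is asking about its wish    3
#> 6 B16   Thinks the trainee is asking about a confidant 4
#>   group                            start_value end_value delta desirability_sign
#>   <chr>                                  <dbl>     <dbl> <dbl>             <dbl>
#> 1 About the child helpline trainee         0.4       0.5   0.1               0.1
#> 2 About the child helpline trainee         0.4       0.5   0.1               0.1
#> 3 About the child helpline trainee         0.5       0.4  -0.1              -0.1
#> 4 About the child helpline trainee         0.5       0.3  -0.2              -0.2
#> 5 About conversation                       0         1     1                 1
#> 6 About confidant                          0         1     1                 1
```

Trust and understanding rose a little (+0.1 each), the wish and confidant
questions were registered (+1), but the bare rejection cost the child its
belief that the trainee can help (−0.1) and solve the problem (−0.2). The
adherent fixture — same scenario, a trainee who follows the Five Phase
Model — scores a higher conversational outcome (mean end belief 0.606 vs
0.541) and ends with the trainee's goodbye:

```r
batch_run(scenario, list(example_script("rushing"), example_script("adherent")))
```

`autoplot(run$report)` draws the per-belief deltas;
`plot_belief_trajectory(run)` shows each belief across turns. An
interactive chat and the scenario utilities are also available from a
shell via the bundled front end:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","bdichat.R",package="bdichat"))')" chat
```

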