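---
title: "A BDI child-helpline training simulator: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A BDI child-helpline training simulator: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdichat)
```

## The model

bdichat simulates a bullied, gender-neutral child contacting a helpline
chat, so counsellor trainees can practise the Five Phase Model (rapport,
story, session goal, goal work, round off). The child is a
belief–desire–intention agent:

* **Beliefs** are 17 parameters on the unit interval, weak (0) to strong
  (1). They encode the child's stance toward itself, the trainee, the
  conversation, and a possible confidant. Every trainee message is
  classified to one intent label, and rules add signed deltas to beliefs,
  clamped into $[0,1]$ by `clamp_unit()`.
* **Desires** are conversational goals with activation conditions —
  boolean trees of threshold comparisons over beliefs. A desire with no
  true condition leaves the default desire (talk about the problem)
  active, so the agent always wants something.
* The **intention** is the active desire with the best priority rank;
  ranks are unique, so selection is total and deterministic.
* **Actions** form an ordered list per desire, each with a completion
  flag. The agent replies with the intention's next incomplete action;
  executing an action of the terminal desire ("wants to end the
  conversation") closes the session from the agent's side.
* If the trainee is silent for the idle threshold, the agent
  self-initiates with the same next-action rule, at most once per
  silence window.

The reasoning cycle for a turn is
`classify() → apply_intent() → evaluate_desires() → select_intention() →
next_action() → execute_action()`. The whole engine is free of
randomness; with the scripted clock, a replay of the same script is
bit-identical every time.

## Parameters and their defaults

All behavioural parameters live in the scenario file
(`inst/extdata/bullying.yaml`), not in code.

**Initial belief values.** The published account of this scenario prints
per-belief *net changes* for a worked conversation, but not the starting
values themselves. The packaged values are the reconstruction those
changes force or suggest: B12 and B16 start at 0 (a net change of +1 on a
unit interval pins them to $0 \to 1$); B04 and B05 start at 0.4 so the
+0.1 greeting and empathy updates never clamp; all other beliefs start at
0.5, the neutral midpoint.

**Rule magnitudes** (per firing, in belief units): greeting → B04 +0.1;
empathy → B05 +0.1; asking about the wish → B12 +1; asking about a
confidant → B16 +1; rejecting the child's request without an alternative
→ B07 −0.1 and B08 −0.2. These reproduce the published net changes
exactly when each rule fires once in the rushing replay. The remaining
rules (problem details, feelings, summarising, suggesting alternatives,
safety check, goodbye) use ±0.1 steps — small enough that several turns
are needed to cross any threshold, which matches how gradually trust
builds in a real conversation.

**Desire thresholds.** Also unpublished; the packaged values are chosen
once to reproduce the worked trajectory. The wish desire D3 activates at
B12 ≥ 0.9, the confidant desire D4 at B16 ≥ 0.9 and B17 ≥ 0.5, the
joint-solution desire D5 at B09 ≥ 0.7. The end-conversation desire D2
activates when the child feels misunderstood (B05 ≤ 0.2 and B06 ≤ 0.3),
*or* doubts the trainee's ability (B07 ≤ 0.4 and B08 ≤ 0.3), *or*
believes the trainee wants to leave (B15 ≥ 0.9). The ability disjunct is
deliberately set at (0.4, 0.3) rather than a symmetric (0.3, 0.3): with
the calibrated rejection rule (B07 −0.1, B08 −0.2 from 0.5), a single
bare rejection after an unmet request is exactly the event that should
tip the child over, and (0.4, 0.3) is the state that event produces. A
0.3 threshold on B07 would require two rejections and would contradict
the published single-rejection net change of −0.1.

**The rushing mechanism.** The narrated version of the failed
conversation says that rushing the story phase lowers the child's sense
of being understood (B05, B06), yet the same source's feedback table
prints net changes of +0.1 for B05 and 0 for B06. The two cannot both
hold for a single replay, and we treat the table as authoritative: the
packaged scenario drives the end-conversation desire through the doubt
route (B07/B08, which the table *does* show falling) rather than through
a B05/B06 decay rule. The misunderstood disjunct of D2 is retained in
the condition so trainers who add penalty rules for phase-skipping get
the original mechanism without touching code.

**Priority ranks.** "Most prominent" is not formalised in the source;
the packaged order is fixed ranks D2 > D4 > D5 > D3 > D1, so that ending
the conversation dominates everything, the confidant goal dominates the
child's own (unfulfillable) wish, and the default desire is last.
Configurable per scenario.

**Idle threshold.** 10 seconds, per the original system's self-initiation
rule; a scenario parameter. One idle message per silence window
(`multi_idle: false`), because the narrated conversation shows idle lines
separated by trainee turns, never back to back.

**Desirability direction.** The feedback report multiplies each delta by
a per-belief direction flag; +1 for every belief except "thinks the
trainee wants to end the conversation" (B15), whose increase is
undesirable from the helpline's perspective. Reports print raw deltas
(the published feedback table is consistent with raw values for the
falling beliefs); the signed column is additional.

## The intent recogniser

The original system classified trainee messages with a trained NLU
model that is not available. bdichat ships a deterministic first-match
keyword recogniser: ordered whole-word patterns, case-insensitive,
first match wins, `unrecognized` for everything else. The taxonomy is
closed (14 labels) and every rule trigger is checked against it at load
time. The contract is one function, `classify(text, lexicon) → label`,
so a statistical recogniser can be substituted without touching the
engine; the test suite includes a stub-recogniser substitution check.

Deliberate consequences of this design: a single label per utterance (no
multi-intent fusion, mirroring the original's limitation), no confidence
scores, no segmentation of multi-part messages, and brittle recall — an
empathic message phrased outside the lexicon falls back to
"I don't understand" with no belief change. Penalising beliefs on
recogniser failure would conflate recognition errors with trainee
mistakes, so unrecognised input is belief-neutral.

## The scripted fixtures

Two scripts stand in for human trainees. `rushing` reconstructs the
narrated failed conversation: greeting, one idle self-initiation, one
empathic turn, a second (silent) pause, then straight to the wish
question, a confidant question, and a bare rejection; the agent answers
the rejection with "Bye!". The confidant turn is included although the
narrative omits it, because the published feedback table shows B16
rising by 1, which only that intent produces; it is placed before the
rejection because the rejection activates the terminal desire and must
come last. `adherent` works through the phases in order and ends with
the trainee's goodbye.

The fixtures emulate *turn structure and timing*, not language
variation: they use phrases the packaged lexicon recognises by
construction. Passing replays therefore validate the engine's dynamics —
belief arithmetic, threshold logic, action ordering, idle behaviour,
termination — and say nothing about recognition robustness on free text,
or about how human trainees would behave.

The conversational-outcome summary is the mean of the 17 final belief
values, on $[0,1]$. The original evaluation reports session outcomes
around 6.4–6.7 on an unstated scale that is not derivable from 17 unit
interval beliefs; batch summaries therefore emit both the raw mean and a
×10 rescaling (`mean_end_belief_0_10`) and leave the correspondence
open.

## Numerical and degenerate-case choices

* Rule effects apply in file order, each clamped immediately; for
  multiple effects on one belief, the last write wins before clamping.
* `next_action()` returns `NA_character_` when an intention's actions
  are exhausted; the dialogue layer then suppresses idle prompts and
  answers direct questions with the fallback. No action is re-emitted
  unless the scenario sets `allow_repeat`.
* Desires are re-evaluated from the current beliefs every turn — no
  latching. The terminal desire latches in effect, because its action
  ends the session.
* A trainee goodbye terminates after one farewell response
  (`trainee_goodbye`), distinct from the agent-initiated
  `agent_goodbye`; feedback reports are produced for unterminated
  sessions too.
* The clock is injected (`scripted_clock()` / `realtime_clock()`), so
  idle behaviour is testable without sleeping and replays are exactly
  reproducible.
* `validate_scenario()`'s unreachable-desire warning uses a static
  per-belief reachability search on a 0.1 grid: rules are iterated per
  belief, honouring guard atoms that mention the belief itself and
  assuming other atoms satisfiable; conjunctions are checked leaf-wise.
  This over-approximates joint reachability (it can miss an unreachable
  conjunction whose legs are individually reachable), which is the safe
  direction for a warning.
* Scenario loading *rejects* out-of-range initial values rather than
  clamping them: a bad configuration should fail loudly at load, never
  bend silently at run time.

## Problem sizes in the test suite

The invariant suite checks unit-interval conservation over 10,000
random 8-intent sequences, replay determinism on the packaged fixtures,
and desire evaluation against a brute-force condition evaluator on the
full $11^3$ grid of a 3-belief toy scenario — sizes at which the whole
suite completes in well under a minute while the grid check remains
exhaustive.

## Known limitations

* Keyword recognition is a fidelity floor, not a model of NLU; lexicon
  coverage determines how natural the chat feels.
* The taxonomy, thresholds, priorities, and initial values are
  reconstructions constrained by the published tables and one worked
  conversation; the original system's settings were not published.
* One scenario (bullying) ships; other case topics require new scenario
  files but no code.
* Surface text is English; the original deployment language (Dutch) is
  supported only by swapping the lexicon and templates.
* No real-time in-conversation guidance, no emotion layer on top of the
  BDI state, no learning of rule weights.
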