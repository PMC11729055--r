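# Packaged scenario: a bullied child contacts the helpline chat.
#
# Belief values range over [0, 1] (weak to strong). Initial values are a
# reconstruction: B12 and B16 must start at 0 (their published net change
# of +1 on a unit interval forces 0 -> 1); B04 and B05 start at 0.4 so the
# +0.1 greeting/empathy updates never clamp; everything else starts at 0.5.
# Rule magnitudes are calibrated so that each rule firing once in the
# rushing-trainee replay reproduces the published net changes exactly.
name: "Bullied child (helpline chat)"
description: >
  A gender-neutral child who is being bullied at school contacts the
  helpline. The trainee should follow the Five Phase Model: build rapport,
  explore the story and feelings, elicit the child's wish, work toward a
  confidant, and round off.
language: en
idle_threshold_seconds: 10
allow_repeat: false
multi_idle: false
lexicon: lexicon_en.yaml
fallback:
  no_understanding: "Hmm... I don't really get what you mean."
  farewell: "Okay... bye."

beliefs:
  - {id: B01, description: "Thinks it is in control",                              phase: All, group: "About self",                        initial: 0.5, desirable: 1}
  - {id: B02, description: "Thinks it is competent to solve the problem",          phase: 4,   group: "About self",                        initial: 0.5, desirable: 1}
  - {id: B03, description: "Feels connected to the child helpline",                phase: All, group: "About self",                        initial: 0.5, desirable: 1}
  - {id: B04, description: "Thinks the trainee can be trusted",                    phase: 2,   group: "About the child helpline trainee",  initial: 0.4, desirable: 1}
  - {id: B05, description: "Thinks the trainee understands it",                    phase: All, group: "About the child helpline trainee",  initial: 0.4, desirable: 1}
  - {id: B06, description: "Thinks the trainee is interested in its story",        phase: 2,   group: "About the child helpline trainee",  initial: 0.5, desirable: 1}
  - {id: B07, description: "Thinks the trainee can help it",                       phase: 3,   group: "About the child helpline trainee",  initial: 0.5, desirable: 1}
  - {id: B08, description: "Thinks the trainee can solve its problem",             phase: 3,   group: "About the child helpline trainee",  initial: 0.5, desirable: 1}
  - {id: B09, description: "Thinks it and the trainee will reach a solution",      phase: 4,   group: "About the child helpline trainee",  initial: 0.5, desirable: 1}
  - {id: B10, description: "Thinks the trainee is going to solve its problem",     phase: 4,   group: "About the child helpline trainee",  initial: 0.5, desirable: 1}
  - {id: B11, description: "Thinks it has talked about its situation",             phase: 2,   group: "About conversation",                initial: 0.5, desirable: 1}
  - {id: B12, description: "Thinks the trainee is asking about its wish",          phase: 3,   group: "About conversation",                initial: 0.0, desirable: 1}
  - {id: B13, description: "Thinks the trainee is asking about a positive wish",   phase: 3,   group: "About conversation",                initial: 0.5, desirable: 1}
  - {id: B14, description: "Feels safe in the conversation",                       phase: All, group: "About conversation",                initial: 0.5, desirable: 1}
  - {id: B15, description: "Thinks the trainee wants to end the conversation",     phase: 5,   group: "About conversation",                initial: 0.5, desirable: -1}
  - {id: B16, description: "Thinks the trainee is asking about a confidant",       phase: 4,   group: "About confidant",                   initial: 0.0, desirable: 1}
  - {id: B17, description: "Thinks its teacher can help it",                       phase: 4,   group: "About confidant",                   initial: 0.5, desirable: 1}

# Priority rank 1 is the most prominent: ending the conversation dominates,
# then the confidant goal, the joint-solution goal, the child's own wish,
# and finally the default desire to talk about the problem.
desires:
  - id: D1
    description: "Wants to talk about its problem"
    phase: 2
    priority: 5
    default: true
  - id: D2
    description: "Wants to end the conversation"
    phase: 5
    priority: 1
    terminal: true
    condition:
      any:
        - all:
            - {belief: B05, op: "<=", value: 0.2}
            - {belief: B06, op: "<=", value: 0.3}
        - all:
            - {belief: B07, op: "<=", value: 0.4}
            - {belief: B08, op: "<=", value: 0.3}
        - {belief: B15, op: ">=", value: 0.9}
  - id: D3
    description: "Wants the trainee to get the bullies out of school"
    phase: 3
    priority: 4
    condition: {belief: B12, op: ">=", value: 0.9}
  - id: D4
    description: "Wants to talk to its teacher about its problem"
    phase: 4
    priority: 2
    condition:
      all:
        - {belief: B16, op: ">=", value: 0.9}
        - {belief: B17, op: ">=", value: 0.5}
  - id: D5
    description: "Wants to work with the trainee to find a solution"
    phase: 3
    priority: 3
    action_free: true
    condition: {belief: B09, op: ">=", value: 0.7}

actions:
  - id: A1
    desire: D1
    name: "Introduces the problem"
    templates:
      - "Hi... I'm getting bullied at school and I don't really know what to do."
  - id: A2
    desire: D1
    name: "Provides more details about the problem"
    templates:
      - "Some kids in my class keep taking my stuff and laughing at me, almost every day."
  - id: A3
    desire: D1
    name: "Talks about the emotional impact of the problem"
    templates:
      - "It makes me feel really alone. I'm scared of going to school in the morning."
  - id: A4
    desire: D2
    name: "Says goodbye"
    templates:
      - "Bye!"
  - id: A5
    desire: D3
    name: "Asks the trainee to call the school to get the bullies out"
    templates:
      - "Can you call my school and make the bullies leave?"
  - id: A6
    desire: D4
    name: "Asks how its teacher can help"
    templates:
      - "Do you think my teacher could do something about the bullying?"
  - id: A7
    desire: D4
    name: "Expresses concern about the bullying getting worse"
    templates:
      - "I'm scared that the bullying will get worse if I tell my teacher."
  - id: A8
    desire: D4
    name: "Asks the trainee what to tell its teacher"
    templates:
      - "What should I say to my teacher?"

rules:
  - intent: greeting
    effects:
      - {belief: B04, delta: 0.1}
  - intent: show_empathy
    effects:
      - {belief: B05, delta: 0.1}
  - intent: ask_problem_details
    effects:
      - {belief: B11, delta: 0.1}
      - {belief: B06, delta: 0.1}
  - intent: ask_feelings
    effects:
      - {belief: B05, delta: 0.1}
      - {belief: B06, delta: 0.1}
  - intent: summarise_story
    effects:
      - {belief: B05, delta: 0.1}
      - {belief: B11, delta: 0.1}
  - intent: ask_wish
    effects:
      - {belief: B12, delta: 1.0}
  - intent: ask_positive_wish
    effects:
      - {belief: B13, delta: 0.5}
  - intent: suggest_alternative
    effects:
      - {belief: B07, delta: 0.1}
      - {belief: B09, delta: 0.1}
  - intent: reject_request_without_alternative
    effects:
      - {belief: B07, delta: -0.1}
      - {belief: B08, delta: -0.2}
  - intent: ask_confidant
    effects:
      - {belief: B16, delta: 1.0}
  - intent: ask_what_to_say
    effects:
      - {belief: B17, delta: 0.1}
      - {belief: B09, delta: 0.1}
  - intent: confirm_safety
    effects:
      - {belief: B14, delta: 0.1}
  - intent: goodbye
    effects:
      - {belief: B15, delta: 0.1}
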