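# Packaged English keyword lexicon for the deterministic intent
# recogniser. Patterns are whole-word phrases, tried top to bottom;
# the first match wins, so more specific phrases must come first.
case_insensitive: true
patterns:
  - {pattern: "hello", intent: greeting}
  - {pattern: "hi", intent: greeting}
  - {pattern: "hey", intent: greeting}
  - {pattern: "good morning", intent: greeting}
  - {pattern: "good afternoon", intent: greeting}
  - {pattern: "goodbye", intent: goodbye}
  - {pattern: "bye", intent: goodbye}
  - {pattern: "see you", intent: goodbye}
  - {pattern: "take care", intent: goodbye}
  - {pattern: "sounds really difficult", intent: show_empathy}
  - {pattern: "sounds hard", intent: show_empathy}
  - {pattern: "sounds tough", intent: show_empathy}
  - {pattern: "sounds awful", intent: show_empathy}
  - {pattern: "that must be", intent: show_empathy}
  - {pattern: "sorry to hear", intent: show_empathy}
  - {pattern: "what happened", intent: ask_problem_details}
  - {pattern: "tell me more", intent: ask_problem_details}
  - {pattern: "can you tell me about", intent: ask_problem_details}
  - {pattern: "what do they do", intent: ask_problem_details}
  - {pattern: "how often", intent: ask_problem_details}
  - {pattern: "how do you feel", intent: ask_feelings}
  - {pattern: "how does that make you feel", intent: ask_feelings}
  - {pattern: "how are you feeling", intent: ask_feelings}
  - {pattern: "so you are saying", intent: summarise_story}
  - {pattern: "if i understand correctly", intent: summarise_story}
  - {pattern: "let me summarise", intent: summarise_story}
  - {pattern: "to sum up", intent: summarise_story}
  - {pattern: "what do you wish", intent: ask_wish}
  - {pattern: "what would you like to happen", intent: ask_wish}
  - {pattern: "what do you want to happen", intent: ask_wish}
  - {pattern: "what would make you happy", intent: ask_positive_wish}
  - {pattern: "what would you like instead", intent: ask_positive_wish}
  - {pattern: "maybe you could", intent: suggest_alternative}
  - {pattern: "you could try", intent: suggest_alternative}
  - {pattern: "have you thought about", intent: suggest_alternative}
  - {pattern: "perhaps you could", intent: suggest_alternative}
  - {pattern: "you could", intent: suggest_alternative}
  - {pattern: "can't call", intent: reject_request_without_alternative}
  - {pattern: "cannot call", intent: reject_request_without_alternative}
  - {pattern: "can't do that", intent: reject_request_without_alternative}
  - {pattern: "cannot do that", intent: reject_request_without_alternative}
  - {pattern: "not able to", intent: reject_request_without_alternative}
  - {pattern: "we don't do that", intent: reject_request_without_alternative}
  - {pattern: "what would you say", intent: ask_what_to_say}
  - {pattern: "what to say", intent: ask_what_to_say}
  - {pattern: "what would you tell", intent: ask_what_to_say}
  - {pattern: "someone you trust", intent: ask_confidant}
  - {pattern: "adult you trust", intent: ask_confidant}
  - {pattern: "your teacher", intent: ask_confidant}
  - {pattern: "your parents", intent: ask_confidant}
  - {pattern: "have you told", intent: ask_confidant}
  - {pattern: "anyone you can talk to", intent: ask_confidant}
  - {pattern: "are you safe", intent: confirm_safety}
  - {pattern: "safe right now", intent: confirm_safety}
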