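# A Five-Phase-adherent trainee: rapport, story, feelings, wish, an
# alternative instead of a bare rejection, steering toward the teacher as
# confidant, safety check, and a proper goodbye.
name: adherent
intended_outcome: >
  Trainee ends the conversation (trainee_goodbye) after the confidant
  actions complete; every belief moves in its desirable direction.
events:
  - {utter: "Hello!"}
  - {utter: "Can you tell me more about what happened?"}
  - {utter: "That sounds really difficult for you."}
  - {utter: "What do you wish would happen?"}
  - {utter: "I can't promise that, but maybe you could talk to someone at school about it."}
  - {utter: "Is there an adult you trust, like your teacher?"}
  - {utter: "What would you say to your teacher?"}
  - {utter: "Are you safe right now?"}
  - {utter: "Goodbye!"}
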