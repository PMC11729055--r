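# The rushing-trainee replay: one empathic turn, then straight to the
# child's wish; the request is rejected without an alternative, the child
# loses faith in the trainee's ability to help, and the agent ends the
# conversation itself. The waits let the agent self-initiate (idle lines).
name: rushing
intended_outcome: >
  Agent ends the conversation (agent_goodbye); net belief changes
  B04 +0.1, B05 +0.1, B07 -0.1, B08 -0.2, B12 +1, B16 +1, others 0.
events:
  - {utter: "Hi!"}
  - {wait: 10}
  - {utter: "That sounds really difficult for you."}
  - {wait: 10}
  - {utter: "What do you wish would happen?"}
  - {utter: "Have you told your teacher about the bullying?"}
  - {utter: "No, we can't call your school. That's not something the helpline can do."}
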