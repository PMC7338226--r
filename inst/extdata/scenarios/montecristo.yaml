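# Audience Studio scenario: Dantès avenges the wrong done to him. His
# justice value, long at stake, is restored by his own act (pride) and the
# restoration goal is achieved (joy): together, gratification. Fernand
# merely loses what he had — a failed goal, other-caused — and feels
# distress.
id: montecristo
study: audience
title: The Count of MonteCristo
predicates: [wronged, rich, avenged, ruined]
world:
  - wronged(dantes)
  - rich(fernand)
characters:
  - id: dantes
    protagonist: true
    values:
      - id: justice
        priority: 0.9
        violation: [wronged(dantes)]
    plans:
      - id: revenge
        goal: restore:justice
        probability_of_success: 0.8
        steps:
          - id: execute_revenge
            preconditions: [rich(fernand)]
            effects:
              - del: wronged(dantes)
              - add: avenged(dantes)
              - add: ruined(fernand)
              - del: rich(fernand)
  - id: fernand
    goals:
      - id: keep_status
        importance_of_success: 0.7
        importance_of_failure: 0.8
        adoption: [rich(fernand)]
        failure: [ruined(fernand)]
script:
  max_cycles: 1
  outcomes:
    revenge: success
predicted:
  emotions:
    dantes: [joy, gratification, pride]
    fernand: [distress]
  provisional: [fernand]
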