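# Actor Studio scenario 2: a humiliated schoolboy can take revenge on the
# bully or let it go. Revenge restores his wounded self-worth (the value at
# stake spawns the restoration goal the plan serves): achieving it brings
# joy and pride, hence gratification, while hurting the bully violates his
# kindness and adds shame.
id: at_school
study: actor
title: At school!
predicates: [humiliated, bully, avenged, hurt, moved_on]
world:
  - humiliated(nino)
  - bully(marco)
characters:
  - id: nino
    protagonist: true
    goals:
      - id: move_on
        importance_of_success: 0.3
        importance_of_failure: 0.2
        adoption: [humiliated(nino)]
        success: [moved_on(nino)]
    values:
      - id: self_worth
        priority: 0.9
        violation: [humiliated(nino)]
      - id: kindness
        priority: 0.4
        violation: [hurt(marco)]
    plans:
      - id: revenging
        goal: restore:self_worth
        probability_of_success: 0.8
        steps:
          - id: take_revenge
            preconditions: [bully(marco)]
            effects:
              - del: humiliated(nino)
              - add: avenged(nino)
              - add: hurt(marco)
      - id: letting_go
        goal: move_on
        probability_of_success: 1.0
        steps:
          - id: let_go
            effects:
              - add: moved_on(nino)
script:
  max_cycles: 1
  outcomes:
    revenging: success
predicted:
  plan: revenging
  emotions:
    nino: [joy, pride, shame, gratification]
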