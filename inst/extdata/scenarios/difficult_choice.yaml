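# Actor Studio scenario 3: stay to care for an ill mother or leave for the
# long-dreamt opportunity. Staying achieves the (heavier) care goal but
# fails the dream and breaks the promise she made to herself: joy mixed
# with distress, shame and remorse. Leaving would violate the far weightier
# family bond, so the agent stays.
id: difficult_choice
study: actor
title: A difficult choice
predicates: [ill, offer, cared_for, renounced, departed, abandoned]
world:
  - ill(mother)
  - offer(elena)
characters:
  - id: elena
    protagonist: true
    goals:
      - id: care_for_mother
        importance_of_success: 0.9
        importance_of_failure: 0.8
        adoption: [ill(mother)]
        success: [cared_for(mother)]
        failure: [abandoned(mother)]
      - id: follow_dream
        importance_of_success: 0.5
        importance_of_failure: 0.4
        adoption: [offer(elena)]
        success: [departed(elena)]
        failure: [renounced(elena)]
    values:
      - id: self_promise
        priority: 0.4
        violation: [renounced(elena)]
      - id: family_bond
        priority: 0.9
        violation: [abandoned(mother)]
    plans:
      - id: staying
        goal: care_for_mother
        probability_of_success: 0.9
        steps:
          - id: stay
            preconditions: [ill(mother)]
            effects:
              - add: cared_for(mother)
              - add: renounced(elena)
      - id: leaving
        goal: follow_dream
        probability_of_success: 0.9
        steps:
          - id: leave
            preconditions: [offer(elena)]
            effects:
              - add: departed(elena)
              - add: abandoned(mother)
script:
  max_cycles: 1
  outcomes:
    staying: success
predicted:
  plan: staying
  emotions:
    elena: [distress, joy, shame, remorse]
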