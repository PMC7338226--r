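# Actor Studio scenario 1: a guard is begged for the cell key. Giving it
# away betrays his duty (shame) but refusing abandons the prisoner, which
# his high-priority compassion cannot bear. Freedom itself lies beyond the
# episode, so handing over the key achieves nothing yet; the only realized
# emotion is the shame of the violated duty.
id: wallace
study: actor
title: Wallace
predicates: [pleads, captive, has_key, gave_key, refused, abandoned, free]
world:
  - pleads(prisoner)
  - captive(prisoner)
  - has_key(wallace)
characters:
  - id: wallace
    protagonist: true
    goals:
      - id: save_prisoner
        importance_of_success: 0.8
        importance_of_failure: 0.6
        adoption: [pleads(prisoner)]
        success: [free(prisoner)]
        failure: [abandoned(prisoner)]
      - id: uphold_duty
        importance_of_success: 0.3
        importance_of_failure: 0.2
        adoption: [pleads(prisoner)]
        success: [refused(wallace)]
    values:
      - id: duty
        priority: 0.6
        violation: [gave_key(wallace)]
      - id: compassion
        priority: 0.9
        violation: [abandoned(prisoner)]
    plans:
      - id: giving_key
        goal: save_prisoner
        probability_of_success: 0.9
        steps:
          - id: give_key
            preconditions: [has_key(wallace)]
            effects:
              - add: gave_key(wallace)
              - add: has_key(prisoner)
              - del: has_key(wallace)
      - id: refusing_key
        goal: uphold_duty
        probability_of_success: 1.0
        steps:
          - id: refuse
            preconditions: [has_key(wallace)]
            effects:
              - add: refused(wallace)
              - add: abandoned(prisoner)
script:
  max_cycles: 1
  outcomes:
    giving_key: success
predicted:
  plan: giving_key
  emotions:
    wallace: [shame]
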