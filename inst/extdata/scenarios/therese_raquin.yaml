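# Audience Studio scenario: Thérèse and Laurent drown Camille hoping for a
# life together; what they get is haunting. For each, their own action
# violates the sanctity of life (shame) and fails the goal of a happy life
# (distress); sharing a cause, the two compound into remorse.
id: therese_raquin
study: audience
title: Thérèse Raquin
predicates: [married, loves, drowned, haunted, complicit, free_together]
world:
  - married(therese,camille)
  - loves(therese,laurent)
characters:
  - id: therese
    protagonist: true
    goals:
      - id: live_happily
        importance_of_success: 0.7
        importance_of_failure: 0.8
        adoption: ["loves(therese,laurent)"]
        success: ["free_together(therese,laurent)"]
        failure: [haunted(therese)]
    values:
      - id: sanctity_of_life
        priority: 0.9
        violation: [drowned(camille)]
    plans:
      - id: drowning
        goal: live_happily
        probability_of_success: 0.6
        steps:
          - id: drown_camille
            preconditions: ["married(therese,camille)"]
            effects:
              - add: drowned(camille)
              - add: haunted(therese)
  - id: laurent
    goals:
      - id: new_life
        importance_of_success: 0.7
        importance_of_failure: 0.8
        adoption: ["loves(therese,laurent)"]
        success: ["free_together(therese,laurent)"]
        failure: [haunted(laurent)]
    values:
      - id: respect_for_life
        priority: 0.8
        violation: [complicit(laurent)]
    plans:
      - id: assisting
        goal: new_life
        probability_of_success: 0.6
        steps:
          - id: assist_drowning
            preconditions: ["loves(therese,laurent)"]
            effects:
              - add: complicit(laurent)
              - add: haunted(laurent)
script:
  max_cycles: 1
  outcomes:
    drowning: success
    assisting: success
predicted:
  emotions:
    therese: [remorse, distress, shame]
    laurent: [remorse, distress, shame]
  provisional: [laurent]
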