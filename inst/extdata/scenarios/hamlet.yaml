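# Audience Studio scenario: Ophelia, ordered by her father, deceives
# Hamlet. His trust is violated by another's action (reproach) and his hope
# of being loved fails (distress); sharing a cause they compound into
# anger. Ophelia's own loyalty is violated by her own deed: shame — her
# obedience goal is not yet satisfied, so no joy tempers it.
id: hamlet
study: audience
title: Hamlet
predicates: [loves, ordered, deceived, betrayed, father_satisfied]
world:
  - loves(hamlet,ophelia)
  - ordered(polonius)
characters:
  - id: hamlet
    protagonist: true
    goals:
      - id: be_loved
        importance_of_success: 0.8
        importance_of_failure: 0.9
        adoption: ["loves(hamlet,ophelia)"]
        failure: [betrayed(hamlet)]
    values:
      - id: trust
        priority: 0.8
        violation: [deceived(hamlet)]
  - id: ophelia
    goals:
      - id: obey_father
        importance_of_success: 0.5
        importance_of_failure: 0.4
        adoption: [ordered(polonius)]
        success: [father_satisfied]
    values:
      - id: loyalty
        priority: 0.7
        violation: [deceived(hamlet)]
    plans:
      - id: spying
        goal: obey_father
        probability_of_success: 0.9
        steps:
          - id: spy_on_hamlet
            preconditions: [ordered(polonius)]
            effects:
              - add: deceived(hamlet)
              - add: betrayed(hamlet)
script:
  max_cycles: 1
  outcomes:
    spying: success
predicted:
  emotions:
    hamlet: [reproach, anger, distress]
    ophelia: [shame]
  provisional: [ophelia]
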