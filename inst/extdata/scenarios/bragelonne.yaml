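# Audience Studio scenario: Raoul restores the tarnished family name by his
# own deed — value restored plus restoration goal achieved, compounding
# into gratification; Athos, whose own stake in the house's honor is
# restored by his son's praiseworthy act, feels gratitude. Here the
# published prediction marks the compounds alone, so component co-emission
# is switched off for this scenario.
id: bragelonne
study: audience
title: The Vicomte of Bragelonne
config:
  coemit_compounds: false
predicates: [dishonored, glory]
world:
  - dishonored(family)
characters:
  - id: raoul
    protagonist: true
    values:
      - id: family_name
        priority: 0.8
        violation: [dishonored(family)]
    plans:
      - id: restoring_glory
        goal: restore:family_name
        probability_of_success: 0.9
        steps:
          - id: restore_glory
            preconditions: [dishonored(family)]
            effects:
              - del: dishonored(family)
              - add: glory(family)
  - id: athos
    values:
      - id: house_honor
        priority: 0.7
        violation: [dishonored(family)]
script:
  max_cycles: 1
  outcomes:
    restoring_glory: success
predicted:
  emotions:
    raoul: [gratification]
    athos: [gratitude]
  provisional: [athos]
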