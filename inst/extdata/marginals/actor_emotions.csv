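scenario,group,emotion,predicted,pct,source
wallace,TBI,distress,0,38.5,emo:wallace:TBI:distress
wallace,TBI,joy,0,23.1,emo:wallace:TBI:joy
wallace,TBI,fear,0,0.0,emo:wallace:TBI:fear
wallace,TBI,hope,0,15.4,emo:wallace:TBI:hope
wallace,TBI,pride,0,23.1,emo:wallace:TBI:pride
wallace,TBI,shame,1,23.1,emo:wallace:TBI:shame
wallace,TBI,admiration,0,23.1,emo:wallace:TBI:admiration
wallace,TBI,reproach,0,7.7,emo:wallace:TBI:reproach
wallace,TBI,gratification,0,7.7,emo:wallace:TBI:gratification
wallace,TBI,gratitude,0,0.0,emo:wallace:TBI:gratitude
wallace,TBI,remorse,0,38.5,emo:wallace:TBI:remorse
wallace,TBI,anger,0,23.1,emo:wallace:TBI:anger
wallace,control,distress,0,9.1,emo:wallace:control:distress
wallace,control,joy,0,0.0,emo:wallace:control:joy
wallace,control,fear,0,0.0,emo:wallace:control:fear
wallace,control,hope,0,18.2,emo:wallace:control:hope
wallace,control,pride,0,9.1,emo:wallace:control:pride
wallace,control,shame,1,27.3,emo:wallace:control:shame
wallace,control,admiration,0,27.3,emo:wallace:control:admiration
wallace,control,reproach,0,27.3,emo:wallace:control:reproach
wallace,control,gratification,0,18.2,emo:wallace:control:gratification
wallace,control,gratitude,0,0.0,emo:wallace:control:gratitude
wallace,control,remorse,0,27.3,emo:wallace:control:remorse
wallace,control,anger,0,9.1,emo:wallace:control:anger
at_school,TBI,distress,0,23.1,emo:at_school:TBI:distress
at_school,TBI,joy,1,23.1,emo:at_school:TBI:joy
at_school,TBI,fear,0,46.2,emo:at_school:TBI:fear
at_school,TBI,hope,0,0.0,emo:at_school:TBI:hope
at_school,TBI,pride,1,23.1,emo:at_school:TBI:pride
at_school,TBI,shame,1,23.1,emo:at_school:TBI:shame
at_school,TBI,admiration,0,7.7,emo:at_school:TBI:admiration
at_school,TBI,reproach,0,53.8,emo:at_school:TBI:reproach
at_school,TBI,gratification,1,53.8,emo:at_school:TBI:gratification
at_school,TBI,gratitude,0,7.7,emo:at_school:TBI:gratitude
at_school,TBI,remorse,0,15.4,emo:at_school:TBI:remorse
at_school,TBI,anger,0,46.2,emo:at_school:TBI:anger
at_school,control,distress,0,0.0,emo:at_school:control:distress
at_school,control,joy,1,36.4,emo:at_school:control:joy
at_school,control,fear,0,54.5,emo:at_school:control:fear
at_school,control,hope,0,0.0,emo:at_school:control:hope
at_school,control,pride,1,27.3,emo:at_school:control:pride
at_school,control,shame,1,18.2,emo:at_school:control:shame
at_school,control,admiration,0,0.0,emo:at_school:control:admiration
at_school,control,reproach,0,36.4,emo:at_school:control:reproach
at_school,control,gratification,1,0.0,emo:at_school:control:gratification
at_school,control,gratitude,0,0.0,emo:at_school:control:gratitude
at_school,control,remorse,0,27.3,emo:at_school:control:remorse
at_school,control,anger,0,9.1,emo:at_school:control:anger
difficult_choice,TBI,distress,1,23.1,emo:difficult_choice:TBI:distress
difficult_choice,TBI,joy,1,76.9,emo:difficult_choice:TBI:joy
difficult_choice,TBI,fear,0,23.1,emo:difficult_choice:TBI:fear
difficult_choice,TBI,hope,0,30.8,emo:difficult_choice:TBI:hope
difficult_choice,TBI,pride,0,38.5,emo:difficult_choice:TBI:pride
difficult_choice,TBI,shame,1,23.1,emo:difficult_choice:TBI:shame
difficult_choice,TBI,admiration,0,30.8,emo:difficult_choice:TBI:admiration
difficult_choice,TBI,reproach,0,7.7,emo:difficult_choice:TBI:reproach
difficult_choice,TBI,gratification,0,53.8,emo:difficult_choice:TBI:gratification
difficult_choice,TBI,gratitude,0,23.1,emo:difficult_choice:TBI:gratitude
difficult_choice,TBI,remorse,1,69.2,emo:difficult_choice:TBI:remorse
difficult_choice,TBI,anger,0,7.7,emo:difficult_choice:TBI:anger
difficult_choice,control,distress,1,18.2,emo:difficult_choice:control:distress
difficult_choice,control,joy,1,54.5,emo:difficult_choice:control:joy
difficult_choice,control,fear,0,9.1,emo:difficult_choice:control:fear
difficult_choice,control,hope,0,9.1,emo:difficult_choice:control:hope
difficult_choice,control,pride,0,36.4,emo:difficult_choice:control:pride
difficult_choice,control,shame,1,18.2,emo:difficult_choice:control:shame
difficult_choice,control,admiration,0,18.2,emo:difficult_choice:control:admiration
difficult_choice,control,reproach,0,9.1,emo:difficult_choice:control:reproach
difficult_choice,control,gratification,0,27.3,emo:difficult_choice:control:gratification
difficult_choice,control,gratitude,0,9.1,emo:difficult_choice:control:gratitude
difficult_choice,control,remorse,1,45.5,emo:difficult_choice:control:remorse
difficult_choice,control,anger,0,9.1,emo:difficult_choice:control:anger
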