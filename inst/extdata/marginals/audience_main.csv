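scenario,group,emotion,predicted,pct,source
hamlet,TBI,distress,1,80.0,aud_main:hamlet:TBI:distress
hamlet,TBI,joy,0,0.0,aud_main:hamlet:TBI:joy
hamlet,TBI,fear,0,13.3,aud_main:hamlet:TBI:fear
hamlet,TBI,hope,0,0.0,aud_main:hamlet:TBI:hope
hamlet,TBI,pride,0,0.0,aud_main:hamlet:TBI:pride
hamlet,TBI,shame,0,33.3,aud_main:hamlet:TBI:shame
hamlet,TBI,admiration,0,0.0,aud_main:hamlet:TBI:admiration
hamlet,TBI,reproach,1,46.7,aud_main:hamlet:TBI:reproach
hamlet,TBI,gratification,0,0.0,aud_main:hamlet:TBI:gratification
hamlet,TBI,gratitude,0,0.0,aud_main:hamlet:TBI:gratitude
hamlet,TBI,remorse,0,6.7,aud_main:hamlet:TBI:remorse
hamlet,TBI,anger,1,100.0,aud_main:hamlet:TBI:anger
hamlet,control,distress,1,30.0,aud_main:hamlet:control:distress
hamlet,control,joy,0,0.0,aud_main:hamlet:control:joy
hamlet,control,fear,0,10.0,aud_main:hamlet:control:fear
hamlet,control,hope,0,10.0,aud_main:hamlet:control:hope
hamlet,control,pride,0,10.0,aud_main:hamlet:control:pride
hamlet,control,shame,0,0.0,aud_main:hamlet:control:shame
hamlet,control,admiration,0,10.0,aud_main:hamlet:control:admiration
hamlet,control,reproach,1,50.0,aud_main:hamlet:control:reproach
hamlet,control,gratification,0,10.0,aud_main:hamlet:control:gratification
hamlet,control,gratitude,0,20.0,aud_main:hamlet:control:gratitude
hamlet,control,remorse,0,10.0,aud_main:hamlet:control:remorse
hamlet,control,anger,1,30.0,aud_main:hamlet:control:anger
montecristo,TBI,distress,0,14.3,aud_main:montecristo:TBI:distress
montecristo,TBI,joy,1,35.7,aud_main:montecristo:TBI:joy
montecristo,TBI,fear,0,21.4,aud_main:montecristo:TBI:fear
montecristo,TBI,hope,0,35.7,aud_main:montecristo:TBI:hope
montecristo,TBI,pride,1,71.4,aud_main:montecristo:TBI:pride
montecristo,TBI,shame,0,14.3,aud_main:montecristo:TBI:shame
montecristo,TBI,admiration,0,21.4,aud_main:montecristo:TBI:admiration
montecristo,TBI,reproach,0,28.6,aud_main:montecristo:TBI:reproach
montecristo,TBI,gratification,1,42.9,aud_main:montecristo:TBI:gratification
montecristo,TBI,gratitude,0,7.1,aud_main:montecristo:TBI:gratitude
montecristo,TBI,remorse,0,14.3,aud_main:montecristo:TBI:remorse
montecristo,TBI,anger,0,28.6,aud_main:montecristo:TBI:anger
montecristo,control,distress,0,0.0,aud_main:montecristo:control:distress
montecristo,control,joy,1,50.0,aud_main:montecristo:control:joy
montecristo,control,fear,0,0.0,aud_main:montecristo:control:fear
montecristo,control,hope,0,0.0,aud_main:montecristo:control:hope
montecristo,control,pride,1,75.0,aud_main:montecristo:control:pride
montecristo,control,shame,0,0.0,aud_main:montecristo:control:shame
montecristo,control,admiration,0,37.5,aud_main:montecristo:control:admiration
montecristo,control,reproach,0,25.0,aud_main:montecristo:control:reproach
montecristo,control,gratification,1,87.5,aud_main:montecristo:control:gratification
montecristo,control,gratitude,0,0.0,aud_main:montecristo:control:gratitude
montecristo,control,remorse,0,0.0,aud_main:montecristo:control:remorse
montecristo,control,anger,0,25.0,aud_main:montecristo:control:anger
therese_raquin,TBI,distress,1,69.2,aud_main:therese_raquin:TBI:distress
therese_raquin,TBI,joy,0,0.0,aud_main:therese_raquin:TBI:joy
therese_raquin,TBI,fear,0,46.2,aud_main:therese_raquin:TBI:fear
therese_raquin,TBI,hope,0,15.4,aud_main:therese_raquin:TBI:hope
therese_raquin,TBI,pride,0,7.7,aud_main:therese_raquin:TBI:pride
therese_raquin,TBI,shame,1,76.9,aud_main:therese_raquin:TBI:shame
therese_raquin,TBI,admiration,0,0.0,aud_main:therese_raquin:TBI:admiration
therese_raquin,TBI,reproach,0,30.8,aud_main:therese_raquin:TBI:reproach
therese_raquin,TBI,gratification,0,0.0,aud_main:therese_raquin:TBI:gratification
therese_raquin,TBI,gratitude,0,0.0,aud_main:therese_raquin:TBI:gratitude
therese_raquin,TBI,remorse,1,76.9,aud_main:therese_raquin:TBI:remorse
therese_raquin,TBI,anger,0,30.8,aud_main:therese_raquin:TBI:anger
therese_raquin,control,distress,1,44.4,aud_main:therese_raquin:control:distress
therese_raquin,control,joy,0,11.1,aud_main:therese_raquin:control:joy
therese_raquin,control,fear,0,55.6,aud_main:therese_raquin:control:fear
therese_raquin,control,hope,0,0.0,aud_main:therese_raquin:control:hope
therese_raquin,control,pride,0,11.1,aud_main:therese_raquin:control:pride
therese_raquin,control,shame,1,77.8,aud_main:therese_raquin:control:shame
therese_raquin,control,admiration,0,0.0,aud_main:therese_raquin:control:admiration
therese_raquin,control,reproach,0,11.1,aud_main:therese_raquin:control:reproach
therese_raquin,control,gratification,0,11.1,aud_main:therese_raquin:control:gratification
therese_raquin,control,gratitude,0,0.0,aud_main:therese_raquin:control:gratitude
therese_raquin,control,remorse,1,88.9,aud_main:therese_raquin:control:remorse
therese_raquin,control,anger,0,0.0,aud_main:therese_raquin:control:anger
bragelonne,TBI,distress,0,15.4,aud_main:bragelonne:TBI:distress
bragelonne,TBI,joy,0,53.8,aud_main:bragelonne:TBI:joy
bragelonne,TBI,fear,0,23.1,aud_main:bragelonne:TBI:fear
bragelonne,TBI,hope,0,46.2,aud_main:bragelonne:TBI:hope
bragelonne,TBI,pride,0,53.8,aud_main:bragelonne:TBI:pride
bragelonne,TBI,shame,0,15.4,aud_main:bragelonne:TBI:shame
bragelonne,TBI,admiration,0,46.2,aud_main:bragelonne:TBI:admiration
bragelonne,TBI,reproach,0,7.7,aud_main:bragelonne:TBI:reproach
bragelonne,TBI,gratification,1,69.2,aud_main:bragelonne:TBI:gratification
bragelonne,TBI,gratitude,0,7.7,aud_main:bragelonne:TBI:gratitude
bragelonne,TBI,remorse,0,15.4,aud_main:bragelonne:TBI:remorse
bragelonne,TBI,anger,0,0.0,aud_main:bragelonne:TBI:anger
bragelonne,control,distress,0,0.0,aud_main:bragelonne:control:distress
bragelonne,control,joy,0,70.0,aud_main:bragelonne:control:joy
bragelonne,control,fear,0,10.0,aud_main:bragelonne:control:fear
bragelonne,control,hope,0,30.0,aud_main:bragelonne:control:hope
bragelonne,control,pride,0,60.0,aud_main:bragelonne:control:pride
bragelonne,control,shame,0,10.0,aud_main:bragelonne:control:shame
bragelonne,control,admiration,0,30.0,aud_main:bragelonne:control:admiration
bragelonne,control,reproach,0,0.0,aud_main:bragelonne:control:reproach
bragelonne,control,gratification,1,60.0,aud_main:bragelonne:control:gratification
bragelonne,control,gratitude,0,0.0,aud_main:bragelonne:control:gratitude
bragelonne,control,remorse,0,0.0,aud_main:bragelonne:control:remorse
bragelonne,control,anger,0,0.0,aud_main:bragelonne:control:anger
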