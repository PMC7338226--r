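scenario,group,emotion,predicted,pct,source,provisional
hamlet,TBI,distress,0,73.3,aud_other:hamlet:TBI:distress,1
hamlet,TBI,joy,0,0.0,aud_other:hamlet:TBI:joy,1
hamlet,TBI,fear,0,26.7,aud_other:hamlet:TBI:fear,1
hamlet,TBI,hope,0,6.7,aud_other:hamlet:TBI:hope,1
hamlet,TBI,pride,0,6.7,aud_other:hamlet:TBI:pride,1
hamlet,TBI,shame,1,86.7,aud_other:hamlet:TBI:shame,1
hamlet,TBI,admiration,0,0.0,aud_other:hamlet:TBI:admiration,1
hamlet,TBI,reproach,0,20.0,aud_other:hamlet:TBI:reproach,1
hamlet,TBI,gratification,0,0.0,aud_other:hamlet:TBI:gratification,1
hamlet,TBI,gratitude,0,0.0,aud_other:hamlet:TBI:gratitude,1
hamlet,TBI,remorse,0,53.3,aud_other:hamlet:TBI:remorse,1
hamlet,TBI,anger,0,33.3,aud_other:hamlet:TBI:anger,1
hamlet,control,distress,0,10.0,aud_other:hamlet:control:distress,1
hamlet,control,joy,0,0.0,aud_other:hamlet:control:joy,1
hamlet,control,fear,0,50.0,aud_other:hamlet:control:fear,1
hamlet,control,hope,0,20.0,aud_other:hamlet:control:hope,1
hamlet,control,pride,0,0.0,aud_other:hamlet:control:pride,1
hamlet,control,shame,1,50.0,aud_other:hamlet:control:shame,1
hamlet,control,admiration,0,0.0,aud_other:hamlet:control:admiration,1
hamlet,control,reproach,0,20.0,aud_other:hamlet:control:reproach,1
hamlet,control,gratification,0,0.0,aud_other:hamlet:control:gratification,1
hamlet,control,gratitude,0,0.0,aud_other:hamlet:control:gratitude,1
hamlet,control,remorse,0,40.0,aud_other:hamlet:control:remorse,1
hamlet,control,anger,0,0.0,aud_other:hamlet:control:anger,1
montecristo,TBI,distress,1,42.9,aud_other:montecristo:TBI:distress,1
montecristo,TBI,joy,0,0.0,aud_other:montecristo:TBI:joy,1
montecristo,TBI,fear,0,78.6,aud_other:montecristo:TBI:fear,1
montecristo,TBI,hope,0,0.0,aud_other:montecristo:TBI:hope,1
montecristo,TBI,pride,0,7.1,aud_other:montecristo:TBI:pride,1
montecristo,TBI,shame,0,57.1,aud_other:montecristo:TBI:shame,1
montecristo,TBI,admiration,0,0.0,aud_other:montecristo:TBI:admiration,1
montecristo,TBI,reproach,0,35.7,aud_other:montecristo:TBI:reproach,1
montecristo,TBI,gratification,0,0.0,aud_other:montecristo:TBI:gratification,1
montecristo,TBI,gratitude,0,0.0,aud_other:montecristo:TBI:gratitude,1
montecristo,TBI,remorse,0,57.1,aud_other:montecristo:TBI:remorse,1
montecristo,TBI,anger,0,28.6,aud_other:montecristo:TBI:anger,1
montecristo,control,distress,1,37.5,aud_other:montecristo:control:distress,1
montecristo,control,joy,0,0.0,aud_other:montecristo:control:joy,1
montecristo,control,fear,0,50.0,aud_other:montecristo:control:fear,1
montecristo,control,hope,0,0.0,aud_other:montecristo:control:hope,1
montecristo,control,pride,0,0.0,aud_other:montecristo:control:pride,1
montecristo,control,shame,0,62.5,aud_other:montecristo:control:shame,1
montecristo,control,admiration,0,0.0,aud_other:montecristo:control:admiration,1
montecristo,control,reproach,0,0.0,aud_other:montecristo:control:reproach,1
montecristo,control,gratification,0,0.0,aud_other:montecristo:control:gratification,1
montecristo,control,gratitude,0,0.0,aud_other:montecristo:control:gratitude,1
montecristo,control,remorse,0,25.0,aud_other:montecristo:control:remorse,1
montecristo,control,anger,0,50.0,aud_other:montecristo:control:anger,1
therese_raquin,TBI,distress,1,23.1,aud_other:therese_raquin:TBI:distress,1
therese_raquin,TBI,joy,0,0.0,aud_other:therese_raquin:TBI:joy,1
therese_raquin,TBI,fear,0,38.5,aud_other:therese_raquin:TBI:fear,1
therese_raquin,TBI,hope,0,15.4,aud_other:therese_raquin:TBI:hope,1
therese_raquin,TBI,pride,0,7.7,aud_other:therese_raquin:TBI:pride,1
therese_raquin,TBI,shame,1,84.6,aud_other:therese_raquin:TBI:shame,1
therese_raquin,TBI,admiration,0,0.0,aud_other:therese_raquin:TBI:admiration,1
therese_raquin,TBI,reproach,0,30.8,aud_other:therese_raquin:TBI:reproach,1
therese_raquin,TBI,gratification,0,0.0,aud_other:therese_raquin:TBI:gratification,1
therese_raquin,TBI,gratitude,0,7.7,aud_other:therese_raquin:TBI:gratitude,1
therese_raquin,TBI,remorse,1,76.9,aud_other:therese_raquin:TBI:remorse,1
therese_raquin,TBI,anger,0,46.2,aud_other:therese_raquin:TBI:anger,1
therese_raquin,control,distress,1,66.7,aud_other:therese_raquin:control:distress,1
therese_raquin,control,joy,0,11.1,aud_other:therese_raquin:control:joy,1
therese_raquin,control,fear,0,33.3,aud_other:therese_raquin:control:fear,1
therese_raquin,control,hope,0,0.0,aud_other:therese_raquin:control:hope,1
therese_raquin,control,pride,0,0.0,aud_other:therese_raquin:control:pride,1
therese_raquin,control,shame,1,66.7,aud_other:therese_raquin:control:shame,1
therese_raquin,control,admiration,0,0.0,aud_other:therese_raquin:control:admiration,1
therese_raquin,control,reproach,0,33.3,aud_other:therese_raquin:control:reproach,1
therese_raquin,control,gratification,0,11.1,aud_other:therese_raquin:control:gratification,1
therese_raquin,control,gratitude,0,0.0,aud_other:therese_raquin:control:gratitude,1
therese_raquin,control,remorse,1,55.6,aud_other:therese_raquin:control:remorse,1
therese_raquin,control,anger,0,33.3,aud_other:therese_raquin:control:anger,1
bragelonne,TBI,distress,0,23.1,aud_other:bragelonne:TBI:distress,1
bragelonne,TBI,joy,0,76.9,aud_other:bragelonne:TBI:joy,1
bragelonne,TBI,fear,0,15.4,aud_other:bragelonne:TBI:fear,1
bragelonne,TBI,hope,0,38.5,aud_other:bragelonne:TBI:hope,1
bragelonne,TBI,pride,0,15.4,aud_other:bragelonne:TBI:pride,1
bragelonne,TBI,shame,0,23.1,aud_other:bragelonne:TBI:shame,1
bragelonne,TBI,admiration,0,46.2,aud_other:bragelonne:TBI:admiration,1
bragelonne,TBI,reproach,0,0.0,aud_other:bragelonne:TBI:reproach,1
bragelonne,TBI,gratification,0,30.8,aud_other:bragelonne:TBI:gratification,1
bragelonne,TBI,gratitude,1,84.6,aud_other:bragelonne:TBI:gratitude,1
bragelonne,TBI,remorse,0,7.7,aud_other:bragelonne:TBI:remorse,1
bragelonne,TBI,anger,0,15.4,aud_other:bragelonne:TBI:anger,1
bragelonne,control,distress,0,0.0,aud_other:bragelonne:control:distress,1
bragelonne,control,joy,0,60.0,aud_other:bragelonne:control:joy,1
bragelonne,control,fear,0,0.0,aud_other:bragelonne:control:fear,1
bragelonne,control,hope,0,30.0,aud_other:bragelonne:control:hope,1
bragelonne,control,pride,0,0.0,aud_other:bragelonne:control:pride,1
bragelonne,control,shame,0,0.0,aud_other:bragelonne:control:shame,1
bragelonne,control,admiration,0,60.0,aud_other:bragelonne:control:admiration,1
bragelonne,control,reproach,0,0.0,aud_other:bragelonne:control:reproach,1
bragelonne,control,gratification,0,10.0,aud_other:bragelonne:control:gratification,1
bragelonne,control,gratitude,1,60.0,aud_other:bragelonne:control:gratitude,1
bragelonne,control,remorse,0,10.0,aud_other:bragelonne:control:remorse,1
bragelonne,control,anger,0,10.0,aud_other:bragelonne:control:anger,1
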