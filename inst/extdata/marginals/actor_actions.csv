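scenario,group,plan,predicted,pct,source
wallace,TBI,giving_key,1,46.2,actions:wallace:TBI:giving_key
wallace,TBI,refusing_key,0,53.8,actions:wallace:TBI:refusing_key
wallace,control,giving_key,1,18.2,actions:wallace:control:giving_key
wallace,control,refusing_key,0,81.8,actions:wallace:control:refusing_key
at_school,TBI,revenging,1,84.6,actions:at_school:TBI:revenging
at_school,TBI,letting_go,0,15.4,actions:at_school:TBI:letting_go
at_school,control,revenging,1,81.8,actions:at_school:control:revenging
at_school,control,letting_go,0,18.2,actions:at_school:control:letting_go
difficult_choice,TBI,staying,1,84.6,actions:difficult_choice:TBI:staying
difficult_choice,TBI,leaving,0,15.4,actions:difficult_choice:TBI:leaving
difficult_choice,control,staying,1,81.8,actions:difficult_choice:control:staying
difficult_choice,control,leaving,0,18.2,actions:difficult_choice:control:leaving
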