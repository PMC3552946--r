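label,effect,se,scale_tag
Trial 1,-0.5151667840250176,0.18423386667855085,log_ratio
Trial 2,-1.5205833874728032,0.2377921629929915,log_ratio
Trial 3,-1.253981760739454,0.23368567409925162,log_ratio
Trial 4,-1.6976189660179148,0.26291577857919035,log_ratio
Trial 5,-0.16418189455919102,0.28547120166476814,log_ratio
Trial 6,-0.9572300335292827,0.3054522324353457,log_ratio
Trial 7,-0.8542243457051704,0.17988565529230982,log_ratio
Trial 8,-0.7781928318215281,0.16122122132219374,log_ratio
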