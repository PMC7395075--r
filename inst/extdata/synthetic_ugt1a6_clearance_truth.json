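{"substrates":[{"substrate_id":"deferiprone_like","mu":0.641853886172395,"sigma_ind":0.385253170159927,"sigma_study":0.25}],"parameter":"clearance","route":"oral","true_cv":0.4,"seed":8}
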