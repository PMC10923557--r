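parish,fertility_weight,note
Birstall,0,omitted from marital fertility rates (no FRFs for childless families); half weight in analyses not involving childless couples
Shepshed,0.5,half weight to better approximate the occupational structure of England
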