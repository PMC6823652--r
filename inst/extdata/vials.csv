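name,outer_diameter_mm,inner_diameter_mm
Schott 6R,22,20
5800W,24.5,22
5816W,29.5,27
5303,46.8,42.7
Wheaton 2mL,15,13
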