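accession,mu_RPHt,mu_RFW,mu_RDW
P47,1,1,1
P48,0.6237,0.8247,0.3539
P52,0.2281,0.7464,0.6238
P15,0.2986,0.615,0.566
P63,0,0.6798,0.3106
P39,0.2821,0.2737,0.2309
P6,0.1977,0.0625,0.0454
P18,0.124,0,0
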