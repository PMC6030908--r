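# SYNTHETIC default CFD PAM-class penalties; first matching
# pattern of the observed PAM's length wins.
pam	penalty
NGG	1
NAG	0.26
NGA	0.07
NNGRRT	1
TTTV	1
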