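# SYNTHETIC CFD-style PAM activity fractions keyed by PAM positions 2-3
# (NGG = 1). Stand-in values; same schema as the published PAM table.
dinucleotide	penalty
AA	0.01
AC	0.01
AG	0.26
AT	0.01
CA	0.01
CC	0.01
CG	0.11
CT	0.01
GA	0.07
GC	0.02
GG	1
GT	0.05
TA	0.01
TC	0.01
TG	0.05
TT	0.01
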