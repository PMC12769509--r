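# Synthetic stand-in for per-length mono-A indel rate estimates at L = 1..8
# (expansion / contraction / non-motif insertion, per target per generation).
# Constructed from printed constraints, not measured data; see
# ?empirical_rates_mono_a and the methods vignette.
tract_length_units	expansion	contraction	non_motif_insertion
1	2e-11	0	0
2	3e-11	1.5e-11	3e-13
3	5e-11	3e-11	5e-13
4	8e-11	5e-11	8e-13
5	2.5e-10	1.6e-10	2.5e-12
6	1e-09	6.4e-10	1e-11
7	4e-09	2.6e-09	4e-11
8	1.1e-08	7e-09	1.1e-10
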