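parameter	feature	sign
G.4	beta_amp	-
G.4	gamma_amp	+
G.5	beta_amp	+
G.5	gamma_amp	+
G.6	beta_freq	+
G.6	beta_amp	+
G.7	beta_amp	-
G.7	gamma_freq	+
G.8	beta_amp	+
G.8	gamma_amp	+
G.9	beta_amp	+
G.11	beta_amp	-
G.11	gamma_amp	+
G.12	beta_amp	+
G.12	gamma_amp	+
T.SP	beta_amp	+
T.SP	gamma_amp	-
T.II	beta_amp	-
T.II	gamma_amp	+
T.DP	beta_freq	+
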