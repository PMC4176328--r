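gene	intron_type	donor	acceptor	edited_position
NRK	U2	GT	AA	acceptor2
ADARB1	U2	GT	AA	acceptor2
HOOK3	U2	GT	AA	acceptor2
COG8	U2	GT	AA	acceptor2
C14orf37	U2	AT	AG	donor1
NUP210	U12	AT	AG	donor1
CRYZL1	U12	AT	AG	donor1
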