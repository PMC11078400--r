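ALPHABET: A C G T
ORDER: 0
SUBST_MOD: REV
BACKGROUND: 0.300000 0.200000 0.200000 0.300000
RATE_MAT:
  -0.890410 0.136986 0.547945 0.205479
  0.205479 -1.164383 0.136986 0.821918
  0.821918 0.136986 -1.164383 0.205479
  0.205479 0.547945 0.136986 -0.890410
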