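marker,innervated,total,n_adults
zn-12,284,311,3
p2rx3a_mCherry,196,228,4
p2rx3b_EGFP,225,228,4
trpa1b_EGFP,217,225,9
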