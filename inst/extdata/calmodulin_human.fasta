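>CaM_human mature calmodulin (CALM1/2/3 identical protein), initiator Met removed
ADQLTEEQIAEFKEAFSLFDKDGDGTITTKELGTVMRSLGQNPTEAELQDMINEVDADGN
GTIDFPEFLTMMARKMKDTDSEEEIREAFRVFDKDGNGYISAAELRHVMTNLGEKLTDEE
VDEMIREADIDGDGQVNYEEFVQMMTAK
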