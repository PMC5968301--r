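# Registry of taxonomic groups: sets of species whose 16S rRNA sequences are
# nearly identical (>99.9% for the pumilus group) and therefore unresolvable
# by that marker alone. Membership is configuration, not code.
groups:
  pumilus_group:
    - Bacillus pumilus
    - Bacillus safensis
    - Bacillus australimaris
    - Bacillus zhangzhouensis
  cereus_group:
    - Bacillus cereus
    - Bacillus thuringiensis
    - Bacillus anthracis
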