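CC  Default disintegrin motif blocks: the integrin-binding triads seen in
CC  salivary/venom disintegrins (RGD, KGD, KTS, RTS, RED), plus variants
CC  requiring a cysteine within 10 residues on each side of the triad
CC  (the pair that can staple the presenting hairpin). Supply your own
CC  PROSITE-format file to replace these defaults.
ID  DISINTEGRIN_RGD; PATTERN.
PA  R-G-D.
//
ID  DISINTEGRIN_KGD; PATTERN.
PA  K-G-D.
//
ID  DISINTEGRIN_KTS; PATTERN.
PA  K-T-S.
//
ID  DISINTEGRIN_RTS; PATTERN.
PA  R-T-S.
//
ID  DISINTEGRIN_RED; PATTERN.
PA  R-E-D.
//
ID  DISINTEGRIN_RGD_CFLANK; PATTERN.
PA  C-x(0,9)-R-G-D-x(0,9)-C.
//
ID  DISINTEGRIN_KGD_CFLANK; PATTERN.
PA  C-x(0,9)-K-G-D-x(0,9)-C.
//
ID  DISINTEGRIN_KTS_CFLANK; PATTERN.
PA  C-x(0,9)-K-T-S-x(0,9)-C.
//
ID  DISINTEGRIN_RTS_CFLANK; PATTERN.
PA  C-x(0,9)-R-T-S-x(0,9)-C.
//
ID  DISINTEGRIN_RED_CFLANK; PATTERN.
PA  C-x(0,9)-R-E-D-x(0,9)-C.
//
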