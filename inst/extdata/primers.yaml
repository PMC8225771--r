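# Tagged degenerate FTHFS primer pair used for in silico amplicon
# construction. The forward primer carries the fluorophore, so the detected
# terminal fragment is the 5' fragment of the top strand.
primers:
  fwd:
    name: FTHFS_fwd
    seq: CCNACNCCNNNNGGNGANGGNAA
    label: FAM
  rev:
    name: FTHFS_rev
    seq: ATNTTNGCNAANGGNCCNCCNTG
    label: null
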