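# Restriction enzyme definitions (REBASE-standard recognition sites).
# site: IUPAC pattern, 5'->3' on the top strand.
# cut_offset: top-strand cut position, bases from the 5' end of the site.
enzymes:
  - name: AluI
    site: AGCT
    cut_offset: 2
  - name: Hpy188III
    site: TCNNGA
    cut_offset: 2
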