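# Example genome layout: one chromosome with a 9.5 Mb inversion.
# Breakpoint coordinates are 0-based half-open (BED-style).
chromosomes:
  - name: chr4
    length: 30000000
inversions:
  - chromosome: chr4
    start: 10000000
    end: 19500000
buffer_bp: 1500000
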