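# Synthetic U-rich hexamer position weight matrix (consensus UUUUAU),
# shaped like a CPEB-family binding element. For examples and tests only;
# not an experimentally determined motif. Rows A,C,G,U; columns 1-6.
A 0.05 0.05 0.05 0.05 0.85 0.05
C 0.05 0.05 0.05 0.05 0.05 0.05
G 0.05 0.05 0.05 0.05 0.05 0.05
U 0.85 0.85 0.85 0.85 0.05 0.85
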