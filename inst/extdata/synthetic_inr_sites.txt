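TCAGTG
CTAGTC
TGAGTT
TTAATT
TCAGTT
TCCGGC
TAGGTC
TGAGTC
TCTCTT
TCAGTG
GCAGTC
CCAGAT
TCAGTC
TCATTT
TCAGTG
TAATGC
TTAGTC
TTTGTT
TGAGGA
TCAGTT
CCAGTT
TAAGTT
TCAGTC
TCAGTT
ACATCT
TCAATC
TCAGTT
TAAGTC
TCAGTC
TCAACC
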