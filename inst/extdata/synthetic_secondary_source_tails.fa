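>chr7_tail synthetic reconstruction of the founder poly(A) tail region
AAAAAAAAAACCAAAACAAAAAAAAAATTTTGAGTCAAGGTC
>chr17_tail synthetic reconstruction of the youngest offspring tail region
AAAAAAAAAAAAAAAAAAAAAAAAAAAAAATTTTCAGGCTAG
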