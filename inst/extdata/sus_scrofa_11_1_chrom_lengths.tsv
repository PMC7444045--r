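chrom	length_bp
1	274330532
2	151935994
4	130910915
6	170843587
7	121844099
8	138966237
14	141755446
16	79944280
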