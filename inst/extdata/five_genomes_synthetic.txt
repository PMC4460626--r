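# Synthetic five-genome worked example over blocks 1..8 (a..h).
# Reconstructed textbook instance; see five_genome_example().
>A
1 2 3 4 5 6 7 8 $
>B
1 -2 3 4 5 6 7 -8 $
>C
1 2 $
3 4 5 6 8 -7 $
>D
3 -5 2 1 $
8 -7 -6 4 $
>E
3 -5 1 2 $
-4 6 7 8 $
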