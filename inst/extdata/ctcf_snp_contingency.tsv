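# Co-occurrence of differential CTCF ChIP-seq binding and differential
# DNase-seq read-count signal at 11,355 CTCF motif sites containing an
# allelic SNP, aggregated over a public allelic-imbalance study of 114
# cell and tissue types from 166 individuals (reported in that study's
# Supplementary Table 11).
# n_signal: sites with differential DNase-seq read-count signal
# n_event:  sites with differential CTCF ChIP-seq binding
# n_both:   sites with both
# n_nosignal_noevent: sites with neither (of the 8,276 without signal)
cell	count
n_total	11355
n_signal	3079
n_event	810
n_both	566
n_nosignal_noevent	8032
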