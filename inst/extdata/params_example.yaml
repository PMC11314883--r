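# Reference fusion parameters for 8-bit epifluorescence pollen stacks.
# Intensity thresholds (threshold0, threshold4) scale with bit depth.
block_h: 15
block_w: 15
threshold0: 60     # confidence: selected-patch max must exceed this
kernel: 2          # voting window radius in blocks -> 5x5 window
threshold1: 40     # index gap that counts as a disagreeing vote
threshold2: 4      # minimum confident voters before replacement
ratio: 0.5         # disagreeing-vote fraction that triggers replacement
threshold3: 10     # block-index gap that opens a pair to information filling
threshold4: 80     # pixels at least this bright are never reassigned
smoothing_sigma: 1
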