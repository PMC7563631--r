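# Standard 26-item User Experience Questionnaire scale map. Item indices
# partition 1..26 into six scales. The polarity flag is +1/-1 per item;
# the bundled default assumes responses already recoded to the -3..+3
# "higher is better" orientation (as in the instrument's analysis sheet),
# hence all +1. Supply a custom map for raw, direction-alternating data.
scales:
  attractiveness: [1, 12, 14, 16, 24, 25]
  perspicuity: [2, 4, 13, 21]
  efficiency: [9, 20, 22, 23]
  dependability: [8, 11, 17, 19]
  stimulation: [5, 6, 7, 18]
  novelty: [3, 10, 15, 26]
polarity: [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
           1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
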