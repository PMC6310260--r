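# Reference synthetic study: 13 longitudinal sub-corpora of short tagged
# utterances with Zipfian word frequencies, category-selective carrier
# contexts, homographs, and per-corpus idiosyncratic words.
n_corpora: 13
n_utterances: 3000
vocab_size:
  "N": 120
  "V": 80
  "ADJ": 40
  "ADV": 30
  "FUNCT": 40
zipf_exponent: 1.0
n_templates:
  "N": 4
  "V": 4
  "ADJ": 3
  "ADV": 3
selectivity: 0.75
homograph_rate: 0.05
mean_utterance_length: 5
formulaicity: 0.6
n_idiosyncratic: 4
tag_weights:
  "N": 0.35
  "V": 0.30
  "ADJ": 0.20
  "ADV": 0.15
rng_seed: 1
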