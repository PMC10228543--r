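assignment w1 w2 height
T3N-H 118.21 8.31 5.2e6
K4N-H 121.04 8.15 4.8e6
Q5N-H 120.33 8.27 5.0e6
T6N-H 114.91 8.09 4.6e6
A7N-H 125.12 8.22 5.5e6
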