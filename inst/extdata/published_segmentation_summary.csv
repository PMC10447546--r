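model,accuracy,dice,iou,jaccard_distance,precision,recall
U-net,99.46,98.99,99.14,0.0085,99.40,98.57
Res-U-net,98.71,98.38,98.51,0.0148,99.01,97.76
Attention U-net,99.03,98.94,99.13,0.0086,99.03,98.85
DeepLab V3,93.50,93.18,93.72,0.0627,94.35,99.04
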