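oil,lipase_id,published_pred_Uml,measured_Uml
Olive oil,L-A1,25.83,27.53
Olive oil,L-A2,27.86,26.52
Olive oil,L-A3,26.43,27.47
Soybean oil,L-A1,28.32,29.21
Soybean oil,L-A2,26.65,28.43
Soybean oil,L-A3,29.45,28.38
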