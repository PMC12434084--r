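cause,p_hat_observed,p_hat_forecast
C1,0.479,0.452
C2,0.495,0.433
C3,0.490,0.500
C4,0.474,0.471
C5,0.423,0.433
C6,0.459,0.365
C7,0.484,0.509
C8,0.469,0.452
C9,0.469,0.404
C10,0.464,0.452
C11,0.500,0.385
C12,0.536,0.942
C13,0.474,0.481
C14,0.459,0.461
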