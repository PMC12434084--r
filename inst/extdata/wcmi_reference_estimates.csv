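cause,label,n,p_hat
C1,DIAMEL,297,0.475
C2,MALNEO,297,0.478
C3,ALZ,297,0.498
C4,INFPNE,297,0.478
C5,CLRD,297,0.431
C6,HD,297,0.431
C7,CD,297,0.498
C8,COVIDUC,297,0.468
C9,SEPTICEMIA,297,0.451
C10,ODRS,297,0.465
C11,NNSN,297,0.464
C12,SSACL,297,0.683
C13,NATCAUSE,297,0.482
C14,ALLCAUSE,297,0.467
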