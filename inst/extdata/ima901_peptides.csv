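name,sequence,half_life_h
ADF-1,SVASTITGV,
ADF-2,VMAGDIYSV,
APO-1,ALADGVQKV,
CCN-1,LLGATCMFV,
GUC-1,SVFAGVVGV,
K67-1,ALFDGDPHL,
MET-1,YVDPVITSI,
MUC-1,STAPPVHNV,
RGS-1,LAALPHSCL,
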