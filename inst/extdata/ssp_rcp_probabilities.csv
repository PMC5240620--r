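ssp,RCP2.6,RCP4.5,RCP6.0,RCP8.5
SSP1,0.09,0.45,0.45,0.00
SSP2,0.00,0.09,0.68,0.23
SSP3,0.00,0.17,0.50,0.33
SSP4,0.00,0.37,0.56,0.07
SSP5,0.00,0.07,0.37,0.56
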