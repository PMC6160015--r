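arm,amount_aud
discount_only,205346
discount_plus_education,133785
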