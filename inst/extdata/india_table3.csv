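outcome,enci,se
immunisation,0.1640,0.0056
food_security,-0.0548,0.0059
nutrition,-0.2314,0.0048
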