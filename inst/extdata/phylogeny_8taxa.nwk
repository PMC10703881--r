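(((human:20,(nomascus:5,hylobates:5):15):5,rhesus:25):55,((mouse:3,(caroli:2,pahari:2):1):12,rat:15):65);
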