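"original","low","medium","high"
"low",87,13,2
"medium",47,58,23
"high",25,41,128
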