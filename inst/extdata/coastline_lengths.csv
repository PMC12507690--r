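basin,sector,length_km
Atlantic,northern_tropical,48831
Atlantic,southern_tropical,18185
IWP,northern_tropical,122730
IWP,southern_tropical,97727
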