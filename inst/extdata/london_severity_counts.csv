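severity,frequency
fatal,1670
serious,27788
slight,213324
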