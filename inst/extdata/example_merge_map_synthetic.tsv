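old_rsid	current_rsid
rs7920517	rs10993994
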