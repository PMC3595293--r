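label	forward	reverse
limnohabitans_its	GMAAGYCTGATCCAGCCATT	TTAKTCACTTGACCCTATAACTTTGA
universal_its	TGYACACACCGCCCGT	GGGTTBCCCCATTCRG
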