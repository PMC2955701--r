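>mir01
AAACAGGUUUAGUCCUGGACAU
>mir02
GCUUUCUCUACGCAGGUUGCUC
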