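# Synthetic 30-term emotion lexicon (fear / outrage / conspiracy vocabulary).
# Non-canonical: a small fixture for exercising the emotion-word proxy, not a
# validated sentiment resource.
fear
afraid
scared
terrified
panic
dread
horror
threat
danger
deadly
outrage
outraged
furious
anger
angry
disgusting
shameful
scandal
betrayal
corrupt
conspiracy
coverup
hoax
plot
scheme
secret
agenda
lies
deceit
sheeple
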