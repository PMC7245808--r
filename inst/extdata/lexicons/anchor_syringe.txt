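# Anchor keyword and surface variants.  No stemming anywhere in the
# pipeline: plural forms are listed explicitly.
syringe
syringes
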