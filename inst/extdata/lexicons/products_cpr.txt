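# Insulin pen/cartridge product dictionary for the tagging pipeline:
# marketed brand names plus fictional brands used by the synthetic corpus
# generator, plus device-class words.
novolog
novorapid
levemir
flexpen
penfill
novopen
flextouch
actrapid
insulatard
mixtard
pentora
glargix
rapidex
flexitra
pen
pens
cartridge
cartridges
insulin pen
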