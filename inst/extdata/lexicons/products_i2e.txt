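# Product dictionary of the pattern-rule cascade.  Deliberately omits the
# FlexTouch brand and its fictional analogue "flexitra": records whose only
# product is one of those are not retrieved, reproducing a documented
# product-coverage miss of the original query.
novolog
novorapid
levemir
flexpen
penfill
novopen
actrapid
insulatard
mixtard
pentora
glargix
rapidex
pen
pens
cartridge
cartridges
insulin pen
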