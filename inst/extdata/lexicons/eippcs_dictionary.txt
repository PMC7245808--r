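# EIPPCS phrase dictionary: words and short phrases descriptive of
# extracting insulin from a prefilled pen or cartridge with a syringe.
# Surface inflections listed explicitly (no stemmer).
withdrew
withdraw
withdrawn
withdrawing
drew
drew up
drawn
drawn up
draw
draw up
drawing up
extract
extracted
extracting
mix
mixed
mixing
transfer
transferred
transferring
take
taking
took
inject
injected
injecting
aspirate
aspirated
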