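# Action-verb synonym list for the sentence co-occurrence rule: verbs
# which, in the same sentence as the syringe anchor, can describe the
# extraction error.  Inflections listed explicitly.
inject
injects
injected
injecting
administer
administered
administering
use
uses
used
using
withdraw
withdrew
withdrawn
withdrawing
extract
extracted
extracting
draw
drew
drawn
drawing
mix
mixed
mixing
take
taking
took
taken
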