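# Sentence-scoped negation cues: any of these sharing a sentence with an
# anchor or EIPPCS-dictionary span disqualifies the record.
did not
does not
do not
was not
were not
has not
had not
have not
never
without using
denied
denies
not performed
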