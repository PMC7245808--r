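# Context exclusion vocabulary: inhaled-insulin clinical-trial reports are
# out of scope for this error; any hit anywhere in retained text
# disqualifies the record.
inhaled insulin
inhaled
inhalation
inhaler
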