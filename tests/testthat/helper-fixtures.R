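# Frozen checksum of the transcribed reference tables (see
# fixture_checksum()); recompute only when the fixtures are deliberately
# corrected.
FIXTURE_CHECKSUM <- 1720863706
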