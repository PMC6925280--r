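quantity	value
cohort_n	407388
derivation_n	11995
derivation_is_events	888
derivation_as_events	2065
validation_n	395393
validation_prevalent_is	1152
validation_incident_is	1923
validation_prevalent_as	4543
validation_incident_as	2607
validation_excl_prevalent_n	390849
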