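library_id	condition_id	stressor	dose	dose_mM	time_min	replicate
none_t30_r1	none	none	none	0	30	1
butanol_low_t30_r1	butanol_low	butanol	low	30	30	1
butanol_medium_t30_r1	butanol_medium	butanol	medium	60	30	1
butanol_high_t30_r1	butanol_high	butanol	high	90	30	1
butyrate_low_t30_r1	butyrate_low	butyrate	low	30	30	1
butyrate_medium_t30_r1	butyrate_medium	butyrate	medium	40	30	1
butyrate_high_t30_r1	butyrate_high	butyrate	high	50	30	1
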