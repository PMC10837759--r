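# Nationally reported cumulative screening/monitoring encounter counts per
# disease module (Turkish Disease Management Platform, as of 2023-09-18).
# The older-adult module has no screening track.
module,screening,monitoring
hypertension,13857594,12046449
obesity,18029994,800480
diabetes,8914193,5071646
cvd_risk,4364755,9182814
older_adult,NA,1447344
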