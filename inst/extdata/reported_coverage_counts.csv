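# Nationally reported target-population sizes and unique patients screened or
# monitored at least once, per module and track (as of 2023-09-18).
module,track,target_count,covered_count
hypertension,screening,48443467,10820774
hypertension,monitoring,14943378,4083057
obesity,screening,59956288,14640013
obesity,monitoring,769654,383920
diabetes,screening,27450172,6486947
diabetes,monitoring,7588543,2472585
cvd_risk,screening,17276617,3319070
cvd_risk,monitoring,17759500,5078665
older_adult,monitoring,8770474,1056766
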