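# Nationally reported monthly encounter targets and performed encounters per
# module and track for January 2023.
module,track,target,performed
hypertension,screening,3868662,789699
hypertension,monitoring,4795117,709004
obesity,screening,4849306,1083414
obesity,monitoring,53770,51512
diabetes,screening,898665,670502
diabetes,monitoring,2128955,279071
cvd_risk,screening,742634,262419
cvd_risk,monitoring,1488004,589523
older_adult,monitoring,720928,73697
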