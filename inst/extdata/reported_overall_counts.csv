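# Nationally reported overall aggregates (as of 2023-09-18 unless dated).
quantity,numerator,denominator
total_encounters,73715269,NA
unique_patients,16058904,NA
female_patients,9025104,16058904
male_patients,7033800,16058904
fmp_units_logged_in,26210,26600
fmp_units_with_encounter,22982,26600
achievement_2021_07,511198,13117900
achievement_2023_01,4508841,19546041
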