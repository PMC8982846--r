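covariate,level,hydrocodone_n,oxycodone_n
age_category,18-24,46361,19749
age_category,25-34,70898,35471
age_category,35-44,61222,29352
age_category,45-54,61827,28325
age_category,55-64,61304,29146
age_category,65-74,32150,16062
age_category,75+,19191,8008
gender,F,190687,95801
gender,M,162266,70312
race_ethnicity,White,258135,123445
race_ethnicity,Black,10910,5473
race_ethnicity,Hispanic,33323,14027
race_ethnicity,Asian-Pacific Islander,8564,3959
race_ethnicity,Other,5598,2310
race_ethnicity,Unknown,36423,16899
insurance,commercial,155868,76540
insurance,medicaid,136672,60300
insurance,medicare,45421,21610
insurance,dual,14854,7599
insurance,unknown,138,64
urbanization,Large central metro,60065,33624
urbanization,Large fringe metro,73610,41016
urbanization,Medium metro,68742,29670
urbanization,Small metro,52546,21073
urbanization,Micropolitan,35776,12842
urbanization,Noncore,5385,1994
urbanization,Unknown,56829,25894
index_year,2015,140357,61713
index_year,2016,120426,56939
index_year,2017,92170,47461
mme_category,<=75,138274,14075
mme_category,76-100,100861,8124
mme_category,101-200,72381,55601
mme_category,201-300,31293,53952
mme_category,>300,10144,34361
days_supply_category,<=3,213278,78753
days_supply_category,4-6,92024,59008
days_supply_category,7+,47651,28352
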