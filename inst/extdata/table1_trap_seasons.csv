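# Adult assessment fixture: Cheboygan River system study streams (Pigeon,
# Sturgeon, Maple), spawning years 2013-2022, transcribed from the published
# decade-long sterile-male-release assessment.
# Columns beyond the raw counts carry published-table context:
#   wild_males_observed - sexed wild-male count where the published ratio
#     implies captures were sexed (Sturgeon 2022: 2 of 3).
#   abundance_override  - the study's independently derived abundance estimate,
#     used where the Petersen estimate is unavailable (no-release years) or
#     differs from the published value (Pigeon 2017/2021/2022, Maple 2021).
#   ratio_censored_at   - bound of right-censored published ratios (">40:1").
#   ambiguous           - published arithmetic internally inconsistent;
#     excluded from integer-exact tests.
stream,year,sterile_released,sterile_recaptured,wild_captured,wild_males_observed,abundance_override,ratio_censored_at,ambiguous
Pigeon,2013,0,NA,2,,21,,FALSE
Pigeon,2014,0,NA,0,,,,FALSE
Pigeon,2015,0,NA,1,,10,,FALSE
Pigeon,2016,0,NA,0,,,,FALSE
Pigeon,2017,1425,413,2,,8,,TRUE
Pigeon,2018,1338,428,4,,12,,TRUE
Pigeon,2019,360,72,1,,5,,TRUE
Pigeon,2020,0,NA,0,,,,FALSE
Pigeon,2021,275,28,9,,90,,FALSE
Pigeon,2022,525,74,15,,110,,FALSE
Sturgeon,2013,0,NA,1,,10,,FALSE
Sturgeon,2014,0,NA,0,,,,FALSE
Sturgeon,2015,0,NA,0,,,,FALSE
Sturgeon,2016,0,NA,0,,,,FALSE
Sturgeon,2017,1425,399,1,,1,,TRUE
Sturgeon,2018,1350,257,1,,,,FALSE
Sturgeon,2019,908,163,6,,,,FALSE
Sturgeon,2020,0,NA,0,,,,FALSE
Sturgeon,2021,528,23,0,,,40,FALSE
Sturgeon,2022,1400,70,3,2,,,FALSE
Maple,2013,0,NA,1,,5,,FALSE
Maple,2014,0,NA,2,,26,,FALSE
Maple,2015,0,NA,2,,23,,FALSE
Maple,2016,0,NA,0,,,,FALSE
Maple,2017,830,498,0,,,40,FALSE
Maple,2018,813,203,0,,,40,FALSE
Maple,2019,628,44,0,,,40,FALSE
Maple,2020,0,NA,1,,,,FALSE
Maple,2021,666,53,1,,5,40,FALSE
Maple,2022,1400,70,0,,,40,FALSE
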