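# Annotated costing configuration.
#
# Each setting block supplies the salary input (a fixed monthly salary OR a
# path to a Woreda salary survey), the billable-minutes input (a fixed value
# OR `derive_from_log: true` to measure it from the observation log), and an
# optional explicit uplifted salary-per-minute rate that bypasses the
# campaign-uplift formula.
settings:
  urban:
    salary_month: 1419          # birr/month; alternative: salary_survey_path: path/to/survey.csv
    billable_min_month: 900     # minutes/worker-month; alternative: derive_from_log: true
    rate_uplifted_override: 1.88  # birr/min; omit to use salary/minutes * 1/(1-f)
  rural:
    salary_month: 1513
    billable_min_month: 1600
    rate_uplifted_override: 1.25

# Non-salary cost recovery, as fractions of salary cost. Either explicit
# multipliers (canonical) or national cost shares from which multipliers are
# derived as share/share_salary (the share path warns when shares do not sum
# to 1).
multipliers:
  supplies: 1.88
  management: 0.33
  overhead: 0.49
# cost_shares:
#   salary: 0.27
#   supplies: 0.55
#   management: 0.09
#   overhead: 0.13

campaign_fraction: 0.1742   # fraction of the year lost to seasonal campaigns
exchange_rate: 22           # birr per US$
rounding: half_up           # decimal half-up; birr to 1 decimal, US$ to 2
outlier_rule: one_sided     # drop durations above mean + 3 SD; 'two_sided' also drops below mean - 3 SD
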