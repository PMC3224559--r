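# Historical example: Israeli Defense Forces field hospital, 2010 Haiti
# earthquake. 1111 patients treated over 10 days; the 60-72 bed hospital
# reached capacity before day 2. The capacity-limited model is fitted to
# t1 = 2 d and t99 = 10 d under the constraint t99 - t2 = t1 (tau = 2 d).
# Death rates: background 8/1000/yr after discharge; 8.6% inpatient
# mortality over 15 days (Hanshin-Awaji 1995); surge rate = inpatient rate
# scaled by 0.93/0.07 (Chi-Chi 1999: 7% of fatalities died hospitalized).
name: haiti-2010-idf-field-hospital
model: capacity
n0: 1111
threshold: 0.99
fit:
  t1_days: 2.0
  t99_days: 10.0
  tau_days: 2.0
  branch: ka<kd
deaths:
  omega_s_per_day: 0.07617142857142857
  omega_a_per_day: 0.005733333333333333
  omega_p_per_day: 0.005733333333333333
  omega_d_per_day: 0.00002
grid:
  t_max_days: 12
  dt_days: 0.1
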