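n_patients: 1581
seed: 1
gmfcs_probs:
- 0.07463630613535736
- 0.18279569892473119
- 0.37444655281467426
- 0.29728020240354208
- 0.07084123972169513
gmfm_level_means:
- 85.0
- 65.0
- 50.0
- 35.0
- 15.0
gmfm_level_sd: 8.0
age_mean: 8.09999999999999964
age_sd: 4.29999999999999982
age_range:
- 2.20000000000000018
- 25.5
device_profiles:
- code: transtibial_orthosis
  label: Transtibial orthosis
  base_rate: 0.44479999999999997
  score_center: 55.0
  score_width: 22.0
- code: active_wheelchair
  label: Active wheelchair
  base_rate: 0.60729999999999995
  score_center: 35.0
  score_width: 14.0
- code: posterior_walker
  label: Posterior walker
  base_rate: 0.42699999999999999
  score_center: 48.0
  score_width: 12.0
- code: standing_frame
  label: Standing frame
  base_rate: 0.52300000000000002
  score_center: 28.0
  score_width: 12.0
- code: night_splint
  label: Night splint
  base_rate: 0.2248
  score_center: 50.0
  score_width: 20.0
- code: therapy_bike
  label: Therapy bike with training wheels
  base_rate: 0.3805
  score_center: 71.18999999999999773
  score_width: 12.0
- code: shoe_insert
  label: Shoe inserts
  base_rate: 0.31
  score_center: 61.06000000000000227
  score_width: 12.0
- code: roller_board
  label: Roller board
  base_rate: 0.2863
  score_center: 30.28999999999999915
  score_width: 9.0
- code: passive_wheelchair
  label: Passive wheelchair
  base_rate: 0.60980000000000001
  score_center: 26.19999999999999929
  score_width: 9.0
- code: seating_shell
  label: Seating shell
  base_rate: 0.46700000000000003
  score_center: 22.0
  score_width: 12.0
- code: forearm_crutch
  label: Forearm crutches
  base_rate: 0.23999999999999999
  score_center: 58.0
  score_width: 10.0
- code: hand_orthosis
  label: Hand orthosis
  base_rate: 0.10580000000000001
  score_center: 40.0
  score_width: 20.0
subtype_probs_by_level:
- - 0.50050050050050054
  - 0.39839839839839841
  - 0.02502502502502503
  - 0.02502502502502503
  - 0.05105105105105105
- - 0.75800000000000001
  - 0.121
  - 0.017
  - 0.042
  - 0.062
- - 0.82099999999999995
  - 0.035
  - 0.037
  - 0.017
  - 0.09
- - 0.77400000000000002
  - 0.015
  - 0.077
  - 0.011
  - 0.123
- - 0.60699999999999998
  - 0.0
  - 0.223
  - 0.009
  - 0.161
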