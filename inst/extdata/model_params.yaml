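# Model parameters for the Barrett's-esophagus LGD management model.
#
# Annual rates (rate_*) are converted to per-cycle probabilities on the
# 6-month cycle grid; p_*/frac_* are per-cycle or per-procedure
# probabilities; costs in 2023 Australian dollars; utilities per year of
# full health; disutilities per procedure.
#
# rate_lgd_prog_index / rate_lgd_prog_surv / rate_lgd_revert /
# rate_nd_recur are calibrated so an all-LGD cohort reproduces the
# surveillance targets (progression 1.0 and 2.2 per 100 person-years;
# course proportions 0.690 / 0.198 / 0.112); see calibrate().
# Parameters listed under `placeholders` are literature-informed stand-ins
# pending published local values; they are flagged on load.
model:
  cycle_length: 0.5
  horizon: 35
  discount_rate: 0.05
  wtp: 50000
start_distribution:
  LGD_index: 0.52
  LGD_surv: 0.48
params:
  rate_lgd_prog_index: 0.01355
  rate_lgd_prog_surv: 0.03798
  rate_lgd_revert: 0.29764
  rate_nd_recur: 0.05893
  rate_nd_prog: 0.006457
  rate_hgd_to_eac: 0.10
  rate_postrfa_recur: 0.08
  rate_postrfa_prog: 0.006
  rate_postemr_recur: 0.10
  rate_postemr_prog: 0.012
  rate_eac_t1a_progress: 0.10
  rate_eac_t1a_death: 0.02
  rate_eac_adv_death: 0.45
  rate_mortality_other: 0.011
  p_rfa_success: 0.90
  p_hgd_rfa: 0.85
  p_t1a_treat: 0.90
  p_rfa_complication: 0.05
  frac_prog_to_eac: 0.348
  frac_eac_t1a: 0.60
  cost_endoscopy: 1500
  cost_rfa: 6000
  cost_rfa_complication: 5000
  cost_emr: 8000
  cost_eac_advanced_care: 90000
  cost_eac_advanced_cycle: 2000
  u_ndbe: 0.95
  u_lgd: 0.93
  u_hgd: 0.90
  u_eac_t1a: 0.87
  u_eac_advanced: 0.67
  u_post_rfa: 0.95
  u_post_emr_rfa: 0.93
  du_rfa: 0.05
  du_emr: 0.05
placeholders:
  - rate_hgd_to_eac
  - rate_postrfa_recur
  - rate_postrfa_prog
  - rate_postemr_recur
  - rate_postemr_prog
  - rate_eac_t1a_progress
  - rate_eac_t1a_death
  - rate_eac_adv_death
  - rate_mortality_other
  - p_rfa_success
  - p_hgd_rfa
  - p_t1a_treat
  - p_rfa_complication
  - frac_eac_t1a
  - cost_endoscopy
  - cost_rfa
  - cost_rfa_complication
  - cost_emr
  - cost_eac_advanced_care
  - cost_eac_advanced_cycle
  - u_ndbe
  - u_lgd
  - u_hgd
  - u_eac_t1a
  - u_eac_advanced
  - u_post_rfa
  - u_post_emr_rfa
  - du_rfa
  - du_emr
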