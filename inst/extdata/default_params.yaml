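# Default cohort design and per-genotype behavioral parameters for the
# mouse-agent simulator. These calibration constants are the package's
# reference study conditions; all of them can be overridden via sim_config().
#
# Rates are visits/hour; times are seconds; probabilities are in [0, 1].
#   visit_rate_dark / visit_rate_light : two-level circadian visit rates
#       (lights on 06:00-20:00 = first 14 h of each session day).
#   day1_rate_mult : multiplier on visit rates during the first day in the
#       novel cage (neophobia; < 1 means suppressed day-1 exploration).
#   w_explore   : probability a visit is exploratory (uniform corner) rather
#       than water-seeking (highest-preference corner).
#   alpha       : corner-preference reinforcement per rewarded drink,
#       w_c <- w_c + alpha * (1 - w_c), renormalized.
#   p_drink_fail: probability an animal never learns to drink from the
#       waterspout (zero licks; subject to the 24-h removal rule).
#   licks_per_bout_mean : mean licks per drinking bout, 1 + Poisson(mean-1).
#   p_poke_explore / p_drink_explore : probability an exploratory visit
#       includes a nosepoke / a drink when the door opens.
#   p_attend    : probability of responding during the 7-s SRT cue window.
#   p_impulsive : probability of a premature poke (during the 2-s pre-cue
#       delay) per initiated trial.
#   rt_scale    : mean of the exponential cue-response latency (s),
#       truncated to the 7-s cue window.
#   avoid_learn : per-airpuff multiplicative suppression of the return
#       probability to the airpuff corner (beta).
cohort:
  cages:
    - {n_nontg: 8, n_tg: 8}
seed: 1
params:
  NonTg:
    visit_rate_dark: 6.0
    visit_rate_light: 2.0
    day1_rate_mult: 1.0
    w_explore: 0.60
    alpha: 0.20
    p_drink_fail: 0.13
    licks_per_bout_mean: 20
    p_poke_explore: 0.50
    p_drink_explore: 0.50
    p_attend: 0.80
    p_impulsive: 0.15
    rt_scale: 1.5
    avoid_learn: 0.50
  TG:
    visit_rate_dark: 6.0
    visit_rate_light: 2.0
    day1_rate_mult: 0.60
    w_explore: 0.35
    alpha: 0.20
    p_drink_fail: 0.43
    licks_per_bout_mean: 20
    p_poke_explore: 0.50
    p_drink_explore: 0.50
    p_attend: 0.65
    p_impulsive: 0.15
    rt_scale: 1.5
    avoid_learn: 0.25
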