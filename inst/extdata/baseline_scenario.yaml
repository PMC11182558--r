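# gpsim scenario file: all quantities in persons and days
schema: 1  # scenario schema version
lambda1: 0.20000000000000001  # government-response effect (fraction, 0-1)
lambda2: 0.20000000000000001  # emotional-guidance effect (fraction, 0-1)
lambda3: 0.40000000000000002  # heat-reduction effect (fraction, 0-1)
lambda4: 0.90000000000000002  # event-coupling effect (fraction, 0-1)
lambda5: 0.20000000000000001  # user risk propensity (fraction of entrants, 0-1)
lambda6: 0.5  # information uncertainty (fraction, 0-1)
T_c: 2  # opinion-conversion time (days)
T_e: 6  # extreme-opinion formation time (days)
T_ef: 7  # extreme-opinion extinction time (days)
T_pi: 3  # positive-opinion interaction time (days)
T_ni: 1  # negative-opinion interaction time (days)
S0: 100  # initial user pool (persons)
horizon: 100  # simulation horizon (days)
dt: 0.025000000000000001  # Euler step size (days)
mode: meanfield  # meanfield | stochastic
seed: 1  # RNG seed (integer; stochastic mode)
strict_integer: false  # floor opinion allocations to whole persons
epsilon: 0.0000000010000000000000001  # denominator guard while NE = 0 (persons)
heat_threshold: 1  # NE level that latches heat reduction on (persons)
ratio_cap: 10  # cap on the NIN/NE escalation ratio
delay_fraction: 0.5  # fraction of entrants present at t = 0
entry_time: 3  # mean delayed-entry time (days)
exit_scale_days: 365  # lifecycle exit-hazard scale (days)
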