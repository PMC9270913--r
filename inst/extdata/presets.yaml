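# Task and agent presets for the firefly navigation simulator.
# Values not listed fall back to the sim_config()/agent_params() defaults.
config:
  monkey_default:
    target_r_range: [1.0, 4.0]
    target_theta_range: [-35.0, 35.0]
    pert_profile: gaussian
    obs_noise_base_sd: [0.4, 12.0]
  human_default:
    target_r_range: [1.0, 6.0]
    target_theta_range: [-40.0, 40.0]
    pert_profile: triangular
    obs_noise_base_sd: [0.4, 12.0]
  human_flow:
    target_r_range: [3.0, 3.0]
    target_theta_range: [-30.0, 30.0]
    pert_profile: triangular
    obs_noise_base_sd: [0.4, 12.0]
    max_trial_duration: 20.0
agent:
  integrator:
    lambda_sensory: 1.0
  dead_reckoner:
    lambda_sensory: 0.0
    assumed_gain: 1.0
    max_linear_command: 0.5
    stop_distance: 0.05
  ideal:
    lambda_sensory: 1.0
    stop_distance: 0.05
  flow_prior:
    lambda_sensory: 0.8
    prior_mean_speed: 0.3
    prior_weight: 2.0
    prior_cv: 0.5
    k_angular: 0.8
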