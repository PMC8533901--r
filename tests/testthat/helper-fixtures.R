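# Shared fixtures: noise-free template features and small sequences.

# A feature row for a given stage, built from the default templates.
template_row <- function(stage, noise = 0, cfg = cohort_config(feature_noise = noise)) {
  simulate_features_from_stages(stage_to_vigilance(stage), cfg)
}

# Balanced block sequence covering all seven stages, active wakefulness
# first (so the stage-0 block carries no drowsiness context).
balanced_codes <- function(per_stage = 40) {
  rep(7:1, each = per_stage)
}

# Feature table for a vector of vigilance codes at a given noise level.
features_for <- function(codes, noise = 0) {
  cfg <- cohort_config(feature_noise = noise)
  simulate_features_from_stages(codes, cfg)
}

# Bare-bones segment list for classify_segment().
seg <- function(alpha, dt, sem = FALSE, graph = FALSE) {
  list(alpha_o = alpha[1], alpha_p = alpha[2], alpha_t = alpha[3],
       alpha_f = alpha[4], dt_o = dt[1], dt_p = dt[2], dt_t = dt[3],
       dt_f = dt[4], sem = sem, graph = graph)
}

# The 15 Table-style dimension x metric p-values of the reference analysis
# (inputs for internal-consistency checks of the multiple-testing stack).
reference_p15 <- function() {
  c(0.170, 0.025, 0.027, 0.561, 0.624,   # mean vigilance
    0.515, 0.038, 0.009, 0.791, 0.913,   # stability score
    0.972, 0.003, 2e-4, 0.496, 0.399)    # slope index
}
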