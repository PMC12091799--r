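# Shared fixtures: the six treated scenarios and a few ready-made objects.

p1_high <- patient_preset(1, "high")
all_scenarios <- do.call(rbind, lapply(1:3, function(p)
  data.frame(patient = p, arm = c("high", "low"))))

scenario_list <- lapply(seq_len(nrow(all_scenarios)), function(i)
  patient_preset(all_scenarios$patient[i], all_scenarios$arm[i]))

classical_spec <- fractional_spec(1, 1)

# direct-arithmetic right-hand sides, independent of tumor_rhs, used as the
# oracle for frozen model values
rhs_oracle <- function(x1, x2, p) {
  c(p$alpha1 * x1 * (1 - x1 / p$K1) - p$beta1 * x1 * x2 -
      p$epsilon * p$gamma * x1,
    p$alpha2 * x2 * (1 - x2 / p$K2) - p$beta2 * x1 * x2 - p$gamma * x2)
}

random_state_in_box <- function(n, K1 = 1, K2 = 1, lo = 0.01) {
  cbind(stats::runif(n, lo, K1), stats::runif(n, lo, K2))
}
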