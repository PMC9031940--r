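# Shared study configuration for the analysis scripts (sourced, not run).
#
# The study emulates an annotated scalp EEG recording session at desk scale:
# 8 bipolar channels at 256 Hz, one hour of signal, six seizures of ~30 s,
# with ictal rhythms planted on two channel/band combinations so that a
# known set of amplitude features is genuinely discriminative. Downstream
# settings follow the package defaults: 0.5 Hz high-pass, 60 Hz notch,
# 2-s epochs with 50% ictal overlap, 9:1 rebalancing, five sub-bands,
# 0.95 correlation pruning, and the six ranking methods paired with a
# 150-tree random forest.

library(ictalfs)

study_seed <- 20260401

study_synth_config <- function() {
  synth_config(
    n_channels = 8, fs = 256, duration = 3600,
    n_seizures = 6, seizure_duration = 30, seizure_jitter = 5,
    ictal_spec = data.frame(
      channel = c(1L, 4L),
      band = c("delta", "alpha"),
      gain = c(45, 35),
      freq_hz = c(3, 10)
    ),
    seed = study_seed
  )
}

study_preprocess_config <- function() preprocess_config(seed = study_seed + 1)
study_feature_config <- function() feature_config("fs1")
study_fsm_config <- function() fsm_config(seed = study_seed + 2)
study_classifier <- function() classifier_config("RF", seed = study_seed + 3)

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)
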