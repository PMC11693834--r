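# Small programmatic fixtures.

make_session <- function(characters, predicted = NULL, actual = NULL,
                         participant_id = "p1") {
  n <- length(characters)
  set.seed(1234 + n)
  data.frame(participant_id = participant_id, trial = seq_len(n),
             character_id = as.character(characters),
             predicted_loc = predicted %||% stats::runif(n),
             actual_loc = actual %||% stats::runif(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single-pattern environment (all three characters share one pattern).
uniform_env <- function(noise_sd, hazard) {
  environment_config(list(
    a = pattern_config(noise_sd, hazard, label = "a"),
    b = pattern_config(noise_sd, hazard, label = "b"),
    c = pattern_config(noise_sd, hazard, label = "c")))
}
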