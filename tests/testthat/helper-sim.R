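# Deterministic (noise-free) simulation shortcut used across tests.
noiseless_config <- function(..., n_subjects = 60, seed = 11) {
  sim_config(n_subjects = n_subjects, noise_sd = 0, re_sd = 0,
             seed = seed, ...)
}

# Tiny drinking history builder: one row per (subject, visit).
history_row <- function(id, age, sex, days, drinks) {
  data.frame(subject_id = id, age = age, sex = sex,
             lifetime_days = days, max_drinks = drinks,
             stringsAsFactors = FALSE)
}
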