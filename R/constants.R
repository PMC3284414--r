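# The five EQ-5D dimensions in the fixed code order, with the letter used
# in dummy-variable names (M2, A3, ...).
eq_dimensions <- c(
  mobility = "M",
  self_care = "S",
  usual_activities = "U",
  pain_discomfort = "P",
  anxiety_depression = "A"
)

eq_dummy_names <- c(paste0(eq_dimensions, "2"), paste0(eq_dimensions, "3"))
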