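# shared fixtures, built in code

# clean neonatal test record: 150 bpm, no noise terms
clean_spec <- function(duration_s = 10, seed = 1, ...) {
  synth_spec(fs = 250, duration_s = duration_s, base_hr_bpm = 150,
             seed = seed, ...)
}

# ground-truth peaks visible to the detector (outside the warm-up)
truth_after_warmup <- function(truth, warmup_s = 2) {
  truth$peak_times[truth$peak_times >= warmup_s]
}

# sensitivity / PPV of detected peak times against ground truth
score_detection <- function(detected_s, truth_s, tol_s = 2 / 250) {
  match_events(detected_s, truth_s, tolerance_s = tol_s)
}
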