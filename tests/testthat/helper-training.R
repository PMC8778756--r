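# The scaled-down training replication: twenty synthetic sessions (mini
# preset), weak labels from each session's own detected optical plateau,
# one stratified 80/10/10 split, and the default network at input side 32.
# Built once and shared between the training-replication and end-to-end
# monitoring tests.

scaled_training_run <- function() {
  fixture("scaled_training", function() {
    seeds <- decellwatch:::derive_seeds(1L, 20L)
    dss <- vector("list", 20L)
    for (i in seq_len(20L)) {
      s <- simulate_session(preset_config("mini", seed = seeds[i]),
                            session_id = sprintf("train%02d", i))
      tr <- spectrometer_trace(s)
      onset <- detect_plateau(tr$value, tr$time_min)$onset_index - 1L
      dss[[i]] <- build_dataset(s, onset, store_side = 32L,
                                frames_per_cycle = 10L)
    }
    splits <- make_splits(combine_datasets(dss), seed = 1L)
    model <- train_classifier(splits,
                              classifier_config(input_side = 32L,
                                                seed = 1L))
    list(model = model, splits = splits,
         eval = evaluate_classifier(model, splits$test))
  })
}
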