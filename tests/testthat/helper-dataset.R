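# Shared synthetic dataset (20 recordings per class, default profiles,
# fixed seed) with extracted features. Built once per test run; used by the
# simulator-property and end-to-end acceptance tests.
.shared <- new.env(parent = emptyenv())

shared_dataset <- function() {
  if (is.null(.shared$ds)) {
    ds <- simulate_dataset(class_counts = rep(20, 5), seed = 7)
    ds$features <- extract_dataset(ds$recordings, ds$labels)
    .shared$ds <- ds
  }
  .shared$ds
}
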