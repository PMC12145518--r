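# One desk-scale trained model shared across test files (training is the
# expensive step; the end-to-end acceptance check and the synthetic
# difficulty check reuse the same fit).

.desk_cache <- new.env(parent = emptyenv())

desk_experiment <- function() {
  if (!is.null(.desk_cache$fit)) return(.desk_cache$fit)
  preset <- desk_preset(seed = 1L)
  scenes <- simulate_samples(40, preset$scene)
  train <- scenes[1:32]
  heldout <- scenes[33:40]
  model <- fit_papillae(preset$spec, train, preset$training, preset$heatmap)
  .desk_cache$fit <- list(model = model, train = train, heldout = heldout,
                          preset = preset)
  .desk_cache$fit
}
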