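# The end-to-end and mechanism acceptance checks share one trained desk-scale
# pipeline (training it takes a few minutes); it is built lazily and cached
# for the duration of the test run. Seed fixed at 42.

.pipeline_cache <- new.env(parent = emptyenv())

get_trained_pipeline <- function() {
  if (is.null(.pipeline_cache$result)) {
    dir <- file.path(tempdir(), "gleasonmil-acceptance-run")
    cfg <- run_config(seed = 42, out_dir = dir)
    message("training the shared desk-scale pipeline (seed 42) ...")
    .pipeline_cache$result <- run_pipeline(cfg, mechanism = TRUE)
  }
  .pipeline_cache$result
}
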