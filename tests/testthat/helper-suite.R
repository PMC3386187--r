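# Shared end-to-end run suite for the pipeline-level tests: ten full
# pipeline runs of the default generator (one image per stage, 20 + 20
# ROIs per image) under master seeds 1..10, computed once per session.

.suite_env <- new.env(parent = emptyenv())

pipeline_suite <- function(seeds = 1:10) {
  key <- paste0("suite_", paste(seeds, collapse = "_"))
  if (!is.null(.suite_env[[key]])) return(.suite_env[[key]])
  runs <- lapply(seeds, function(seed) {
    cfg <- pipeline_config(n_per_stage = 1L, master_seed = seed)
    out_dir <- file.path(tempdir(), sprintf("ilpcitex-suite-%d", seed))
    res <- suppressMessages(run_pipeline(cfg, out_dir))
    unlink(out_dir, recursive = TRUE)
    res
  })
  names(runs) <- paste0("seed", seeds)
  .suite_env[[key]] <- runs
  runs
}
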