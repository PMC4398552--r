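# Fixtures built in code; nothing on disk.

make_parent <- function(seq = NULL, parent_id = "p1", len = 102L) {
  if (is.null(seq)) seq <- random_dna(len)
  tibble::tibble(variant_id = paste0(parent_id, "_wt"), parent_id = parent_id,
                 category = "native_wt", window_start = NA_integer_,
                 window_end = NA_integer_, replicate_index = 1L,
                 barcode = NA_character_, variable_region = seq)
}

# A tiny fitted pipeline shared by the eemodel tests; built once per session.
.small_run_cache <- new.env(parent = emptyenv())

small_pipeline_run <- function() {
  if (is.null(.small_run_cache$run)) {
    cfg <- library_config(n_native = 25, n_rsd_groups = 0)
    .small_run_cache$run <- run_pipeline(cfg, seed = 101)
  }
  .small_run_cache$run
}
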