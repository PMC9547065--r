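# The default synthetic bundle is expensive enough to share across test
# files; memoize one instance per option.
.bundle_cache <- new.env(parent = emptyenv())

default_bundle <- function(matrices = TRUE, seed = 1) {
  key <- paste0("b", as.integer(matrices), "_", seed)
  if (is.null(.bundle_cache[[key]])) {
    .bundle_cache[[key]] <- simulate_bundle(
      synthetic_config(make_matrix = matrices), seed = seed)
  }
  .bundle_cache[[key]]
}

# derived analysis layers for the default bundle, shared as well
bundle_layers <- function(b) {
  key <- paste0("layers_", b$seed, "_", is.null(b$matrices))
  if (is.null(.bundle_cache[[key]])) {
    cres <- merge_active_states(b$states)
    proms <- promoter_regions(b$genes, 2500, b$build)
    stitched <- region_signal(stitch(exclude_tss_cres(cres, proms), 12500),
                              b$case_track, b$control_track)
    call <- rose_cutoff(stitched)
    .bundle_cache[[key]] <- list(cres = cres, proms = proms,
                                 stitched = stitched, call = call,
                                 ses = se_regions(call))
  }
  .bundle_cache[[key]]
}
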