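# one moderately coarse synthetic AVF shared across test files (built once)
.avf_cache <- new.env(parent = emptyenv())

shared_avf <- function() {
  if (is.null(.avf_cache$model)) {
    set.seed(20260920)
    design <- avf_design(artery_length = 60, vein_length = 60,
                         distal_length = 40, mesh_edge_target = 0.8)
    .avf_cache$model <- build_end_to_side_avf(design)
  }
  .avf_cache$model
}
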