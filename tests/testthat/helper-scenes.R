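# Small shared fixtures for fast tests: one deterministic scene + stack.
tiny_scene <- function(seed = 7L, height = 120L, width = 120L, n_cells = 10L) {
  generate_micrograph(scene_config(height = height, width = width,
                                   n_cells = n_cells, seed = seed))
}

tiny_stack <- function(scene, n_members = 25L, seed = 3L, ...) {
  generate_cmp_stack(scene, noise_config(n_members = n_members, seed = seed,
                                         ...))
}

grid_truth <- function(scene, stack) {
  pm <- probability_map(stack$values[, , 1L])
  attr(pm, "grid_rows") <- attr(stack, "grid_rows")
  attr(pm, "grid_cols") <- attr(stack, "grid_cols")
  mask_on_grid(scene$mask, pm)
}
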