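# Objects shared across test files, built once per run.
.oxygel_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.oxygel_test_cache[[name]]))
    assign(name, force(expr), envir = .oxygel_test_cache)
  .oxygel_test_cache[[name]]
}

# Default geometry at a coarse working resolution: fast, still resolves every
# region with several cells.
coarse_grid <- function() {
  cached("coarse_grid", build_domain(construct_geometry(), resolution = 0.25))
}

# Default geometry at the production resolution (used by acceptance checks).
fine_grid <- function() {
  cached("fine_grid", build_domain(construct_geometry(), resolution = 0.1))
}

# Small-dish geometry for randomized property sweeps: same topology, far
# fewer cells.
tiny_grid <- function() {
  cached("tiny_grid",
         build_domain(construct_geometry(dish_radius = 6), resolution = 0.5))
}

default_params <- function() cached("default_params", model_parameters())

seeding_20M <- function() cached("seeding_20M", cell_density_map(20e6))
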