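# Small phantoms shared across test files: coarse grid keeps unit tests fast.

small_geometry <- function(...) {
  phantom_geometry(grid_size = 96L, pixel_spacing = 2, n_slices = 2L,
                   endo_radius = 18, epi_radius = 28, ...)
}

small_config <- function(field = "1.5T", phase = "acute", ...) {
  subject_config(field = field, phase = phase, geometry = small_geometry(), ...)
}

# one-slice image stack from a matrix
as_stack <- function(m) array(m, dim = c(dim(m), 1L))
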