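# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# the reference 18-cultivar image dataset used by the end-to-end checks
shared_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    spec <- synthetic_spec(images_per_cultivar = 15, image_size = c(48, 48),
                           seed = 42)
    .fixtures$ds <- generate_dataset(spec)
  }
  .fixtures$ds
}

shared_features <- function() {
  if (is.null(.fixtures$ft)) .fixtures$ft <- extract_features(shared_dataset())
  .fixtures$ft
}

tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_cultivars = 3, images_per_cultivar = 2,
                   image_size = c(48, 48), seed = 7)
  do.call(synthetic_spec, utils::modifyList(defaults, args))
}

calibrate_generated <- function(g, spec) {
  calibrate_reflectance(g$image,
                        panel_reference(g$image$panel_region,
                                        spec$panel_reflectance))
}

# flat reflectance-domain image with constant per-band values
flat_image <- function(vals, nr = 12, nc = 12) {
  bands <- lapply(vals, function(v) matrix(v, nr, nc))
  names(bands) <- c("B", "G", "R", "RE", "NIR")
  multispectral_image(bands, domain = "reflectance")
}
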