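# Shared fixtures, memoized per test session so expensive objects are
# built once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small ramp volume for I/O tests
ramp_image <- function(dims = c(6L, 5L, 4L), spacing = c(0.5, 0.5, 2.0)) {
  volumetric_image(array(seq_len(prod(dims)) - 1, dim = dims) %% 256,
                   spacing, channel_label = "NP")
}

# canonical phantom world (memoized inside the package as well)
fx_reference <- function() fixture("reference", canonical_reference)

fx_clean_phantom <- function() fixture("clean_phantom", function()
  generate_phantom(42L, deform_amplitude = 7))

fx_template <- function() fixture("template", function()
  phantom_template(n_calib = 8L, seed = 900L))

lm_coords <- function(set) as.matrix(as.data.frame(set)[, c("x", "y", "z")])

# deformable config scaled down for unit tests (documented: unit tests
# exercise correctness, the acceptance suite runs the production-scale
# recovery checks)
fast_deformable <- function(...) {
  args <- list(levels = 4L, iterations_per_level = 120L,
               samples_per_iteration = 1500L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(deformable_config, args)
}

fast_global <- function() {
  cfg <- larvreg_config()$global
  cfg$iterations <- 180L
  cfg$n_samples <- 2000L
  cfg
}
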