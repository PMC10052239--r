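# shared fixtures, built once per test run and memoized

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small random cube with a guaranteed black border pixel
small_cube <- function(seed = 1, h = 6, w = 5, k = 8) {
  set.seed(seed)
  vals <- array(runif(h * w * k), dim = c(h, w, k))
  vals[1, 1, ] <- 0
  msi_cube(vals, seq_len(k) * 10 + 100, pixel_size = 10, "lipid_neg")
}

# fast small phantom for unit tests (reduced widths, no misalignment)
tiny_phantom <- function() {
  cached("tiny_phantom", function()
    make_phantom(phantom_spec(grid = c(32, 32), upscale = 2,
                              block_widths = c(30, 24, 12), n_features = 3,
                              feature_diameter = c(40, 60),
                              misalign = "none", seed = 11)))
}

# 128 x 128 single-modality structured phantom for registration tests
registration_phantom <- function() {
  cached("registration_phantom", function()
    make_phantom(phantom_spec(grid = c(128, 128), upscale = 1,
                              n_features = 10, block_widths = c(40, 30, 20),
                              misalign = "none", seed = 1)))
}

# default-spec phantom (the stated world of the acceptance criteria)
default_phantom <- function(...) {
  args <- list(...)
  key <- paste0("default_phantom_", paste(names(args), unlist(args),
                                          collapse = "_"))
  cached(key, function()
    do.call(make_phantom,
            list(do.call(phantom_spec,
                         utils::modifyList(list(misalign = "none"), args)))))
}

# landmarks + control points used across registration tests
reg_landmarks <- function() {
  list(control = cbind(x = c(40, 90, 64, 50, 80),
                       y = c(40, 40, 90, 70, 70)),
       eval = cbind(x = c(30, 100, 64, 45, 85),
                    y = c(30, 95, 64, 80, 45)))
}

# a random affine perturbation within the stated recovery envelope
random_perturbation <- function(seed, center = c(64.5, 64.5)) {
  set.seed(seed)
  affine_from_params(tx = runif(1, -20, 20), ty = runif(1, -20, 20),
                     rotation = runif(1, -10, 10) * pi / 180,
                     sx = runif(1, 0.95, 1.05), sy = runif(1, 0.95, 1.05),
                     center = center)
}

# a fast pipeline configuration: small grid, few variables
fast_config <- function(dir, seed = 0) {
  pipeline_config(dir, seed = seed,
                  simulate = list(enabled = TRUE, grid = c(32, 32),
                                  upscale = 2, block_widths = c(24, 18, 10),
                                  n_features = 3,
                                  feature_diameter = c(40, 60)),
                  fuse = list(enabled = TRUE, max_ions = 2, n_comp = 4))
}

dice_overlap <- function(a, b, q = 0.5) {
  ia <- a > q * max(a); ib <- b > q * max(b)
  2 * sum(ia & ib) / (sum(ia) + sum(ib))
}
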