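# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# default 64 mm template (noise sd 5)
fix_template <- function() {
  cached("tpl64", function() make_template(template_spec(seed = 1)))
}

# small 48 mm template for cheaper tests
fix_template48 <- function() {
  cached("tpl48", function()
    make_template(template_spec(grid_shape = c(48, 48, 48), seed = 1)))
}

# noiseless 48 mm template (exact tissue intensities)
fix_template48_clean <- function() {
  cached("tpl48c", function()
    make_template(template_spec(grid_shape = c(48, 48, 48), noise_sd = 0,
                                seed = 1)))
}

dice_coef <- function(a, b) {
  a <- as.vector(a) > 0
  b <- as.vector(b) > 0
  2 * sum(a & b) / (sum(a) + sum(b))
}

# build a svd_colour object directly from colour rows and per-colour counts
colour_instance <- function(cols, counts) {
  red <- rep(cols[, 1], counts)
  green <- rep(cols[, 2], counts)
  dm <- c(length(red), 1L, 1L)
  structure(list(red = array(as.integer(red), dm),
                 green = array(as.integer(green), dm),
                 blue = array(0L, dm),
                 brain_mask = array(1L, dm),
                 voxel_size = c(1, 1, 1),
                 affine = diag(4)),
            class = "svd_colour")
}
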