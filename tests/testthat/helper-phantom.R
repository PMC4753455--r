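# Shared fixtures, all generated in code.

# small phantom for unit tests (fast); full-size tests build their own spec
small_phantom_spec <- function(seed = 0L, ...)
  phantom_spec(dims = c(64, 48, 20), voxel_size = c(25, 25, 125),
               seed = seed, ...)

# memoize phantoms across test files
.ph_cache <- new.env(parent = emptyenv())
small_phantom <- function() {
  if (is.null(.ph_cache$ph)) .ph_cache$ph <- make_phantom(small_phantom_spec())
  .ph_cache$ph
}
full_phantom <- function() {
  if (is.null(.ph_cache$full)) .ph_cache$full <- make_phantom(phantom_spec())
  .ph_cache$full
}

# smooth textured test volume with an ellipsoidal support (background 0)
textured_volume <- function(d = c(48, 40, 32), vs = c(100, 100, 100)) {
  xs <- (seq_len(d[1]) - 0.5) / d[1]
  ys <- (seq_len(d[2]) - 0.5) / d[2]
  zs <- (seq_len(d[3]) - 0.5) / d[3]
  X <- array(rep(xs, d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  r2 <- ((X - 0.5) / 0.42)^2 + ((Y - 0.5) / 0.42)^2 + ((Z - 0.5) / 0.45)^2
  tex <- 120 + 50 * sin(8 * pi * X) * cos(6 * pi * Y) +
    40 * sin(5 * pi * Z + 2 * pi * X) + 60 * exp(-2 * r2)
  tex[r2 > 1] <- 0
  volume(tex, vs, "mri")
}

# textured 2D image for section-registration tests
textured_image <- function(nx = 120, ny = 100) {
  xs <- seq_len(nx) - 0.5
  ys <- seq_len(ny) - 0.5
  outer(xs, ys, function(x, y)
    100 + 60 * sin(x / 9) * cos(y / 7) +
      40 * exp(-((x - nx / 2)^2 + (y - ny / 2)^2) / 800))
}

# warp a volume through an arbitrary coordinate mapping (ground-truth warps)
warp_volume <- function(vol, fun, mode = 0L, bg = 0) {
  pts <- voxel_centers(vol)
  dst <- fun(pts)
  vals <- histo3d:::.cpp_interp3(as.numeric(vol$data), dim(vol$data)[1:3],
                                 dst, unname(vol$voxel_size), mode, 1L, bg)
  volume(array(vals, dim(vol$data)[1:3]), unname(vol$voxel_size), vol$modality)
}
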