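# shared fixtures, all generated in code

# small noiseless straight-bundle phantom with hard edges (exact tensor model)
make_straight_phantom <- function(grid = c(20, 9, 9), radius = 5,
                                  noise_sigma = 0, noise_model = "none",
                                  edge = "hard", seed = 1) {
  spec <- phantom_spec(grid_shape = grid, voxel_size = 2.5,
                       bundle_geometry = list(kind = "straight", radius = radius),
                       noise_sigma = noise_sigma, noise_model = noise_model,
                       edge = edge)
  generate_dwi_phantom(spec, seed = seed)
}

# hand-built 90-degree elbow tensor field: x-aligned tensors for i <= nx/2,
# y-aligned beyond, in a single slab
make_elbow_field <- function(nx = 12, ny = 12, nz = 3, voxel = 2) {
  geom <- grid_geometry(c(nx, ny, nz), voxel)
  D6 <- array(0, c(nx, ny, nz, 6))
  dx <- c(1.6, 0, 0.4, 0, 0, 0.4) * 1e-3          # (Dxx,Dxy,Dyy,Dxz,Dyz,Dzz)
  dy <- c(0.4, 0, 1.6, 0, 0, 0.4) * 1e-3
  for (i in seq_len(nx)) for (j in seq_len(ny)) for (k in seq_len(nz))
    D6[i, j, k, ] <- if (i <= nx / 2) dx else dy
  structure(list(D = D6, geom = geom, unfit = array(FALSE, c(nx, ny, nz))),
            class = "tensor_field")
}

# straight streamline along x at given y offset
straight_streamline <- function(y = 0, z = 0, from = 0, to = 40, by = 1) {
  x <- seq(from, to, by = by)
  structure(cbind(x, y, z), class = "streamline", dimnames = NULL)
}

expect_about <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%.6g within %.3g of %.6g", object, tol, expected))
}
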