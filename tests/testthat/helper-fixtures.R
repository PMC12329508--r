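# Mesh fixtures built in code.

# Axis-aligned box mesh (12 triangles), watertight.
box_mesh <- function(lx = 10, ly = 10, lz = 10, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = c(0, lx), y = c(0, ly), z = c(0, lz)))
  v <- sweep(v, 2, origin, "+")
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  triangle_mesh(v, f)
}

# UV sphere mesh, becomes watertight after repair (seam/pole vertices merge).
sphere_mesh <- function(r = 2, n = 64, center = c(3, 3, 3)) {
  th <- seq(0, pi, length.out = n + 1)
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)[-(2 * n + 1)]
  np <- length(ph)
  vs <- matrix(c(0, 0, -r), 1, 3)
  for (i in 2:n)
    vs <- rbind(vs, cbind(r * sin(th[i]) * cos(ph),
                          r * sin(th[i]) * sin(ph),
                          -r * cos(th[i]) + 0 * ph))
  vs <- rbind(vs, c(0, 0, r))
  idx <- function(i, j) 1 + (i - 2) * np + ((j - 1) %% np)
  f <- NULL
  for (j in seq_len(np)) f <- rbind(f, c(1, idx(2, j), idx(2, j + 1)))
  for (i in 2:(n - 1)) for (j in seq_len(np))
    f <- rbind(f,
               c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
               c(idx(i, j + 1), idx(i + 1, j), idx(i + 1, j + 1)))
  top <- nrow(vs)
  for (j in seq_len(np)) f <- rbind(f, c(top, idx(n, j + 1), idx(n, j)))
  triangle_mesh(sweep(vs, 2, center, "+"), f)
}

# Height-field mesh with a central hemisphere bump of radius r in a W x W
# plate; analytic surface area = W^2 - pi r^2 + 2 pi r^2.
hemisphere_plate <- function(r = 1, W = 4, h = 0.02) {
  xs <- seq(0, W, by = h)
  X <- matrix(xs, length(xs), length(xs))
  Y <- t(X)
  rr2 <- (X - W / 2)^2 + (Y - W / 2)^2
  zz <- ifelse(rr2 < r^2, -sqrt(pmax(0, r^2 - rr2)), 0)
  heightfield_mesh(xs, xs, zz, bottom_z = r + 1)
}

# Homogeneous slab voxel model with uniform properties.
slab_model <- function(nx, ny, nz, pitch, props) {
  m <- voxel_model(array(3L, dim = c(nx, ny, nz)), pitch)
  assign_properties(m, superficial = props, volumetric = props)
}
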