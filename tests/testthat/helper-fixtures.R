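## Shared fixtures, built in code at test time.

## small protocol: one shell of the ex-vivo ActiveAx parameters with a few
## directions, cheap enough for unit tests
tiny_protocol <- function(n_dirs = 6, G = 0.14, delta = 0.010, Delta = 0.016,
                          TE = 0.054) {
  dirs <- mcdsim:::repulsion_directions(n_dirs, iterations = 50)
  tab <- data.frame(gx = dirs[, 1], gy = dirs[, 2], gz = dirs[, 3],
                    G = G, Delta = Delta, delta = delta, TE = TE)
  pgse_protocol(tab, label = "tiny")
}

## one cylinder centered in its voxel
single_cylinder <- function(radius, pad = 1.05) {
  side <- 2 * radius * pad
  cylinder_population(matrix(c(side / 2, side / 2), 1, 2), radius,
                      voxel_side = side, periodic = FALSE)
}

## unit cube mesh (8 vertices, 12 triangles, outward-oriented), side in m
cube_mesh <- function(side = 1e-6, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  v <- sweep(v, 2, origin, "+")
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = side
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = side
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = side
  m <- trimesh(v, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}
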