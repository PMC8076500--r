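# small grids and layouts shared across tests

smallGrid <- function(n = 16L, L = 1, depth = 1, coord = "cartesian",
                      origin = c(0, 0)) {
  buildGrid(gridSpec(n, n, L / n, L / n, origin = origin, depth = depth,
                     coord = coord))
}

centeredGrid <- function(n = 32L, L = 1, depth = 1) {
  buildGrid(gridSpec(n, n, L / n, L / n, origin = c(-L / 2, -L / 2),
                     depth = depth))
}

gaussianField <- function(grid, s0, amp = 1) {
  X <- matrix(grid$xc, grid$nx, grid$ny)
  Y <- matrix(grid$yc, grid$nx, grid$ny, byrow = TRUE)
  amp * exp(-(X^2 + Y^2) / (2 * s0^2)) / (2 * pi * s0^2)
}

uniformVelocity <- function(grid, u = 0, v = 0) {
  list(uf = matrix(u, grid$nx + 1, grid$ny),
       vf = matrix(v, grid$nx, grid$ny + 1))
}

tinyTmeLayout <- function(stage = "early", seed = 7L) {
  generateTmeLayout(stage, n_macrophages = 3, n_tcells = 3, seed = seed)
}
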