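# shared fixtures for the archflow test suite

blood <- fluid_properties()

# smooth random periodic traction series (low-order Fourier sum per
# component), sampled on n+1 closed-period points; `factor` oversamples
make_fourier_wss <- function(seed, n = 200, n_modes = 3, factor = 1) {
  set.seed(seed)
  coefs <- lapply(1:3, function(k)
    list(a0 = stats::rnorm(1, 0, 1),
         a = stats::rnorm(n_modes, 0, 0.5),
         b = stats::rnorm(n_modes, 0, 0.5)))
  nn <- n * factor
  t <- seq(0, 1, length.out = nn + 1)
  tr <- array(0, dim = c(1, 3, nn + 1))
  for (k in 1:3) {
    v <- rep(coefs[[k]]$a0, length(t))
    for (m in seq_len(n_modes))
      v <- v + coefs[[k]]$a[m] * cos(2 * pi * m * t) +
        coefs[[k]]$b[m] * sin(2 * pi * m * t)
    tr[1, k, ] <- v
  }
  wall_shear_field(tr, times = t, facet_area = 1)
}

# nodal linear-shear (plane Couette) flow field on a mesh: u_x = gdot * y
couette_field <- function(mesh, gdot) {
  N <- nrow(mesh$nodes)
  U <- array(0, dim = c(N, 2, 1))
  U[, 1, 1] <- gdot * mesh$nodes[, 2]
  flow_field(0, U, matrix(0, N, 1))
}
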