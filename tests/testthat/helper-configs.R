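# Shared miniature configurations: small enough for fast tests, large
# enough to exercise every process.

small_sim_config <- function(seed = 1, mode = "cytoneme", duration = 600,
                             width = 300, height = 300, t_trs = duration,
                             transport_args = list(),
                             dynamics_args = list()) {
  sim_config(
    width = width, height = height, duration = duration, t_trs = t_trs,
    seed = seed,
    transport = do.call(transport_config, c(list(mode = mode),
                                            transport_args)),
    dynamics = do.call(dynamics_config, dynamics_args)
  )
}

# brute-force k nearest occupied sites by full distance sort (oracle)
oracle_knn <- function(lattice, site, k, occupied) {
  xy <- lattice$centers
  d <- sqrt((xy$x - xy$x[site])^2 + (xy$y - xy$y[site])^2)
  idx <- order(d, xy$site)
  idx <- idx[idx != site & occupied[idx]]
  head(idx, k)
}
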