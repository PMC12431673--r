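# shared small fixtures, built once per test run

# cross-block cache for expensive sweep results
acceptanceCache <- new.env(parent = emptyenv())

smallGrid <- function(nx = 21L, nz = 40L, dx = 0.5, dz = 0.5)
  voxelGrid(nx = nx, ny = nx, nz = nz, dx = dx, dz = dz)

# cuboid scene with known geometry
cuboidScene <- function(topDepth = 3, muA = 0.0045, muSp = 1,
                        cTumor = 5, cBackground = 0.5, nx = 21L) {
  exampleScene(nx = nx, nz = 40L, muA = muA, muSp = muSp,
               topDepth = topDepth, size = 4L, thickness = 8L,
               cTumor = cTumor, cBackground = cBackground)
}

# three-phase sinusoid frames with known modulation
sinusoidFrames <- function(m0 = 100, m = 0.42, fx = 0.1, n = 24,
                           phase0 = 0) {
  x <- outer(rep(1, n), (seq_len(n) - 1) * 0.5)
  lapply(phase0 + c(0, 2 * pi / 3, 4 * pi / 3), function(ph)
    m0 * (1 + m * cos(2 * pi * fx * x + ph)))
}
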