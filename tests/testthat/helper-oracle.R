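# Brute-force density-matrix oracle for the real-time chunked acquisition
# on a weakly coupled two-spin pair. Independent of the closed-form
# synthesis path: propagates the full 4x4 density matrix in small time
# steps under the secular weak-coupling Hamiltonian, applying the
# decoupling element (hard pi on both spins followed by a selective pi on
# the active spin) instantaneously at each chunk boundary. Detection is
# Tr(A+ sigma)/2 for the active spin A (the 1/2 removes the passive-spin
# state multiplicity).

oracle_ops <- local({
  I2 <- diag(2)
  sz <- matrix(c(0.5, 0, 0, -0.5), 2)
  raise2 <- matrix(c(0, 0, 1, 0), 2)  # |beta> -> |alpha>
  rx2 <- function(theta) {
    matrix(c(cos(theta / 2), -1i * sin(theta / 2),
             -1i * sin(theta / 2), cos(theta / 2)), 2, byrow = TRUE)
  }
  list(
    Az = kronecker(sz, I2), Pz = kronecker(I2, sz),
    Ap = kronecker(raise2, I2), Am = kronecker(t(raise2), I2),
    Rhard = kronecker(rx2(pi), rx2(pi)),
    Rsel_active = kronecker(rx2(pi), I2)
  )
})

# Detected signal of the ACTIVE spin (frequency nu_a Hz) coupled to a
# passive spin at nu_p with coupling j_hz, over n_chunks chunks of
# chunk_s seconds sampled at sw Hz. Relaxation is not propagated (apply
# exp(-t/T2) outside). dt is the propagation step (<= 10 us).
oracle_zs_fid <- function(nu_a, nu_p, j_hz, n_chunks, chunk_s, sw,
                          dt = 1e-5) {
  ops <- oracle_ops
  hdiag <- 2 * pi * (nu_a * diag(ops$Az) + nu_p * diag(ops$Pz) +
                     j_hz * diag(ops$Az %*% ops$Pz))
  advance <- function(sigma, from, to) {
    while (from < to - 1e-13) {
      h <- min(dt, to - from)
      ph <- exp(-1i * hdiag * h)
      sigma <- (ph %o% Conj(ph)) * sigma
      from <- from + h
    }
    sigma
  }
  element <- function(sigma) {
    sigma <- ops$Rhard %*% sigma %*% Conj(t(ops$Rhard))
    ops$Rsel_active %*% sigma %*% Conj(t(ops$Rsel_active))
  }
  n <- round(n_chunks * chunk_s * sw)
  dwell <- 1 / sw
  edges <- chunk_s / 2 + chunk_s * (0:(n_chunks - 1))
  sigma <- ops$Am  # transverse magnetization of the active spin at t1 = 0
  sig <- complex(length.out = n)
  tcur <- 0
  ei <- 1L
  for (k in seq_len(n)) {
    tk <- (k - 1) * dwell
    while (ei <= length(edges) && edges[ei] <= tk + 1e-12) {
      sigma <- advance(sigma, tcur, edges[ei])
      tcur <- edges[ei]
      sigma <- element(sigma)
      ei <- ei + 1L
    }
    sigma <- advance(sigma, tcur, tk)
    tcur <- tk
    sig[k] <- sum(diag(ops$Ap %*% sigma)) / 2
  }
  sig
}
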