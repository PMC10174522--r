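# Independent oracles, deliberately written with plain loops and dense
# linear algebra so they share no code path with the package internals.

# dense complete-electrode-model forward solver
oracle_cem_forward <- function(mesh, protocol) {
  nd <- mesh$nodes
  el <- mesh$elements
  N <- nrow(nd); L <- mesh$n_elec
  A <- matrix(0, N + L + 1, N + L + 1)
  for (e in seq_len(nrow(el))) {
    idx <- el[e, ]
    x <- nd[idx, 1]; y <- nd[idx, 2]
    ar <- ((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])) / 2
    b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2]) / (2 * ar)
    c2 <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1]) / (2 * ar)
    for (p in 1:3) for (q in 1:3) {
      A[idx[p], idx[q]] <- A[idx[p], idx[q]] +
        mesh$element_conductivity[e] * ar * (b[p] * b[q] + c2[p] * c2[q])
    }
  }
  for (l in seq_len(L)) {
    en <- mesh$electrodes[[l]]
    z <- mesh$contact_impedance[l]
    for (s in seq_len(length(en) - 1)) {
      n1 <- en[s]; n2 <- en[s + 1]
      h <- sqrt(sum((nd[n1, ] - nd[n2, ])^2))
      A[n1, n1] <- A[n1, n1] + (h / z) * 2 / 6
      A[n2, n2] <- A[n2, n2] + (h / z) * 2 / 6
      A[n1, n2] <- A[n1, n2] + (h / z) / 6
      A[n2, n1] <- A[n2, n1] + (h / z) / 6
      A[n1, N + l] <- A[n1, N + l] - (h / z) / 2
      A[n2, N + l] <- A[n2, N + l] - (h / z) / 2
      A[N + l, n1] <- A[N + l, n1] - (h / z) / 2
      A[N + l, n2] <- A[N + l, n2] - (h / z) / 2
      A[N + l, N + l] <- A[N + l, N + l] + h / z
    }
  }
  A[seq_len(N), N + L + 1] <- 1
  A[N + L + 1, seq_len(N)] <- 1
  v <- numeric(nrow(protocol$table))
  Umat <- matrix(0, L, nrow(protocol$injection_pairs))
  for (d in seq_len(nrow(protocol$injection_pairs))) {
    rhs <- numeric(N + L + 1)
    rhs[N + protocol$injection_pairs[d, 1]] <- protocol$current_amplitude
    rhs[N + protocol$injection_pairs[d, 2]] <- -protocol$current_amplitude
    sol <- solve(A, rhs)
    Umat[, d] <- sol[N + seq_len(L)]
  }
  for (r in seq_len(nrow(protocol$table))) {
    d <- protocol$table[r, "drive"]
    mp <- protocol$measurement_pairs[r, ]
    v[r] <- Umat[mp[1], d] - Umat[mp[2], d]
  }
  v
}

# stacked least-squares solution of min ||Jx - y||^2 + lambda^2 ||Rx||^2
oracle_augmented_ls <- function(J, y, lambda, R = diag(ncol(J))) {
  A <- rbind(J, lambda * R)
  b <- c(y, numeric(nrow(R)))
  qr.coef(qr(A), b)
}

# Eq.-style direct DCT-II coefficients computed with explicit loops
oracle_dct2 <- function(A, n_x, n_y) {
  M <- nrow(A); N <- ncol(A)
  V <- matrix(0, n_x, n_y)
  for (p in 0:(n_x - 1)) for (q in 0:(n_y - 1)) {
    ap <- if (p == 0) sqrt(1 / M) else sqrt(2 / M)
    aq <- if (q == 0) sqrt(1 / N) else sqrt(2 / N)
    s <- 0
    for (m in 0:(M - 1)) for (n in 0:(N - 1)) {
      s <- s + A[m + 1, n + 1] * cos((2 * m + 1) * p * pi / (2 * M)) *
        cos((2 * n + 1) * q * pi / (2 * N))
    }
    V[p + 1, q + 1] <- ap * aq * s
  }
  V
}
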