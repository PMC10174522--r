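# Complete electrode model forward solver for 2D EIT.
#
# Unknowns are the nodal potentials u, the electrode potentials U and one
# Lagrange multiplier enforcing the zero-mean gauge over all nodes. The weak
# form contributes, per electrode l with contact impedance z_l:
#   stiffness  int sigma grad(u).grad(v)
#   + (1/z_l) int_El (u - U_l)(v - V_l) ds  =  sum_l I_l V_l

#' Adjacent stimulation / adjacent measurement protocol
#'
#' Injection between neighbouring electrode pairs (l, l+1); voltages measured
#' between the remaining neighbouring pairs. With measurements on driven
#' electrodes excluded, a 16-electrode frame has 16 x 13 = 208 values.
#'
#' @param n_elec electrode count
#' @param current_amplitude injected current (arbitrary units)
#' @param exclude_driven drop measurement pairs sharing an electrode with the
#'   injecting pair
#' @return an `eit_protocol` with the injection/measurement pair tables
#' @export
adjacent_protocol <- function(n_elec = 16L, current_amplitude = 1,
                              exclude_driven = TRUE) {
  n_elec <- as.integer(n_elec)
  inj <- cbind(seq_len(n_elec), seq_len(n_elec) %% n_elec + 1L)
  rows <- list()
  for (d in seq_len(n_elec)) {
    q <- seq_len(n_elec)
    if (exclude_driven) {
      drv <- c(inj[d, 1], inj[d, 2])
      keep <- !(q %in% drv) & !((q %% n_elec + 1L) %in% drv)
      q <- q[keep]
    }
    rows[[d]] <- cbind(drive = d, meas = q)
  }
  tab <- do.call(rbind, rows)
  structure(list(
    n_elec = n_elec,
    injection_pairs = inj,
    measurement_pairs = cbind(tab[, "meas"], tab[, "meas"] %% n_elec + 1L),
    table = tab,                       # (drive pattern, measurement pattern)
    n_meas = nrow(tab),
    current_amplitude = current_amplitude,
    exclude_driven = exclude_driven
  ), class = "eit_protocol")
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat(sprintf("<eit_protocol> %d electrodes, adjacent/adjacent, %d measurements\n",
              x$n_elec, x$n_meas))
  invisible(x)
}

# assemble the (N + L + 1) CEM system matrix for the mesh's conductivity
assemble_cem <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elements
  N <- nrow(nd); L <- mesh$n_elec
  sig <- mesh$element_conductivity
  x1 <- nd[el[, 1], 1]; y1 <- nd[el[, 1], 2]
  x2 <- nd[el[, 2], 1]; y2 <- nd[el[, 2], 2]
  x3 <- nd[el[, 3], 1]; y3 <- nd[el[, 3], 2]
  a <- mesh$areas
  # P1 shape-function gradients
  b1 <- (y2 - y3) / (2 * a); c1 <- (x3 - x2) / (2 * a)
  b2 <- (y3 - y1) / (2 * a); c2 <- (x1 - x3) / (2 * a)
  b3 <- (y1 - y2) / (2 * a); c3 <- (x2 - x1) / (2 * a)
  B <- cbind(b1, b2, b3); C <- cbind(c1, c2, c3)
  ii <- jj <- vv <- vector("list", 9)
  k <- 0
  for (p in 1:3) for (q in 1:3) {
    k <- k + 1
    ii[[k]] <- el[, p]; jj[[k]] <- el[, q]
    vv[[k]] <- sig * a * (B[, p] * B[, q] + C[, p] * C[, q])
  }
  iA <- unlist(ii); jA <- unlist(jj); vA <- unlist(vv)

  # electrode boundary terms
  ei <- c(); ej <- c(); ev <- c()
  wi <- c(); wl <- c(); wv <- c()
  dZ <- numeric(L)
  for (l in seq_len(L)) {
    en <- mesh$electrodes[[l]]
    z <- mesh$contact_impedance[l]
    for (s in seq_len(length(en) - 1)) {
      n1 <- en[s]; n2 <- en[s + 1]
      h <- sqrt(sum((nd[n1, ] - nd[n2, ])^2))
      # edge mass matrix h/6 * [[2,1],[1,2]]
      ei <- c(ei, n1, n1, n2, n2); ej <- c(ej, n1, n2, n1, n2)
      ev <- c(ev, (h / z) * c(2, 1, 1, 2) / 6)
      wi <- c(wi, n1, n2); wl <- c(wl, l, l)
      wv <- c(wv, -(h / z) / 2, -(h / z) / 2)
      dZ[l] <- dZ[l] + h / z
    }
  }

  dim_tot <- N + L + 1
  # one sparseMatrix call: node-node, node-elec, elec-node, elec-elec, gauge
  iS <- c(iA, ei, wi,          N + wl,      N + seq_len(L), seq_len(N),      rep(N + L + 1L, N))
  jS <- c(jA, ej, N + wl,      wi,          N + seq_len(L), rep(N + L + 1L, N), seq_len(N))
  vS <- c(vA, ev, wv,          wv,          dZ,             rep(1, N),       rep(1, N))
  S <- Matrix::sparseMatrix(i = iS, j = jS, x = vS, dims = c(dim_tot, dim_tot))
  list(S = S, N = N, L = L)
}

# solve all injection patterns at once; returns electrode potentials (L x n_drive)
cem_solve_patterns <- function(mesh, protocol) {
  if (protocol$n_elec != mesh$n_elec) stop("mesh and protocol electrode counts disagree")
  sys <- assemble_cem(mesh)
  L <- sys$L; N <- sys$N
  nd <- nrow(protocol$injection_pairs)
  RHS <- matrix(0, N + L + 1, nd)
  for (d in seq_len(nd)) {
    RHS[N + protocol$injection_pairs[d, 1], d] <- protocol$current_amplitude
    RHS[N + protocol$injection_pairs[d, 2], d] <- -protocol$current_amplitude
  }
  sol <- tryCatch(as.matrix(Matrix::solve(sys$S, RHS)),
                  error = function(e) stop("solver error: singular CEM system (",
                                           conditionMessage(e), ")"))
  list(U = sol[N + seq_len(L), , drop = FALSE],
       u = sol[seq_len(N), , drop = FALSE])
}

# extract the measurement vector (drive-major) from electrode potentials
measurements_from_U <- function(U, protocol) {
  tab <- protocol$table
  mp <- protocol$measurement_pairs
  U[cbind(mp[, 1], tab[, "drive"])] - U[cbind(mp[, 2], tab[, "drive"])]
}

#' Solve the EIT forward problem
#'
#' Complete electrode model solution of one boundary-voltage frame for the
#' mesh's current per-element conductivity under the given adjacent protocol.
#'
#' @param mesh an `eit_mesh` (conductivity set via [set_conductivity()])
#' @param protocol an `eit_protocol`
#' @return raw (non-normalized) voltage vector of length `protocol$n_meas`,
#'   ordered drive-major, as an `eit_frame`
#' @export
solve_forward <- function(mesh, protocol = adjacent_protocol(mesh$n_elec)) {
  sol <- cem_solve_patterns(mesh, protocol)
  v <- measurements_from_U(sol$U, protocol)
  structure(v, class = "eit_frame", is_normalized = FALSE)
}

#' Compute the EIT sensitivity (Jacobian) matrix by the adjoint method
#'
#' Entry (i, j) is the derivative of raw boundary voltage i with respect to
#' the conductivity of element j, evaluated at the supplied linearization
#' point. Uses the adjoint identity: for drive field u_d and measurement
#' field u_m (unit current driven through the measurement pair),
#' dV/dsigma_e = -area_e * grad(u_d) . grad(u_m).
#'
#' @param mesh an `eit_mesh`
#' @param sigma_baseline per-element conductivity of the linearization point
#'   (or a function of (x, y)); defaults to the mesh's current conductivity
#' @param protocol an `eit_protocol`
#' @param normalized if `TRUE`, rows are divided by the model baseline
#'   voltages so the matrix maps conductivity change to normalized voltage
#'   change y = (V - V_baseline)/V_baseline
#' @return matrix (n_meas x n_elems) with attributes `linearization` and
#'   `v_baseline`
#' @export
compute_jacobian <- function(mesh, sigma_baseline = NULL,
                             protocol = adjacent_protocol(mesh$n_elec),
                             normalized = FALSE) {
  if (!is.null(sigma_baseline)) mesh <- set_conductivity(mesh, sigma_baseline)
  sol <- cem_solve_patterns(mesh, protocol)
  u <- sol$u
  el <- mesh$elements; nd <- mesh$nodes; a <- mesh$areas
  x1 <- nd[el[, 1], 1]; y1 <- nd[el[, 1], 2]
  x2 <- nd[el[, 2], 1]; y2 <- nd[el[, 2], 2]
  x3 <- nd[el[, 3], 1]; y3 <- nd[el[, 3], 2]
  b1 <- (y2 - y3) / (2 * a); c1 <- (x3 - x2) / (2 * a)
  b2 <- (y3 - y1) / (2 * a); c2 <- (x1 - x3) / (2 * a)
  b3 <- (y1 - y2) / (2 * a); c3 <- (x2 - x1) / (2 * a)
  # per-element field gradients for every drive pattern
  Gx <- b1 * u[el[, 1], , drop = FALSE] + b2 * u[el[, 2], , drop = FALSE] +
        b3 * u[el[, 3], , drop = FALSE]
  Gy <- c1 * u[el[, 1], , drop = FALSE] + c2 * u[el[, 2], , drop = FALSE] +
        c3 * u[el[, 3], , drop = FALSE]
  tab <- protocol$table
  # unit-current scaling of the adjoint (measurement) field
  amp <- protocol$current_amplitude
  J <- matrix(0, nrow(tab), nrow(el))
  for (r in seq_len(nrow(tab))) {
    d <- tab[r, "drive"]; m <- tab[r, "meas"]
    J[r, ] <- -a * (Gx[, d] * Gx[, m] + Gy[, d] * Gy[, m]) / amp
  }
  v0 <- measurements_from_U(sol$U, protocol)
  if (normalized) {
    if (any(abs(v0) < 1e-12)) stop("normalization error: baseline voltage below 1e-12")
    J <- J / v0
  }
  attr(J, "linearization") <- mesh$element_conductivity
  attr(J, "v_baseline") <- v0
  J
}

#' Simulate a noisy normalized voltage-change frame
#'
#' Solves the forward problem on the target and baseline meshes, superimposes
#' Gaussian noise scaled to the standard deviation of the raw voltage change
#' on the target frame, and returns the normalized change
#' y = (V + n - V_baseline)/V_baseline.
#'
#' @param mesh_target mesh carrying the target conductivity
#' @param mesh_baseline mesh carrying the baseline conductivity (same
#'   electrode layout)
#' @param protocol an `eit_protocol`
#' @param noise_fraction noise standard deviation as a fraction of
#'   sd(V - V_baseline); 0.25 reproduces the study's 25% noise condition
#' @param seed integer RNG seed (or NULL to use the current RNG state)
#' @return normalized `eit_frame` with attribute `noise_seed`
#' @export
simulate_measurement <- function(mesh_target, mesh_baseline,
                                 protocol = adjacent_protocol(mesh_target$n_elec),
                                 noise_fraction = 0.25, seed = NULL) {
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  v <- as.numeric(solve_forward(mesh_target, protocol))
  v0 <- as.numeric(solve_forward(mesh_baseline, protocol))
  add_measurement_noise(v, v0, noise_fraction, seed)
}

#' Normalize a raw voltage pair into a noisy difference frame
#'
#' The low-level noise model behind [simulate_measurement()]: noise with
#' standard deviation `noise_fraction * sd(v - v_baseline)` is added to the
#' raw target voltages before normalization.
#'
#' @param v raw target-frame voltages
#' @param v_baseline raw baseline-frame voltages (noise-free reference)
#' @param noise_fraction noise scale relative to sd of the raw change
#' @param seed integer RNG seed or NULL
#' @return normalized `eit_frame`
#' @export
add_measurement_noise <- function(v, v_baseline, noise_fraction = 0.25,
                                  seed = NULL) {
  if (length(v) != length(v_baseline)) stop("frame lengths disagree")
  if (any(abs(v_baseline) < 1e-12)) stop("normalization error: baseline voltage below 1e-12")
  if (!is.null(seed)) set.seed(as.integer(seed))
  s <- stats::sd(v - v_baseline)
  n <- if (noise_fraction > 0) stats::rnorm(length(v), 0, noise_fraction * s) else 0
  y <- (v + n - v_baseline) / v_baseline
  structure(as.numeric(y), class = "eit_frame", is_normalized = TRUE,
            noise_seed = seed)
}

#' Write voltage frames to a delimited text file
#' @param frames numeric vector or matrix (one frame per row)
#' @param file output path
#' @param protocol protocol used (recorded in the header)
#' @param seed seed recorded in the header
#' @export
write_voltage_frames <- function(frames, file, protocol = NULL, seed = NA) {
  frames <- rbind(frames)
  hdr <- sprintf("# protocol=%s n_meas=%d seed=%s",
                 if (is.null(protocol)) "unknown" else
                   sprintf("adjacent%d", protocol$n_elec),
                 ncol(frames), as.character(seed))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(frames, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' Read voltage frames written by [write_voltage_frames()]
#' @param file input path
#' @return numeric matrix, one frame per row
#' @export
read_voltage_frames <- function(file) {
  as.matrix(utils::read.table(file, sep = ",", comment.char = "#"))
}
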