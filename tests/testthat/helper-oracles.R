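# Independent plain-R oracles used across the suite. These deliberately use
# the most direct formulation available (double loops, central differences)
# and never call the compiled fast paths they check.

# O(n^2) direct summation density
oracle_density <- function(x, y, m, spec) {
  n <- length(x)
  m <- rep_len(m, n)
  rho <- numeric(n)
  for (j in seq_len(n)) {
    s <- 0
    for (i in seq_len(n)) {
      r <- sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)
      s <- s + m[i] * kernel_value(r, spec)
    }
    rho[j] <- s
  }
  rho
}

# pair-by-pair symmetric pressure-gradient acceleration
oracle_repulsion <- function(x, y, m, rho, P, spec) {
  n <- length(x)
  m <- rep_len(m, n)
  a <- matrix(0, n, 2)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == j) next
      dvec <- c(x[j] - x[i], y[j] - y[i])
      gw <- kernel_gradient(dvec, spec)
      S <- P[i] / rho[i]^2 + P[j] / rho[j]^2
      a[j, ] <- a[j, ] - m[i] * S * gw
    }
  }
  a
}

# central-difference gradient of the kernel
oracle_kernel_gradient <- function(r_vec, spec, step = 1e-6) {
  f <- function(v) kernel_value(sqrt(sum(v^2)), spec)
  c((f(r_vec + c(step, 0)) - f(r_vec - c(step, 0))) / (2 * step),
    (f(r_vec + c(0, step)) - f(r_vec - c(0, step))) / (2 * step))
}

# straightforward loop implementation of one donor-cell predictor step on a
# small grid (same scheme as the compiled path, written independently)
oracle_predictor <- function(u, v, mask, dt, dx, nu, vin) {
  nx <- nrow(mask); ny <- ncol(mask)
  us <- u; vs <- v
  u_at <- function(i, j) {                # 0-based face (i, j)
    if (j < 0) return(-u[i + 1, 1])       # inflow edge: tangential u = 0
    if (j >= ny) return(u[i + 1, ny])     # outflow: zero gradient
    u[i + 1, j + 1]
  }
  v_at <- function(i, j) {
    if (i < 0) return(v[1, j + 1])        # lateral free slip
    if (i >= nx) return(v[nx, j + 1])
    v[i + 1, j + 1]
  }
  for (j in 0:(ny - 1)) {
    for (i in 1:(nx - 1)) {
      if (mask[i, j + 1] || mask[i + 1, j + 1]) { us[i + 1, j + 1] <- 0; next }
      uc <- u_at(i, j)
      ce <- 0.5 * (uc + u_at(i + 1, j)); cw <- 0.5 * (u_at(i - 1, j) + uc)
      Fe <- ce * if (ce > 0) uc else u_at(i + 1, j)
      Fw <- cw * if (cw > 0) u_at(i - 1, j) else uc
      vn <- 0.5 * (v_at(i - 1, j + 1) + v_at(i, j + 1))
      vsf <- 0.5 * (v_at(i - 1, j) + v_at(i, j))
      Fn <- vn * if (vn > 0) uc else u_at(i, j + 1)
      Fs <- vsf * if (vsf > 0) u_at(i, j - 1) else uc
      lap <- (u_at(i + 1, j) - 2 * uc + u_at(i - 1, j) +
              u_at(i, j + 1) - 2 * uc + u_at(i, j - 1)) / dx^2
      us[i + 1, j + 1] <- uc +
        dt * (-(Fe - Fw) / dx - (Fn - Fs) / dx + nu * lap)
    }
    us[1, j + 1] <- 0; us[nx + 1, j + 1] <- 0
  }
  for (j in 1:(ny - 1)) {
    for (i in 0:(nx - 1)) {
      if (mask[i + 1, j] || mask[i + 1, j + 1]) { vs[i + 1, j + 1] <- 0; next }
      vc <- v_at(i, j)
      ue <- 0.5 * (u_at(i + 1, j - 1) + u_at(i + 1, j))
      uw <- 0.5 * (u_at(i, j - 1) + u_at(i, j))
      Fe <- ue * if (ue > 0) vc else v_at(i + 1, j)
      Fw <- uw * if (uw > 0) v_at(i - 1, j) else vc
      cn <- 0.5 * (vc + v_at(i, j + 1)); cs <- 0.5 * (v_at(i, j - 1) + vc)
      Fn <- cn * if (cn > 0) vc else v_at(i, j + 1)
      Fs <- cs * if (cs > 0) v_at(i, j - 1) else vc
      lap <- (v_at(i + 1, j) - 2 * vc + v_at(i - 1, j) +
              v_at(i, j + 1) - 2 * vc + v_at(i, j - 1)) / dx^2
      vs[i + 1, j + 1] <- vc +
        dt * (-(Fe - Fw) / dx - (Fn - Fs) / dx + nu * lap)
    }
  }
  for (i in 1:nx) {
    vs[i, 1] <- if (mask[i, 1]) 0 else vin
    vs[i, ny + 1] <- vs[i, ny]
  }
  list(u = us, v = vs)
}

# max |divergence| over fluid cells, computed directly
oracle_max_div <- function(u, v, mask, dx) {
  nx <- nrow(mask); ny <- ncol(mask)
  d <- (u[2:(nx + 1), ] - u[1:nx, ] + v[, 2:(ny + 1)] - v[, 1:ny]) / dx
  max(abs(d[!mask]))
}
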