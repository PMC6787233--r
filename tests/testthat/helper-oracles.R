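# Independent oracles used across test files.

# Literal term-by-term evaluation of the HSR diffusion tensor: explicit
# double sums for the flux operators and explicit loops over state pairs for
# the tensor. Deliberately naive; only usable for small aggregates.
brute_flux <- function(model, basis, direction) {
  mol <- model$molecules
  N <- nrow(mol)
  if (direction == "z") {
    proj <- function(m, n) mol$z[m] - mol$z[n]
  } else if (direction == "phi") {
    R <- sqrt(mol$x^2 + mol$y^2)
    th <- atan2(mol$y, mol$x)
    proj <- function(m, n) {
      d <- th[m] - th[n]
      d <- d - 2 * pi * round(d / (2 * pi))
      d * (R[m] + R[n]) / 2
    }
  } else stop("direction")
  wn2om <- 2 * pi * 2.99792458e-5
  J <- model$coupling * wn2om
  C <- basis$coef
  out <- matrix(0 + 0i, N, N)
  for (mu in 1:N) {
    for (nu in 1:N) {
      acc <- 0
      for (n in 1:N) {
        for (m in 1:N) {
          acc <- acc + C[m, mu] * proj(m, n) * J[n, m] * C[n, nu]
        }
      }
      out[mu, nu] <- 1i * acc
    }
  }
  out
}

brute_tensor_element <- function(basis, ju, jw, gamma, kBT_cm1) {
  N <- basis$n_states
  om <- basis$omega_radfs
  e0 <- min(basis$energies_cm1)
  Z <- sum(exp(-(basis$energies_cm1 - e0) / kBT_cm1))
  acc <- 0
  for (mu in 1:N) {
    for (nu in 1:N) {
      lor <- gamma / (gamma^2 + (om[mu] - om[nu])^2)
      boltz <- exp(-(basis$energies_cm1[nu] - e0) / kBT_cm1)
      acc <- acc + lor * Conj(ju[mu, nu]) * jw[mu, nu] * boltz
    }
  }
  Re(acc) / Z * 1000
}

# A small irregular helical aggregate for HSR property tests.
small_helix_model <- function(n_rings = 4, sites_per_ring = 5,
                              energy = 16700) {
  mol <- build_helical_cylinder(radius = 1.2, n_rings = n_rings,
                                sites_per_ring = sites_per_ring,
                                pitch = 0.6, dipole_tilt = 35,
                                twist = 0.3, site_energy = energy)
  aggregate_model(mol, dipole_length = 0.35, dipole_charge = 0.3,
                  geometry_kind = "helical_cylinder")
}

# Point-dipole interaction, the far-field limit of the extended dipole.
point_dipole_J <- function(r_a, u_a, r_b, u_b, mu2_cm1nm3) {
  d <- r_b - r_a
  r <- sqrt(sum(d^2))
  rh <- d / r
  mu2_cm1nm3 * (sum(u_a * u_b) - 3 * sum(u_a * rh) * sum(u_b * rh)) / r^3
}
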