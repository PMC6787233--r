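# Frenkel-exciton Hamiltonian for tubular aggregates and the
# temperature-weighted Haken-Strobl-Reineker (HSR) diffusion tensor.
#
# Internal energy unit is cm^-1; energies are converted to angular frequency
# (rad/fs) before the tensor evaluation so that the dephasing rate Gamma and
# the eigenfrequency differences share units, and the tensor emerges in
# nm^2/fs (reported x1000 as nm^2/ps).

C_CM_PER_FS <- 2.99792458e-5                  # speed of light, cm per fs
CM1_TO_RADFS <- 2 * pi * C_CM_PER_FS          # cm^-1 -> rad/fs
KE2_CM1_NM <- 1.439964548 * 8065.543937       # e^2/(4 pi eps0) in cm^-1 nm

#' Molecule table for an aggregate
#'
#' @param position N x 3 matrix of molecular positions in nm.
#' @param dipole N x 3 matrix of transition-dipole axes (normalised
#'   internally).
#' @param site_energy Site energies in cm^-1 (recycled).
#' @return Data frame with columns `x, y, z, ux, uy, uz, energy_cm1`.
#' @export
molecule_table <- function(position, dipole, site_energy = 0) {
  position <- as.matrix(position)
  dipole <- as.matrix(dipole)
  stopifnot(ncol(position) == 3L, ncol(dipole) == 3L,
            nrow(position) == nrow(dipole))
  nrm <- sqrt(rowSums(dipole^2))
  if (any(nrm == 0)) stop("zero dipole axis")
  dipole <- dipole / nrm
  data.frame(x = position[, 1], y = position[, 2], z = position[, 3],
             ux = dipole[, 1], uy = dipole[, 2], uz = dipole[, 3],
             energy_cm1 = rep_len(site_energy, nrow(position)))
}

pair_inv_dist <- function(a, b) {
  # 1/distance between every row of a and of b (N x N), nm^-1
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  1 / sqrt(d2)
}

#' Excitonic coupling in the extended-dipole approximation
#'
#' Each transition dipole is represented by two point charges +-q placed at
#' `r +- (l/2) u`; the coupling is the Coulomb sum over the four charge
#' pairs, `J = ke q^2 (1/r++ + 1/r-- - 1/r+- - 1/r-+)` in cm^-1 (q in
#' elementary charges, distances in nm). At separations much larger than `l`
#' this reduces to the point-dipole interaction with mu = q l; at close
#' range it is the better description of the transfer interaction.
#'
#' @param molecules A [molecule_table()].
#' @param dipole_length Charge separation l in nm.
#' @param dipole_charge Effective charge q in elementary charges.
#' @return Symmetric N x N coupling matrix in cm^-1 with zero diagonal.
#' @export
extended_dipole_coupling <- function(molecules, dipole_length, dipole_charge) {
  stopifnot(dipole_length > 0)
  r <- as.matrix(molecules[, c("x", "y", "z")])
  u <- as.matrix(molecules[, c("ux", "uy", "uz")])
  p <- r + (dipole_length / 2) * u
  m <- r - (dipole_length / 2) * u
  J <- KE2_CM1_NM * dipole_charge^2 *
    (pair_inv_dist(p, p) + pair_inv_dist(m, m) -
       pair_inv_dist(p, m) - pair_inv_dist(m, p))
  diag(J) <- 0
  if (any(!is.finite(J))) stop("coincident charge positions (overlapping molecules)")
  (J + t(J)) / 2
}

#' Aggregate model: molecules plus coupling matrix
#'
#' @param molecules A [molecule_table()].
#' @param dipole_length,dipole_charge Extended-dipole parameters (nm,
#'   elementary charges), used unless an explicit `coupling` is given.
#' @param coupling Optional explicit symmetric coupling matrix in cm^-1.
#' @param geometry_kind One of `"chain"`, `"ring"`, `"helical_cylinder"`,
#'   `"explicit"`; `"helical_cylinder"`/`"ring"` geometries define the
#'   circumferential (phi) flux direction about the z axis.
#' @return An object of class `aggregate_model`.
#' @export
aggregate_model <- function(molecules, dipole_length = NULL,
                            dipole_charge = NULL, coupling = NULL,
                            geometry_kind = c("explicit", "chain", "ring",
                                              "helical_cylinder")) {
  geometry_kind <- match.arg(geometry_kind)
  if (is.null(coupling)) {
    coupling <- extended_dipole_coupling(molecules, dipole_length,
                                         dipole_charge)
  } else {
    coupling <- as.matrix(coupling)
    stopifnot(nrow(coupling) == nrow(molecules),
              isTRUE(all.equal(coupling, t(coupling))))
    diag(coupling) <- 0
  }
  structure(list(molecules = molecules, coupling = coupling,
                 dipole_length = dipole_length,
                 dipole_charge = dipole_charge,
                 geometry_kind = geometry_kind),
            class = "aggregate_model")
}

#' Exciton basis by diagonalising the Frenkel Hamiltonian
#'
#' `H_nm = delta_nm E_n + (1 - delta_nm) J_nm`, dense symmetric
#' eigendecomposition; eigenfrequencies are returned sorted ascending, in
#' cm^-1 and in angular frequency (rad/fs).
#'
#' @param model An [aggregate_model()].
#' @return An object of class `exciton_basis`: `energies_cm1`,
#'   `omega_radfs`, `coef` (N x N matrix, column mu = site coefficients
#'   <n|mu>), `n_states`.
#' @export
build_basis <- function(model) {
  stopifnot(inherits(model, "aggregate_model"))
  H <- model$coupling
  if (any(!is.finite(H))) stop("non-finite couplings")
  diag(H) <- model$molecules$energy_cm1
  ee <- eigen(H, symmetric = TRUE)
  ord <- order(ee$values)
  structure(list(energies_cm1 = ee$values[ord],
                 omega_radfs = ee$values[ord] * CM1_TO_RADFS,
                 coef = ee$vectors[, ord, drop = FALSE],
                 n_states = length(ee$values)),
            class = "exciton_basis")
}

# Pairwise displacement matrix Delta[m, n] = u . (r_m - r_n) for the two
# tube-surface directions: z is the axial coordinate, phi the unrolled
# arc-length coordinate about the z axis with minimum-image wrap.
direction_displacement <- function(model, direction) {
  mol <- model$molecules
  if (is.numeric(direction)) {
    stopifnot(length(direction) == 3L)
    u <- direction / sqrt(sum(direction^2))
    p <- as.matrix(mol[, c("x", "y", "z")]) %*% u
    return(outer(drop(p), drop(p), "-"))
  }
  if (direction == "z") return(outer(mol$z, mol$z, "-"))
  if (direction == "phi") {
    radius <- sqrt(mol$x^2 + mol$y^2)
    if (any(radius < 1e-9)) stop("phi direction undefined: molecule on the axis")
    theta <- atan2(mol$y, mol$x)
    dtheta <- outer(theta, theta, "-")
    # antisymmetric minimum-image wrap (round half-even keeps w(-x) = -w(x),
    # so antipodal pairs get +-pi consistently and the flux stays Hermitian)
    dtheta <- dtheta - 2 * pi * round(dtheta / (2 * pi))
    rbar <- outer(radius, radius, "+") / 2
    return(dtheta * rbar)
  }
  stop("unknown direction: ", direction)
}

#' Flux operator in the exciton eigenbasis
#'
#' `j_munu(u) = i sum_{n,m} <mu|m> (u . r_mn) J_nm <n|nu>` with the coupling
#' in angular-frequency units; the real core `u . r_mn J_nm` is
#' antisymmetric, so the operator is Hermitian with purely imaginary
#' entries. Units: nm rad/fs.
#'
#' @param basis An [build_basis()] result.
#' @param model The generating [aggregate_model()].
#' @param direction `"z"`, `"phi"`, or a 3-vector (projected displacement).
#' @return Complex Hermitian N x N matrix.
#' @export
flux_operator <- function(basis, model, direction) {
  stopifnot(inherits(basis, "exciton_basis"))
  delta <- direction_displacement(model, direction)  # r_m - r_n along u
  A <- delta * model$coupling * CM1_TO_RADFS         # A[m,n] = (u.r_mn) J_nm
  C <- basis$coef
  1i * (t(C) %*% A %*% C)
}

#' Haken-Strobl-Reineker diffusion tensor
#'
#' Evaluates, for directions u, w over all pairs of exciton eigenstates,
#' `D_uw = (1/Z) sum_{mu,nu} Gamma / (Gamma^2 + omega_munu^2) *
#' conj(j_munu(u)) j_munu(w) exp(-hbar omega_nu / kBT)` with the Lorentzian
#' dephasing weight and the Boltzmann factor referenced to the band bottom
#' (a pure overall shift that cancels against the partition function Z).
#'
#' @param basis An [build_basis()] result.
#' @param flux_z,flux_phi Flux operators from [flux_operator()].
#' @param gamma_radfs Dephasing rate Gamma in rad/fs (> 0).
#' @param kBT_cm1 Thermal energy in cm^-1 (> 0).
#' @return Object of class `hsr_tensor`: `tensor` (2 x 2 matrix, nm^2/ps,
#'   dimensions z and phi), `Z`, `gamma_radfs`, `kBT_cm1`.
#' @export
diffusion_tensor <- function(basis, flux_z, flux_phi, gamma_radfs, kBT_cm1) {
  stopifnot(inherits(basis, "exciton_basis"))
  if (gamma_radfs <= 0) stop("gamma_radfs must be positive")
  if (kBT_cm1 <= 0) stop("kBT_cm1 must be positive")
  om <- basis$omega_radfs
  L <- gamma_radfs / (gamma_radfs^2 + outer(om, om, "-")^2)  # fs
  b <- exp(-(basis$energies_cm1 - min(basis$energies_cm1)) / kBT_cm1)
  Z <- sum(b)
  W <- L * rep(b, each = length(b))   # weight[mu, nu] = L[mu,nu] * b[nu]
  el <- function(ju, jw) Re(sum(Conj(ju) * jw * W)) / Z * 1000  # nm^2/ps
  tensor <- matrix(c(el(flux_z, flux_z), el(flux_z, flux_phi),
                     el(flux_phi, flux_z), el(flux_phi, flux_phi)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("z", "phi"), c("z", "phi")))
  structure(list(tensor = tensor, Z = Z, gamma_radfs = gamma_radfs,
                 kBT_cm1 = kBT_cm1),
            class = "hsr_tensor")
}

#' @export
print.hsr_tensor <- function(x, ...) {
  cat("<hsr_tensor> (nm^2/ps)\n")
  print(signif(x$tensor, 4))
  cat(sprintf("Gamma = %g rad/fs, kBT = %g cm^-1, Z = %g\n",
              x$gamma_radfs, x$kBT_cm1, x$Z))
  invisible(x)
}

#' Convert a diffusion constant to molecular units
#'
#' Multiplies by the molecular surface density; with the nanotube surface
#' density of 1.8 molecules/nm^2 the axial HSR values 23.9 and 16.3 nm^2/ps
#' translate into 43 and 29 molecules/ps.
#'
#' @param D_nm2_ps Diffusion constant in nm^2/ps.
#' @param surface_density Molecules per nm^2.
#' @return Diffusion constant in molecules/ps.
#' @export
molecular_units <- function(D_nm2_ps, surface_density) {
  stopifnot(D_nm2_ps >= 0, surface_density > 0)
  D_nm2_ps * surface_density
}

#' Helical cylinder geometry builder
#'
#' Places `n_rings` rings of `sites_per_ring` molecules on a cylinder about
#' the z axis: ring r sits at `z = r * pitch` and is rotated azimuthally by
#' `r * twist`; transition dipoles are tilted by `dipole_tilt` degrees from
#' the cylinder axis toward the local circumferential direction. The
#' two-molecule unit cell, tilt angles and extended-dipole parameters of the
#' real C8S3 lattice are not hard-coded: they enter through the arguments.
#'
#' @param radius Cylinder radius in nm (> 0).
#' @param n_rings,sites_per_ring Grid dimensions (>= 1).
#' @param pitch Axial ring spacing in nm (0 gives a planar ring stack).
#' @param dipole_tilt Dipole tilt from the axis, degrees.
#' @param twist Azimuthal offset per ring, radians.
#' @param site_energy Site energy in cm^-1.
#' @return A [molecule_table()].
#' @export
build_helical_cylinder <- function(radius, n_rings, sites_per_ring,
                                   pitch, dipole_tilt = 0, twist = 0,
                                   site_energy = 0) {
  stopifnot(radius > 0, n_rings >= 1, sites_per_ring >= 1, pitch >= 0)
  if (n_rings > 1 && pitch == 0 && twist == 0) {
    stop("degenerate geometry: coincident rings (pitch = 0, twist = 0)")
  }
  grid <- expand.grid(s = seq_len(sites_per_ring) - 1L,
                      r = seq_len(n_rings) - 1L)
  theta <- 2 * pi * grid$s / sites_per_ring + grid$r * twist
  pos <- cbind(radius * cos(theta), radius * sin(theta), grid$r * pitch)
  beta <- dipole_tilt * pi / 180
  dip <- cbind(-sin(theta) * sin(beta), cos(theta) * sin(beta),
               rep(cos(beta), length(theta)))
  molecule_table(pos, dip, site_energy)
}
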