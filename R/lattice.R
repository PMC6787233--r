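# Geometry of the molecular grids: each tube wall is a rectangular lattice of
# molecules, periodic in both the circumferential (i) and axial (j) direction,
# i.e. a cylinder unrolled onto a torus-wrapped plane. Indices are 0-based.

#' Lattice specification for one tube wall
#'
#' A periodic rectangular grid of `n_circ` x `n_axial` molecules with lattice
#' constant `lattice_const` (nm), wrapped on a cylinder. The walls of the
#' double-walled nanotube use 30 (inner) and 55 (outer) molecules around the
#' circumference and 1000 along the axis, with a 0.74 nm lattice constant.
#'
#' @param layer `"inner"` or `"outer"`.
#' @param n_circ Number of sites around the circumference (>= 1).
#' @param n_axial Number of sites along the tube axis (>= 1).
#' @param lattice_const Lattice constant in nm (> 0).
#' @return An object of class `lattice_spec`.
#' @examples
#' inner <- lattice_spec("inner", 30, 1000)
#' tube_diameter(inner)
#' @export
lattice_spec <- function(layer = c("inner", "outer"), n_circ, n_axial,
                         lattice_const = 0.74) {
  layer <- match.arg(layer)
  n_circ <- as.integer(n_circ)
  n_axial <- as.integer(n_axial)
  stopifnot(n_circ >= 1L, n_axial >= 1L, lattice_const > 0)
  structure(list(layer = layer, n_circ = n_circ, n_axial = n_axial,
                 lattice_const = lattice_const),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %s wall: %d x %d sites, a = %g nm\n",
              x$layer, x$n_circ, x$n_axial, x$lattice_const))
  invisible(x)
}

#' Site address on a wall
#'
#' @param layer `"inner"` or `"outer"`.
#' @param i Circumferential index, 0-based; wrapped modulo `n_circ` on use.
#' @param j Axial index, 0-based; wrapped modulo `n_axial` on use.
#' @return An object of class `site_address`.
#' @export
site_address <- function(layer = c("inner", "outer"), i, j) {
  layer <- match.arg(layer)
  structure(list(layer = layer, i = as.integer(i), j = as.integer(j)),
            class = "site_address")
}

check_site <- function(site, spec) {
  stopifnot(inherits(site, "site_address"), inherits(spec, "lattice_spec"))
  if (site$layer != spec$layer) {
    stop("site layer '", site$layer, "' does not match lattice layer '",
         spec$layer, "'")
  }
  invisible(TRUE)
}

#' Four nearest neighbours of a site under periodic wrap
#'
#' Excitons hop between adjacent molecules; every site has exactly four
#' neighbour slots (degenerate duplicates arise only for `n_circ <= 2` or
#' `n_axial <= 2`).
#'
#' @param site A [site_address()] on `spec`.
#' @param spec A [lattice_spec()].
#' @return A list of four `site_address` objects (+i, -i, +j, -j).
#' @export
site_neighbors <- function(site, spec) {
  check_site(site, spec)
  i <- site$i %% spec$n_circ
  j <- site$j %% spec$n_axial
  list(site_address(spec$layer, (i + 1L) %% spec$n_circ, j),
       site_address(spec$layer, (i - 1L) %% spec$n_circ, j),
       site_address(spec$layer, i, (j + 1L) %% spec$n_axial),
       site_address(spec$layer, i, (j - 1L) %% spec$n_axial))
}

#' Minimum-image distance between two same-wall sites
#'
#' Euclidean norm of the minimum-image index displacement, in lattice units
#' (multiply by the lattice constant for nm). This is the metric used for the
#' annihilation-radius criterion, which only applies within one wall, so
#' cross-layer input is an error.
#'
#' @param a,b [site_address()] objects on the same layer.
#' @param spec The wall's [lattice_spec()].
#' @return Distance in lattice units.
#' @export
min_image_distance <- function(a, b, spec) {
  check_site(a, spec)
  check_site(b, spec)
  di <- abs((a$i %% spec$n_circ) - (b$i %% spec$n_circ))
  di <- min(di, spec$n_circ - di)
  dj <- abs((a$j %% spec$n_axial) - (b$j %% spec$n_axial))
  dj <- min(dj, spec$n_axial - dj)
  sqrt(di^2 + dj^2)
}

round_half_up <- function(x) floor(x + 0.5)

#' Adjacent site on the other wall
#'
#' Inter-layer transfer moves an exciton to the nearest molecule of the other
#' wall: the axial index is preserved and the circumferential index rescaled
#' by the ratio of circumferences, `i' = round(i * n_circ_to / n_circ_from)`
#' (round half up), modulo `n_circ_to`. Both walls must have equal axial
#' length.
#'
#' @param site A [site_address()] on `from_spec`.
#' @param from_spec,to_spec [lattice_spec()] objects of the two walls.
#' @return The partner `site_address` on `to_spec`.
#' @export
interlayer_partner <- function(site, from_spec, to_spec) {
  check_site(site, from_spec)
  if (from_spec$n_axial != to_spec$n_axial) {
    stop("walls must have equal axial site counts")
  }
  i <- site$i %% from_spec$n_circ
  i2 <- round_half_up(i * to_spec$n_circ / from_spec$n_circ) %% to_spec$n_circ
  site_address(to_spec$layer, i2, site$j %% from_spec$n_axial)
}

#' Tube diameter implied by a wall lattice
#'
#' `n_circ * lattice_const / pi`; 55 molecules at 0.74 nm give the ~13 nm
#' outer diameter of the double-walled nanotube.
#'
#' @param spec A [lattice_spec()].
#' @return Diameter in nm.
#' @export
tube_diameter <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  spec$n_circ * spec$lattice_const / pi
}
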