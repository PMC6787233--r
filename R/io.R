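# File formats and small spectroscopic unit utilities. Transient tables are
# UTF-8 tab-separated text with '#'-prefixed key=value metadata headers:
# diffable, lossless, and each file alone identifies its producing run
# (seed, parameter hash, version).

fmt_num <- function(x) sprintf("%.15g", x)

#' Deterministic parameter hash
#'
#' Short content hash over the canonical serialisation of a parameter list,
#' embedded in output files so any result identifies its producing
#' configuration.
#'
#' @param params Any R object (typically a [sim_params()]).
#' @return 8-character hexadecimal string.
#' @export
params_hash <- function(params) {
  s <- paste(deparse(params, control = "exact"), collapse = " ")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147480009
  sprintf("%08x", h)
}

#' Write / read a transient table
#'
#' One file per (density, observable): '#'-prefixed `key = value` metadata
#' lines followed by a header row and tab-separated columns `time_ps`,
#' `value`, `sem`. Write-then-read is lossless and read-then-write
#' reproduces the file byte-identically; malformed rows are rejected with
#' their line number.
#'
#' @param series A [transient_series()].
#' @param path File path.
#' @return `write_transient` returns `path` invisibly; `read_transient`
#'   returns the [transient_series()] with the header metadata attached.
#' @export
write_transient <- function(series, path) {
  stopifnot(inherits(series, "transient_series"))
  meta <- attr(series, "meta")
  if (is.null(meta)) meta <- list()
  if (is.null(meta$version)) {
    meta$version <- as.character(utils::packageVersion("excitube"))
  }
  hdr <- vapply(names(meta), function(k) {
    v <- meta[[k]]
    sprintf("# %s = %s", k,
            if (is.numeric(v)) fmt_num(v) else as.character(v))
  }, character(1))
  rows <- sprintf("%s\t%s\t%s", fmt_num(series$time_ps),
                  fmt_num(series$value), fmt_num(series$sem))
  writeLines(c(hdr, "time_ps\tvalue\tsem", rows), path)
  invisible(path)
}

#' @param path File path.
#' @rdname write_transient
#' @export
read_transient <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  n_meta <- match(FALSE, is_meta) - 1L
  if (is.na(n_meta)) n_meta <- length(lines)
  meta <- list()
  for (ln in lines[seq_len(n_meta)]) {
    kv <- regmatches(ln,
                     regexec("^#\\s*([^=[:space:]]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3L) {
      v <- suppressWarnings(as.numeric(kv[3]))
      meta[[kv[2]]] <- if (is.na(v)) kv[3] else v
    }
  }
  if (n_meta + 1L > length(lines)) stop("no column header in ", path)
  cols <- strsplit(lines[n_meta + 1L], "\t", fixed = TRUE)[[1]]
  need <- c("time_ps", "value", "sem")
  if (!identical(cols, need)) {
    stop("missing or misordered columns in ", path, " (line ", n_meta + 1L,
         "): expected 'time_ps value sem'")
  }
  body <- lines[-seq_len(n_meta + 1L)]
  if (!length(body)) stop("no data rows in ", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  for (r in seq_along(parts)) {
    line_no <- n_meta + 1L + r
    if (length(parts[[r]]) != 3L) {
      stop("malformed row in ", path, " at line ", line_no)
    }
    if (anyNA(suppressWarnings(as.numeric(parts[[r]])))) {
      stop("non-numeric value in ", path, " at line ", line_no)
    }
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 3L, byrow = TRUE)
  bad <- which(diff(m[, 1]) <= 0)
  if (length(bad)) {
    stop("non-monotone times in ", path, " at line ", n_meta + 2L + bad[1])
  }
  transient_series(m[, 1], m[, 2], m[, 3], meta = meta)
}

bundle_filename <- function(density, observable_id) {
  sprintf("transient_d%s_%s.tsv", fmt_num(density), observable_id)
}

#' Write / read an experiment bundle as a directory of transient tables
#'
#' @param bundle An [experiment_bundle()] (or [generate_bundle()] result,
#'   whose truth sidecar is stored as `truth.yaml`).
#' @param dir Directory (created if needed).
#' @return `write_bundle` returns `dir` invisibly; `read_bundle` the
#'   reconstructed object.
#' @export
write_bundle <- function(bundle, dir) {
  truth <- NULL
  if (inherits(bundle, "synthetic_bundle")) {
    truth <- bundle$truth
    bundle <- bundle$bundle
  }
  stopifnot(inherits(bundle, "experiment_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in bundle$entries) {
    meta <- attr(e$series, "meta")
    meta$observable_id <- e$observable_id
    meta$density <- e$density
    attr(e$series, "meta") <- meta
    write_transient(e$series, file.path(dir, bundle_filename(e$density,
                                                             e$observable_id)))
  }
  writeLines(bundle$kind, file.path(dir, "kind.txt"))
  if (!is.null(truth)) {
    tr <- truth
    tr$params <- unclass(tr$params)
    tr$system <- NULL  # rebuilt from kind; lattice stored explicitly
    tr$lattice <- lapply(truth$system$layers, function(sp) unclass(sp))
    yaml::write_yaml(unclass(tr), file.path(dir, "truth.yaml"),
                     precision = 15L)
  }
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  kind <- readLines(file.path(dir, "kind.txt"))[1]
  files <- sort(list.files(dir, pattern = "^transient_.*\\.tsv$",
                           full.names = TRUE))
  entries <- lapply(files, function(f) {
    s <- read_transient(f)
    meta <- attr(s, "meta")
    list(density = meta$density, observable_id = meta$observable_id,
         series = s)
  })
  bundle <- experiment_bundle(entries, kind)
  truth_path <- file.path(dir, "truth.yaml")
  if (file.exists(truth_path)) {
    tr <- yaml::read_yaml(truth_path)
    sys_args <- lapply(tr$lattice, function(sp) sp)
    system <- if (kind == "single") {
      single_wall_system(sys_args$inner$n_circ, sys_args$inner$n_axial,
                         sys_args$inner$lattice_const)
    } else {
      double_wall_system(sys_args$inner$n_circ, sys_args$outer$n_circ,
                         sys_args$inner$n_axial, sys_args$inner$lattice_const)
    }
    truth <- truth_params(kind = tr$kind,
                          params = do.call(sim_params, tr$params[
                            setdiff(names(tr$params), character())]),
                          system = system,
                          densities = unlist(tr$densities),
                          times_ps = unlist(tr$times_ps),
                          noise = tr$noise, seed = tr$seed)
    return(structure(list(bundle = bundle, truth = truth),
                     class = "synthetic_bundle"))
  }
  bundle
}

#' Default run configuration
#'
#' Nested configuration reproducing the published parameter table: lattice
#' block (wall sizes, lattice constant), kinetics block ([sim_params()]
#' fields), thermal block, HSR block (geometry and model inputs, no silent
#' defaults for the lattice-specific values), and run block. All physical
#' quantities carry explicit units in their key names.
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    lattice = list(n_circ_inner = 30L, n_circ_outer = 55L, n_axial = 1000L,
                   lattice_const_nm = 0.74),
    kinetics = list(dt_fs = 1, hop_prob = 0.04, lifetime_ps = 33,
                    ann_radius_sites = 3, k_io_fs1 = 0.0013,
                    k_oi_fs1 = 0.0031, density_mol_per_exciton = 625),
    thermal = list(delta_E_cm1 = 300, kBT_cm1 = 200, dos_ratio = 55 / 30),
    hsr = list(geometry = "helical_cylinder", radius_nm = NULL,
               pitch_nm = NULL, dipole_tilt_deg = NULL,
               dipole_length_nm = NULL, dipole_charge_e = NULL,
               gamma_radfs = NULL, kBT_cm1 = 200),
    run = list(seed = 1L, n_real = 50L, t_max_ps = 50,
               sampling_points = 40L))
}

#' Read and validate a run configuration file (YAML)
#'
#' @param path YAML file with the blocks of [default_run_config()].
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (blk in c("lattice", "kinetics", "run")) {
    if (is.null(cfg[[blk]])) stop("config is missing block '", blk, "'")
  }
  ref <- default_run_config()
  for (blk in c("lattice", "kinetics")) {
    missing_keys <- setdiff(names(ref[[blk]]), names(cfg[[blk]]))
    if (length(missing_keys)) {
      stop("config block '", blk, "' is missing key '", missing_keys[1], "'")
    }
  }
  cfg
}

#' Configuration to simulation objects
#'
#' @param cfg A configuration list from [read_run_config()].
#' @param kind `"single"` or `"double"`.
#' @return List with `system` and `params`.
#' @export
config_to_system <- function(cfg, kind = c("double", "single")) {
  kind <- match.arg(kind)
  lat <- cfg$lattice
  kin <- cfg$kinetics
  system <- if (kind == "single") {
    single_wall_system(lat$n_circ_inner, lat$n_axial, lat$lattice_const_nm)
  } else {
    double_wall_system(lat$n_circ_inner, lat$n_circ_outer, lat$n_axial,
                       lat$lattice_const_nm)
  }
  params <- sim_params(dt = kin$dt_fs, hop_prob = kin$hop_prob,
                       lifetime_ps = kin$lifetime_ps,
                       ann_radius = kin$ann_radius_sites,
                       k_io = kin$k_io_fs1, k_oi = kin$k_oi_fs1,
                       density = kin$density_mol_per_exciton,
                       t_max_ps = cfg$run$t_max_ps,
                       n_real = cfg$run$n_real, seed = cfg$run$seed)
  list(system = system, params = params)
}

#' Spectroscopic unit conversions
#'
#' `nm_to_wavenumber` converts a wavelength to wavenumbers (10^7 / lambda):
#' the outer-wall absorption at 589 nm is ~17,000 cm^-1, the inner-wall at
#' 599 nm ~16,700 cm^-1. `nyquist_limit` and `axis_resolution` give the
#' excitation-axis Nyquist limit and resolution of a double-pulse delay
#' scan in the double-sided FFT convention, `1/(2 c dt)` and
#' `1/(2 c t_max)`: a 0.38 fs step and 197.6 fs span yield ~44,000 and
#' ~84 cm^-1. (The single-sided convention would give twice the
#' resolution value and is not used.)
#'
#' @param lambda_nm Wavelength in nm (> 0).
#' @return Wavenumber(s) in cm^-1.
#' @export
nm_to_wavenumber <- function(lambda_nm) {
  if (any(lambda_nm <= 0)) stop("wavelength must be positive")
  1e7 / lambda_nm
}

#' @param dt_fs Delay step in fs (> 0).
#' @rdname nm_to_wavenumber
#' @export
nyquist_limit <- function(dt_fs) {
  if (any(dt_fs <= 0)) stop("delay step must be positive")
  1 / (2 * C_CM_PER_FS * dt_fs)
}

#' @param t_max_fs Maximum scanned delay in fs (> 0).
#' @rdname nm_to_wavenumber
#' @export
axis_resolution <- function(t_max_fs) {
  if (any(t_max_fs <= 0)) stop("delay span must be positive")
  1 / (2 * C_CM_PER_FS * t_max_fs)
}
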