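DISPERSION_HEADER <- c("wavenumber_cm-1", "eps_re", "eps_im", "kappa_re", "kappa_im")

#' Read tabulated optical constants from CSV
#'
#' Schema: header `wavenumber_cm-1,eps_re,eps_im,kappa_re,kappa_im[,mu_re,mu_im]`
#' with a strictly increasing first column. Malformed headers, non-numeric
#' cells and non-monotone grids are reported distinctly.
#'
#' @param path CSV file path.
#' @return a [dispersion_table()].
#' @export
read_dispersion_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("dispersion file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  has_mu <- all(c("mu_re", "mu_im") %in% names(df))
  want <- if (has_mu) c(DISPERSION_HEADER, "mu_re", "mu_im") else DISPERSION_HEADER
  if (!identical(names(df)[seq_along(want)], want)) {
    stop(sprintf("malformed dispersion header; expected '%s', got '%s'",
                 paste(want, collapse = ","), paste(names(df), collapse = ",")),
         call. = FALSE)
  }
  for (cn in want) {
    if (!is.numeric(df[[cn]]) || any(!is.finite(df[[cn]]))) {
      stop(sprintf("non-numeric or non-finite values in column '%s'", cn), call. = FALSE)
    }
  }
  if (any(diff(df[["wavenumber_cm-1"]]) <= 0)) {
    stop("wavenumber column must be strictly increasing", call. = FALSE)
  }
  dispersion_table(
    nu = df[["wavenumber_cm-1"]],
    eps = complex(real = df$eps_re, imaginary = df$eps_im),
    kappa = complex(real = df$kappa_re, imaginary = df$kappa_im),
    mu = if (has_mu) complex(real = df$mu_re, imaginary = df$mu_im) else 1 + 0i)
}

#' Write a dispersion table to CSV
#'
#' Inverse of [read_dispersion_csv()]; the round trip reproduces values
#' bit-identically (values are written with full precision).
#'
#' @param tab a [dispersion_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dispersion_csv <- function(tab, path) {
  stopifnot(inherits(tab, "dispersion_table"))
  df <- data.frame(check.names = FALSE,
                   `wavenumber_cm-1` = tab$nu,
                   eps_re = Re(tab$eps), eps_im = Im(tab$eps),
                   kappa_re = Re(tab$kappa), kappa_im = Im(tab$kappa),
                   mu_re = Re(tab$mu), mu_im = Im(tab$mu))
  write_csv_full(df, path)
  invisible(path)
}

# full-precision CSV writer with a schema comment line
write_csv_full <- function(df, path, schema = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(schema)) writeLines(paste0("# vcdtmm ", schema), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Write a spectrum table to CSV
#'
#' Columns `wavenumber_cm-1,T_plus,T_minus,A_plus,A_minus,vcd`; schema
#' version recorded in a leading comment line.
#'
#' @param sp a `spectrum_set` from [simulate_spectrum()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(sp, path) {
  df <- data.frame(check.names = FALSE,
                   `wavenumber_cm-1` = sp$wavenumber_cm.1,
                   T_plus = sp$T_plus, T_minus = sp$T_minus,
                   A_plus = sp$A_plus, A_minus = sp$A_minus, vcd = sp$vcd)
  write_csv_full(df, path, schema = "spectrum schema v1")
  invisible(path)
}

#' Write an angular map in long format
#'
#' One row per `(theta, wavenumber)` cell with columns
#' `theta_deg,wavenumber_cm-1,vcd_bl,vcd_parallel,vcd_full,dev_itf,dev_cpl,masked`.
#'
#' @param map an `angular_map` from [deviation_maps()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "angular_map"))
  grid <- expand.grid(nu = map$nu_grid, theta = map$theta_grid)
  # matrices are theta x nu; expand.grid varies nu fastest -> transpose order
  flat <- function(m) as.vector(t(m))
  df <- data.frame(check.names = FALSE,
                   theta_deg = grid$theta, `wavenumber_cm-1` = grid$nu,
                   vcd_bl = flat(map$vcd_bl), vcd_parallel = flat(map$vcd_parallel),
                   vcd_full = flat(map$vcd_full), dev_itf = flat(map$dev_itf),
                   dev_cpl = flat(map$dev_cpl), masked = as.integer(flat(map$mask)))
  write_csv_full(df, path, schema = "angular map schema v1")
  invisible(path)
}

material_from_config <- function(mc, name, base_dir) {
  if (!is.list(mc)) stop(sprintf("material '%s' must be an object", name), call. = FALSE)
  if (!is.null(mc$preset)) {
    if (mc$preset != "ideal_absorber") {
      stop(sprintf("material '%s': unknown preset '%s'", name, mc$preset), call. = FALSE)
    }
    k0 <- if (is.null(mc$kappa_0)) 1e-5 else as.numeric(mc$kappa_0)
    return(ideal_absorber(k0))
  }
  type <- mc$type
  if (is.null(type)) stop(sprintf("material '%s': missing 'type' or 'preset'", name), call. = FALSE)
  if (type == "oscillators") {
    oscs <- mc$oscillators
    if (is.null(oscs)) stop(sprintf("material '%s': missing 'oscillators'", name), call. = FALSE)
    if (is.data.frame(oscs)) oscs <- split(oscs, seq_len(nrow(oscs)))
    getv <- function(field) vapply(oscs, function(o) as.numeric(o[[field]]), numeric(1))
    osc <- oscillator_set(eps_inf = as.numeric(mc$eps_inf),
                          nu_p = as.numeric(mc$nu_p),
                          kappa_0 = if (is.null(mc$kappa_0)) 0 else as.numeric(mc$kappa_0),
                          nu_0 = getv("nu_0"), f = getv("f"), gamma = getv("gamma"))
    chiral_material(osc, name = name)
  } else if (type == "dispersion_csv") {
    if (is.null(mc$path)) stop(sprintf("material '%s': missing 'path'", name), call. = FALSE)
    p <- mc$path
    if (!file.exists(p) && !is.null(base_dir)) p <- file.path(base_dir, mc$path)
    chiral_material(read_dispersion_csv(p), name = name)
  } else if (type == "constant") {
    eps <- complex(real = as.numeric(mc$eps_re %||% 1),
                   imaginary = as.numeric(mc$eps_im %||% 0))
    mu <- complex(real = as.numeric(mc$mu_re %||% 1),
                  imaginary = as.numeric(mc$mu_im %||% 0))
    kap <- complex(real = as.numeric(mc$kappa_re %||% 0),
                   imaginary = as.numeric(mc$kappa_im %||% 0))
    chiral_material(eps, mu = mu, kappa = kap, name = name)
  } else {
    stop(sprintf("material '%s': unknown type '%s'", name, type), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a simulation configuration
#'
#' JSON configuration (YAML is not supported: no YAML parser is available
#' in the dependency set). Defaults: `mu = 1`, a single plane wave at
#' `theta = 0` when `illumination` is omitted, and grid 200-4500 cm^-1
#' with step 1 when `grid` is omitted. Every validation failure names the
#' offending key.
#'
#' @param path path to a JSON file with blocks `materials`, `stack`,
#'   optional `illumination` (`theta_deg` list or `aperture` block with
#'   `na_in`, `na_out`, `n_in`, `n_out`), optional
#'   `grid` (`start`, `stop`, `step` in cm^-1) and optional `seed`.
#' @return list of class `"simulation_config"` with resolved `stack`
#'   ([optical_stack()]), `nu_grid`, `theta_deg` and/or `aperture`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  base_dir <- dirname(normalizePath(path))
  if (is.null(cfg$materials) || !length(cfg$materials)) {
    stop("config key 'materials' is missing or empty", call. = FALSE)
  }
  mats <- list()
  for (nm in names(cfg$materials)) {
    mats[[nm]] <- material_from_config(cfg$materials[[nm]], nm, base_dir)
  }
  resolve <- function(ref, key) {
    if (is.null(ref)) stop(sprintf("config key '%s' is missing", key), call. = FALSE)
    if (is.character(ref)) {
      if (ref == "air" && is.null(mats[[ref]])) return(chiral_material(1, name = "air"))
      if (is.null(mats[[ref]])) {
        stop(sprintf("config key '%s': unresolved material reference '%s'", key, ref),
             call. = FALSE)
      }
      mats[[ref]]
    } else material_from_config(ref, key, base_dir)
  }
  sc <- cfg$stack
  if (is.null(sc)) stop("config key 'stack' is missing", call. = FALSE)
  ambient <- resolve(sc$ambient %||% "air", "stack.ambient")
  exit <- resolve(sc$exit %||% "air", "stack.exit")
  layers <- lapply(seq_along(sc$layers %||% list()), function(i) {
    lc <- sc$layers[[i]]
    d <- lc$thickness_um
    if (is.null(d) || !is.numeric(as.numeric(d)) || as.numeric(d) <= 0) {
      stop(sprintf("config key 'stack.layers[%d].thickness_um' must be > 0", i),
           call. = FALSE)
    }
    layer(resolve(lc$material, sprintf("stack.layers[%d].material", i)), as.numeric(d))
  })
  stk <- optical_stack(ambient, layers, exit)

  g <- cfg$grid %||% list(start = 200, stop = 4500, step = 1)
  for (k in c("start", "stop", "step")) {
    if (is.null(g[[k]]) || !is.finite(as.numeric(g[[k]]))) {
      stop(sprintf("config key 'grid.%s' is missing or non-numeric", k), call. = FALSE)
    }
  }
  if (as.numeric(g$step) <= 0) stop("config key 'grid.step' must be > 0", call. = FALSE)
  if (as.numeric(g$stop) <= as.numeric(g$start)) {
    stop("config key 'grid.stop' must exceed 'grid.start'", call. = FALSE)
  }
  nu_grid <- seq(as.numeric(g$start), as.numeric(g$stop), by = as.numeric(g$step))

  ill <- cfg$illumination %||% list(theta_deg = 0)
  theta_deg <- NULL; aperture <- NULL
  if (!is.null(ill$aperture)) {
    ap <- ill$aperture
    for (k in c("na_in", "na_out")) {
      if (is.null(ap[[k]])) {
        stop(sprintf("config key 'illumination.aperture.%s' is missing", k), call. = FALSE)
      }
    }
    aperture <- aperture_config(as.numeric(ap$na_in), as.numeric(ap$na_out),
                                as.integer(ap$n_in %||% 64L),
                                as.integer(ap$n_out %||% ap$n_in %||% 64L))
  } else {
    theta_deg <- as.numeric(unlist(ill$theta_deg %||% 0))
    if (any(theta_deg < 0 | theta_deg >= 90)) {
      stop("config key 'illumination.theta_deg' must lie in [0, 90)", call. = FALSE)
    }
  }
  structure(list(materials = mats, stack = stk, nu_grid = nu_grid,
                 theta_deg = theta_deg, aperture = aperture,
                 seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed)),
            class = "simulation_config")
}
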