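# Network file (JSON) and waveform (CSV) input/output.

#' Read a network description file
#'
#' Loads a JSON network document and builds a validated [network_model()].
#' The document has sections `fluid`, `segments`, `junctions`, `inlet`,
#' `outlets`, and optionally `zeroth` and `solver`. A top-level
#' `units: "CGS"` declares centimetre-gram-second inputs (lengths in cm,
#' kinematic viscosity in cm^2/s, density in g/cm^3, flows in cm^3/s,
#' pressures in mmHg), converted to SI on read; the default is SI.
#' Defaults applied: element length 1 cm, `xi = 3`, Womersley friction,
#' radius-linear interpolation.
#'
#' @param path File path.
#' @return A [network_model()].
#' @export
read_network_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  cgs <- identical(toupper(doc$units %||% "SI"), "CGS")
  len <- function(x) if (cgs) x * 1e-2 else x           # cm -> m
  visc <- function(x) if (cgs) x * 1e-4 else x          # cm^2/s -> m^2/s
  dens <- function(x) if (cgs) x * 1e3 else x           # g/cm^3 -> kg/m^3
  flow <- function(x) if (cgs) x * 1e-6 else x          # cm^3/s -> m^3/s
  pres <- function(x) if (cgs) mmHg_to_Pa(x) else x     # mmHg -> Pa
  fl <- doc$fluid %||% list()
  dens_default <- if (cgs) 1.04 else 1040
  visc_default <- if (cgs) 0.04 else 4e-6
  props <- fluid_properties(dens(fl$density %||% dens_default),
                            visc(fl$kinematic_viscosity %||% visc_default))
  segments <- lapply(doc$segments, function(sd) {
    for (f in c("id", "length")) if (is.null(sd[[f]]))
      stop(sprintf("segment missing field '%s'", f))
    wall <- NULL
    if (!is.null(sd$wall_law)) {
      wl <- sd$wall_law
      if (is.null(wl$type)) stop("wall_law needs a 'type'")
      wall <- wall_law(kind = wl$type,
                       a_0 = len(sd$radius_in %||% sd$radius),
                       c_0 = sd$pwv %||% wl$pwv %||%
                         empirical_pwv(sd$pwv_law %||% "olufsen_exp",
                                       len(sd$radius_in %||% sd$radius)),
                       p_0 = pres(wl$p_0 %||% 0),
                       rho = props$rho, b = wl$b)
    }
    vessel_segment(
      id = sd$id, length = len(sd$length),
      a_in = len(sd$radius_in %||% sd$radius),
      a_out = len(sd$radius_out %||% sd$radius_in %||% sd$radius),
      element_length = len(sd$element_length %||% (if (cgs) 1 else 0.01)),
      interpolation = sd$interpolation %||% "radius",
      pwv = sd$pwv, pwv_law = sd$pwv_law, wall = wall)
  })
  junctions <- lapply(doc$junctions %||% list(), function(j)
    list(parents = as.character(j$parents),
         daughters = as.character(j$daughters)))
  inl <- doc$inlet
  if (is.null(inl)) stop("network file has no inlet section")
  inlet <- list(segment = inl$segment, kind = inl$kind)
  if (!is.null(inl$waveform_file)) {
    wf <- read_waveform_file(inl$waveform_file)
    vals <- if (grepl("pressure", inl$kind)) pres(wf$value) else flow(wf$value)
    inlet$values <- vals
    inlet$period <- wf$period
  } else if (!is.null(inl$values)) {
    inlet$values <- if (grepl("pressure", inl$kind)) pres(inl$values)
                    else flow(inl$values)
    inlet$period <- inl$period
  } else stop("inlet needs 'waveform_file' or 'values' + 'period'")
  outlets <- lapply(doc$outlets %||% list(), function(o) {
    m <- list(model = o$model)
    if (identical(o$model, "windkessel3")) {
      m$R1 <- o$R1; m$R2 <- o$R2; m$C <- o$C
      if (any(vapply(m[c("R1", "R2", "C")], is.null, TRUE)))
        stop("windkessel3 outlet needs R1, R2, C")
    } else if (identical(o$model, "resistance")) {
      m$R_out <- o$R_out
      m$p_out <- pres(o$p_out %||% 0)
      if (is.null(m$R_out)) stop("resistance outlet needs R_out")
    } else if (!identical(o$model, "non_reflecting"))
      stop(sprintf("unknown outlet model '%s'", o$model))
    m
  })
  names(outlets) <- vapply(doc$outlets, `[[`, "", "segment")
  z <- doc$zeroth %||% list()
  zeroth <- list(closure = z$closure %||% "resistance",
                 xi = z$xi %||% 3,
                 p_out = pres(z$p_out %||% 0))
  if (!is.null(z$inlet_mean_pressure))
    zeroth$inlet_mean_pressure <- pres(z$inlet_mean_pressure)
  sv <- doc$solver %||% list()
  gm <- sv$gamma_mode %||% "womersley"
  if (is.list(gm) || (is.character(gm) && grepl("^constant:", gm)))
    gm <- as.numeric(sub("^constant:", "", gm))
  net <- network_model(segments, junctions, inlet, outlets, props, zeroth, gm)
  net$solver <- list(n_harmonics = sv$n_harmonics,
                     nonlinear = isTRUE(sv$nonlinear),
                     alpha = sv$alpha %||% 4 / 3)
  net
}

#' Write a network model to a JSON file
#'
#' Serializes a [network_model()] (in SI units) so that
#' [read_network_file()] reproduces it.
#'
#' @param network A [network_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_file <- function(network, path) {
  segs <- lapply(network$segments, function(s) {
    out <- list(id = s$id, length = s$length,
                radius_in = s$a[1L], radius_out = s$a[s$n_elements + 1L],
                element_length = s$length / s$n_elements,
                interpolation = s$interpolation)
    if (!is.null(s$pwv_law)) out$pwv_law <- s$pwv_law
    else out$pwv <- s$c[1L]
    if (!is.null(s$wall))
      out$wall_law <- list(type = s$wall$kind, p_0 = s$wall$p_0,
                           b = s$wall$b, pwv = s$wall$c_0)
    out
  })
  inl <- network$inlet
  spec <- if (!is.null(inl$spectrum)) inl$spectrum
          else fourier_decompose(inl$values, inl$period)
  m <- max(4L * spec$n_max + 4L, 64L)
  inlet <- list(segment = inl$segment, kind = inl$kind,
                period = spec$period,
                values = fourier_reconstruct(spec,
                                             (0:(m - 1L)) * spec$period / m))
  outs <- lapply(names(network$outlets), function(id) {
    c(list(segment = id), network$outlets[[id]])
  })
  doc <- list(units = "SI",
              fluid = list(density = network$fluid$rho,
                           kinematic_viscosity = network$fluid$nu),
              segments = unname(segs), junctions = network$junctions,
              inlet = inlet, outlets = outs, zeroth = network$zeroth,
              solver = list(gamma_mode = network$gamma_mode))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a waveform CSV file
#'
#' Two-column CSV (`time_s`, `value`) with a header row, uniform time grid
#' covering one period with the end point excluded.
#'
#' @param path File path.
#' @return List with `times`, `value`, inferred `period`.
#' @export
read_waveform_file <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("waveform CSV needs two columns (time, value)")
  t <- df[[1L]]; v <- df[[2L]]
  dt <- diff(t)
  if (max(abs(dt - dt[1L])) > 1e-9 * mean(dt))
    stop("waveform time grid is not uniform")
  list(times = t, value = v, period = t[length(t)] - t[1L] + dt[1L])
}

#' Write waveforms to a CSV file
#'
#' @param waveform `data.frame(time, p, q)` from [evaluate_waveform()].
#' @param path Output path.
#' @param units `"SI"` (Pa, m^3/s) or `"clinical"` (adds mmHg and ml/s
#'   columns).
#' @return `path`, invisibly.
#' @export
write_waveform_file <- function(waveform, path, units = "SI") {
  df <- data.frame(time_s = waveform$time, p_Pa = waveform$p,
                   q_m3s = waveform$q)
  if (identical(units, "clinical")) {
    df$p_mmHg <- Pa_to_mmHg(waveform$p)
    df$q_mls <- waveform$q * 1e6
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Solve a network and write site waveforms
#'
#' End-to-end driver behind the command-line tool: solves the network
#' (linear, or with second-order corrections), evaluates the waveforms at
#' the requested sites, writes one CSV per site plus a JSON dump of the
#' harmonic amplitudes (`[re, im]` pairs) and a short run log.
#'
#' @param network A [network_model()] (or a path to a network file).
#' @param sites Character vector `"segment:position"`, where position is
#'   metres from the segment inlet, a fraction with `%%`, or `"mid"`.
#' @param out_dir Output directory (created if needed).
#' @param n_harmonics Harmonics to solve (default: network file setting or
#'   the inlet spectrum's count).
#' @param nonlinear Apply second-order corrections.
#' @param n_times Output samples per period.
#' @param units Output units, see [write_waveform_file()].
#' @return The solution object, invisibly; side effect: files in
#'   `out_dir`.
#' @export
solve_network <- function(network, sites, out_dir = ".",
                          n_harmonics = NULL, nonlinear = FALSE,
                          n_times = 512L, units = "SI") {
  if (is.character(network)) network <- read_network_file(network)
  if (!is.null(network$solver)) {
    n_harmonics <- n_harmonics %||% network$solver$n_harmonics
    nonlinear <- nonlinear || isTRUE(network$solver$nonlinear)
  }
  t0 <- proc.time()[["elapsed"]]
  sol <- if (nonlinear) solve_with_corrections(network, n_harmonics)
         else solve_linear(network, n_harmonics)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  times <- (0:(n_times - 1L)) * sol$period / n_times
  parsed <- lapply(sites, parse_site, network = network)
  for (ps in parsed) {
    wf <- evaluate_waveform(sol, ps$segment, ps$x, times)
    write_waveform_file(wf, file.path(out_dir,
                                      sprintf("%s_x%.4gm.csv", ps$segment,
                                              ps$x)),
                        units = units)
  }
  dump <- list(period = sol$period, n_harmonics = sol$n_max,
               residual = sol$residual,
               segments = lapply(colnames(sol$P_hat), function(id) list(
                 id = id,
                 P_hat = cbind(Re(sol$P_hat[, id]), Im(sol$P_hat[, id])),
                 Q_hat = cbind(Re(sol$Q_hat[, id]), Im(sol$Q_hat[, id])))))
  jsonlite::write_json(dump, file.path(out_dir, "solution.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(sprintf(
    "harmonics=%d period=%gs residual=%.3e nonlinear=%s elapsed=%.2fs",
    sol$n_max, sol$period, sol$residual, nonlinear,
    proc.time()[["elapsed"]] - t0),
    file.path(out_dir, "run.log"))
  invisible(sol)
}

parse_site <- function(site, network) {
  parts <- strsplit(site, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop(sprintf("site '%s' is not of the form segment:position", site))
  seg <- network$segments[[parts[1L]]]
  if (is.null(seg)) stop(sprintf("unknown segment '%s'", parts[1L]))
  pos <- parts[2L]
  x <- if (identical(pos, "mid")) seg$length / 2
       else if (grepl("%$", pos))
         as.numeric(sub("%$", "", pos)) / 100 * seg$length
       else as.numeric(pos)
  if (is.na(x) || x < 0 || x > seg$length + 1e-12)
    stop(sprintf("position '%s' outside segment '%s'", pos, parts[1L]))
  list(segment = parts[1L], x = x)
}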