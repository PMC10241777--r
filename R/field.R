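#' Specification of an analytic synthetic velocity field
#'
#' Describes one of four analytic surface-current fields used as stand-ins
#' for hindcast ocean-model forcing: `zero` (still water), `uniform`
#' (constant zonal current), `solid_rotation` (rigid-body rotation about a
#' centre, speed = omega * r), and `double_gyre` (two counter-rotating
#' gyres derived from a streamfunction, hence divergence-free).
#'
#' @param kind One of `"zero"`, `"uniform"`, `"solid_rotation"`,
#'   `"double_gyre"`.
#' @param lon,lat Length-2 numeric bounds in decimal degrees.
#' @param step Grid step in degrees, shared by both axes. Must be > 0.
#' @param n_days Number of daily field slices (>= 1).
#' @param amplitude Peak current speed in m/s.
#' @param center Rotation centre `c(lon, lat)` for `solid_rotation`;
#'   defaults to the domain centre.
#' @param omega Angular rate in rad/s for `solid_rotation`. Default scales
#'   so the speed at the farthest grid corner equals `amplitude`.
#' @param wobble For `double_gyre`: amplitude (as a fraction of the domain
#'   width) of a seasonal east-west oscillation of the gyre pattern, giving
#'   day-to-day variability like a hindcast product; 0 (default) is steady.
#' @param period_days Period of the wobble oscillation (default 365).
#' @param start_date Date of the first field slice.
#' @return An object of class `field_spec`.
#' @export
#' @examples
#' field_spec("double_gyre", lon = c(0, 20), lat = c(0, 10), step = 0.5)
field_spec <- function(kind = c("zero", "uniform", "solid_rotation", "double_gyre"),
                       lon = c(0, 10), lat = c(0, 10), step = 0.5,
                       n_days = 1L, amplitude = 0.1, center = NULL,
                       omega = NULL, wobble = 0, period_days = 365,
                       start_date = as.Date("2008-01-01")) {
  kind <- match.arg(kind)
  if (length(lon) != 2 || length(lat) != 2 || diff(lon) <= 0 || diff(lat) <= 0)
    stop_spec("field_spec: bounds must define a non-empty rectangle")
  if (!is.numeric(step) || length(step) != 1 || step <= 0)
    stop_spec("field_spec: grid step must be a single positive number")
  if (!is_count(n_days))
    stop_spec("field_spec: n_days must be a positive integer")
  if (!is.numeric(amplitude) || amplitude < 0)
    stop_spec("field_spec: amplitude must be non-negative (m/s)")
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  structure(list(kind = kind, lon = lon, lat = lat, step = step,
                 n_days = as.integer(n_days), amplitude = amplitude,
                 center = center, omega = omega, wobble = wobble,
                 period_days = period_days,
                 start_date = as.Date(start_date)),
            class = "field_spec")
}

#' Build a gridded daily velocity field from an analytic specification
#'
#' Evaluates the analytic field of a [field_spec()] on a regular lon/lat
#' grid for each day. Land nodes (from `land`) carry `NA` velocities, the
#' missing-value convention of gridded current products; interpolation
#' renormalises over the remaining ocean nodes.
#'
#' The `double_gyre` streamfunction is defined in lon/lat coordinate space,
#' `psi = sin(2*pi*sx) * sin(pi*sy)` on the unit-scaled domain, with
#' `u = -dpsi/dlat` and `v = +dpsi/dlon` (scaled to `amplitude` m/s), so the
#' field is divergence-free in grid coordinates by construction.
#'
#' @param spec A [field_spec()].
#' @param land Optional land mask: either a logical matrix of dim
#'   `c(n_lon, n_lat)` (`TRUE` = land) or a vectorised function
#'   `f(lon, lat)` returning logicals.
#' @return A `velocity_field`: list with `lon`, `lat` (node coordinates),
#'   `days` (Date vector), `u`, `v` (arrays `[lon, lat, day]`, m/s, `NA` on
#'   land) and `land` (logical matrix `[lon, lat]`).
#' @export
make_velocity_field <- function(spec, land = NULL) {
  stopifnot(inherits(spec, "field_spec"))
  lon <- seq(spec$lon[1], spec$lon[2], by = spec$step)
  lat <- seq(spec$lat[1], spec$lat[2], by = spec$step)
  nx <- length(lon); ny <- length(lat)
  if (nx < 2 || ny < 2)
    stop_spec("make_velocity_field: grid must have at least 2 nodes per axis")

  if (is.null(land)) {
    mask <- matrix(FALSE, nx, ny)
  } else if (is.function(land)) {
    mask <- outer(lon, lat, land)
  } else {
    mask <- land
    if (!is.logical(mask) || !all(dim(mask) == c(nx, ny)))
      stop_spec("make_velocity_field: land mask must be logical [n_lon, n_lat]")
  }

  LON <- matrix(lon, nx, ny)
  LAT <- matrix(lat, nx, ny, byrow = TRUE)
  a <- spec$amplitude

  uv <- switch(spec$kind,
    zero = list(u = LON * 0, v = LON * 0),
    uniform = list(u = LON * 0 + a, v = LON * 0),
    solid_rotation = {
      r_m <- EARTH_RADIUS_KM * 1000
      x <- r_m * cos(spec$center[2] * pi / 180) * (LON - spec$center[1]) * pi / 180
      y <- r_m * (LAT - spec$center[2]) * pi / 180
      omega <- spec$omega
      if (is.null(omega)) {
        r_max <- max(sqrt(x^2 + y^2))
        omega <- if (r_max > 0) a / r_max else 0
      }
      list(u = -omega * y, v = omega * x)
    },
    double_gyre = {
      sy <- (LAT - spec$lat[1]) / diff(spec$lat)
      # psi = C sin(2 pi (sx + phase_d)) sin(pi sy); u = -dpsi/dlat,
      # v = +dpsi/dlon, C scaled so the peak speed equals `amplitude`.
      # A non-zero wobble shifts the gyre phase seasonally, one phase per
      # daily slice; the field stays streamfunction-derived every day.
      wx <- 2 * pi / diff(spec$lon)
      wy <- pi / diff(spec$lat)
      C <- a / max(wx, wy)
      gyre_uv <- function(phase) {
        sx <- (LON - spec$lon[1]) / diff(spec$lon) + phase
        list(u = -C * wy * sin(2 * pi * sx) * cos(pi * sy),
             v = C * wx * cos(2 * pi * sx) * sin(pi * sy))
      }
      if (spec$wobble == 0) gyre_uv(0) else {
        phases <- spec$wobble * sin(2 * pi * (seq_len(spec$n_days) - 1) /
                                      spec$period_days)
        lapply(phases, gyre_uv)
      }
    })

  if (is.list(uv) && !is.null(uv$u)) {
    uv$u[mask] <- NA_real_
    uv$v[mask] <- NA_real_
    u <- array(uv$u, dim = c(nx, ny, spec$n_days))
    v <- array(uv$v, dim = c(nx, ny, spec$n_days))
  } else {
    # one slice per day (wobbling gyre)
    u <- array(NA_real_, c(nx, ny, spec$n_days))
    v <- array(NA_real_, c(nx, ny, spec$n_days))
    for (d in seq_len(spec$n_days)) {
      ud <- uv[[d]]$u; vd <- uv[[d]]$v
      ud[mask] <- NA_real_; vd[mask] <- NA_real_
      u[, , d] <- ud; v[, , d] <- vd
    }
  }
  structure(list(lon = lon, lat = lat,
                 days = spec$start_date + seq_len(spec$n_days) - 1L,
                 u = u, v = v, land = mask),
            class = "velocity_field")
}

#' Assemble a velocity field from explicit arrays
#'
#' Low-level constructor for fields not produced by [make_velocity_field()]
#' (e.g. read from file or built in tests).
#'
#' @param lon,lat Strictly increasing node coordinates (degrees).
#' @param days Date vector, one entry per daily slice.
#' @param u,v Arrays `[lon, lat, day]` in m/s (`NA` allowed on land only).
#' @param land Logical land mask `[lon, lat]`; default all ocean.
#' @return A `velocity_field`.
#' @export
velocity_field <- function(lon, lat, days, u, v, land = NULL) {
  nx <- length(lon); ny <- length(lat); nd <- length(days)
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0))
    stop_spec("velocity_field: grids must be strictly increasing")
  if (is.null(land)) land <- matrix(FALSE, nx, ny)
  if (length(u) == nx * ny) u <- array(u, c(nx, ny, nd))
  if (length(v) == nx * ny) v <- array(v, c(nx, ny, nd))
  if (!all(dim(u) == c(nx, ny, nd)) || !all(dim(v) == c(nx, ny, nd)))
    stop_spec("velocity_field: u/v must be [n_lon, n_lat, n_days]")
  ocean <- !land
  if (anyNA(u[, , 1][ocean]) || anyNA(v[, , 1][ocean]))
    stop_spec("velocity_field: u,v must be finite on ocean nodes")
  structure(list(lon = lon, lat = lat, days = as.Date(days),
                 u = u, v = v, land = land),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d x %d nodes, %d day(s), %.0f%% land\n",
              length(x$lon), length(x$lat), length(x$days),
              100 * mean(x$land)))
  cat(sprintf("  lon [%g, %g]  lat [%g, %g]  %s .. %s\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat),
              min(x$days), max(x$days)))
  invisible(x)
}

#' Write / read a velocity field as long-format CSV
#'
#' Columns: `day` (ISO date), `lon`, `lat`, `u`, `v` (m/s; empty on land)
#' and `land` (0/1). One row per grid node per day.
#'
#' @param field A `velocity_field`.
#' @param path File path.
#' @return `write_field_csv` returns `path` invisibly; `read_field_csv`
#'   returns a `velocity_field`.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "velocity_field"))
  nx <- length(field$lon); ny <- length(field$lat)
  grid <- expand.grid(lon = field$lon, lat = field$lat,
                      KEEP.OUT.ATTRS = FALSE)
  out <- do.call(rbind, lapply(seq_along(field$days), function(d) {
    data.frame(day = as.character(field$days[d]),
               lon = grid$lon, lat = grid$lat,
               u = as.vector(field$u[, , d]), v = as.vector(field$v[, , d]),
               land = as.integer(as.vector(field$land)))
  }))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  days <- sort(unique(as.Date(df$day)))
  nx <- length(lon); ny <- length(lat); nd <- length(days)
  u <- array(NA_real_, c(nx, ny, nd)); v <- u
  land <- matrix(FALSE, nx, ny)
  ix <- match(df$lon, lon); iy <- match(df$lat, lat)
  id <- match(as.Date(df$day), days)
  u[cbind(ix, iy, id)] <- df$u
  v[cbind(ix, iy, id)] <- df$v
  land[cbind(ix, iy)] <- df$land == 1
  velocity_field(lon, lat, days, u, v, land)
}
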