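# Analytic spherical-conductor MEG forward model.
#
# The magnetic field of a current dipole inside a homogeneous conducting
# sphere has a closed form (the Sarvas formula). It is exact for spherical
# conductors, depends only on the sphere center (not its radius or
# conductivity), and is the standard stand-in for boundary-element head models
# in MEG simulation work. Positions are in mm, dipole moments in nA.m, fields
# in T (magnetometers) or T/m (planar gradiometers).

MU0 <- 4e-7 * pi

#' Magnetic field of a current dipole in a spherical conductor
#'
#' Evaluates the Sarvas closed-form field of a current dipole inside a
#' homogeneous sphere and projects it onto a sensor orientation. Radial
#' dipole components are magnetically silent, and a dipole at the sphere
#' center produces no field.
#'
#' @param dipole_position Length-3, mm.
#' @param dipole_moment Length-3 moment, nA.m.
#' @param sensor_position Length-3, mm (strictly outside the conductor).
#' @param sensor_orientation Length-3 unit vector.
#' @param center Sphere center, mm.
#' @param head_radius Optional conductor radius (mm) used to validate that the
#'   dipole is strictly inside and the sensor strictly outside.
#' @return Field projection in T per the given moment.
#' @export
sarvas_field <- function(dipole_position, dipole_moment, sensor_position,
                         sensor_orientation, center = c(0, 0, 0),
                         head_radius = NULL) {
  r0 <- (dipole_position - center) * 1e-3
  r <- (sensor_position - center) * 1e-3
  q <- dipole_moment * 1e-9
  rn <- sqrt(sum(r^2))
  r0n <- sqrt(sum(r0^2))
  if (!is.null(head_radius)) {
    hr <- head_radius * 1e-3
    if (r0n >= hr) stop("dipole not strictly inside the conductor sphere")
    if (rn <= hr) stop("sensor not strictly outside the conductor sphere")
  } else if (rn <= r0n) {
    stop("sensor must lie strictly outside the dipole radius")
  }
  a <- r - r0
  an <- sqrt(sum(a^2))
  f <- an * (rn * an + rn^2 - sum(r0 * r))
  adr <- sum(a * r)
  grad_f <- (an^2 / rn + adr / an + 2 * an + 2 * rn) * r -
    (an + 2 * rn + adr / an) * r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  if (sum(qxr0^2) == 0) return(0)
  b <- (MU0 / (4 * pi * f^2)) * (f * qxr0 - sum(qxr0 * r) * grad_f)
  sum(b * sensor_orientation)
}

# Vectorized gain: for one point magnetometer (position p, orientation o) and
# n dipole locations, returns the n x 3 matrix g with B.o = q . g[i, ] for a
# moment q in nA.m at source i. Derived from the Sarvas field via
# (q x r0).x = q.(r0 x x).
sarvas_gain <- function(src_pos_mm, sensor_pos_mm, sensor_ori,
                        center = c(0, 0, 0)) {
  r0 <- sweep(src_pos_mm, 2, center) * 1e-3
  r <- (sensor_pos_mm - center) * 1e-3
  rn <- sqrt(sum(r^2))
  a <- matrix(r, nrow(r0), 3, byrow = TRUE) - r0
  an <- row_norms(a)
  r0dr <- as.vector(r0 %*% r)
  f <- an * (rn * an + rn^2 - r0dr)
  adr <- as.vector(a %*% r)
  c1 <- an^2 / rn + adr / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + adr / an
  grad_f <- outer(c1, r) - c2 * r0
  gdo <- as.vector(grad_f %*% sensor_ori)
  r0xo <- cross3(r0, matrix(sensor_ori, nrow(r0), 3, byrow = TRUE))
  r0xr <- cross3(r0, matrix(r, nrow(r0), 3, byrow = TRUE))
  g <- (MU0 / (4 * pi * f^2)) * (f * r0xo - gdo * r0xr)
  g * 1e-9  # per nA.m
}

#' Build a 306-channel whole-head sensor array
#'
#' Sensor sites are placed near-uniformly on a spherical-cap helmet using a
#' Fibonacci lattice. Each site carries one magnetometer (pickup along the
#' outward radial direction) and two orthogonal planar gradiometers, each
#' modeled as the difference of two point magnetometers separated by
#' `pair_offset` along a tangential baseline, divided by the baseline length.
#'
#' @param n_mag Number of magnetometer sites (default 102).
#' @param n_grad_pairs Number of gradiometer-pair sites (default 102,
#'   co-located with the magnetometers when equal).
#' @param helmet_radius Helmet radius, mm.
#' @param pair_offset Gradiometer baseline, mm.
#' @param cap_min_z Lower edge of the helmet cap as a fraction of the radius
#'   (z/R); the default -0.2 covers the head down to ear level.
#' @param seed Unused (the lattice is deterministic); kept so that callers can
#'   treat array construction like the other seeded generators.
#' @return A `sensor_array` data.frame: channel_id, kind ("mag"/"grad"),
#'   position x/y/z (mm), orientation ox/oy/oz, baseline bx/by/bz,
#'   pair_offset (mm; NA for magnetometers).
#' @export
build_sensor_array <- function(n_mag = 102, n_grad_pairs = 102,
                               helmet_radius = 120, pair_offset = 17,
                               cap_min_z = -0.2, seed = NULL) {
  fib_cap <- function(n) {
    i <- seq_len(n) - 0.5
    z <- 1 - (1 - cap_min_z) * i / n
    th <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
    rho <- sqrt(pmax(0, 1 - z^2))
    cbind(rho * cos(th), rho * sin(th), z) * helmet_radius
  }
  tangents <- function(u) {
    t1 <- cbind(-u[, 2], u[, 1], 0)
    deg <- row_norms(t1) < 1e-8
    if (any(deg)) t1[deg, ] <- matrix(c(1, 0, 0), sum(deg), 3, byrow = TRUE)
    t1 <- normalize_rows(t1)
    list(t1 = t1, t2 = normalize_rows(cross3(u, t1)))
  }
  rows <- list()
  if (n_mag > 0) {
    p <- fib_cap(n_mag)
    u <- normalize_rows(p)
    rows[[1]] <- data.frame(
      channel_id = sprintf("MAG%03d", seq_len(n_mag)), kind = "mag",
      x = p[, 1], y = p[, 2], z = p[, 3],
      ox = u[, 1], oy = u[, 2], oz = u[, 3],
      bx = NA_real_, by = NA_real_, bz = NA_real_,
      pair_offset = NA_real_, stringsAsFactors = FALSE)
  }
  if (n_grad_pairs > 0) {
    p <- fib_cap(n_grad_pairs)
    u <- normalize_rows(p)
    tg <- tangents(u)
    g1 <- data.frame(
      channel_id = sprintf("GRD%03dA", seq_len(n_grad_pairs)), kind = "grad",
      x = p[, 1], y = p[, 2], z = p[, 3],
      ox = u[, 1], oy = u[, 2], oz = u[, 3],
      bx = tg$t1[, 1], by = tg$t1[, 2], bz = tg$t1[, 3],
      pair_offset = pair_offset, stringsAsFactors = FALSE)
    g2 <- g1
    g2$channel_id <- sprintf("GRD%03dB", seq_len(n_grad_pairs))
    g2$bx <- tg$t2[, 1]; g2$by <- tg$t2[, 2]; g2$bz <- tg$t2[, 3]
    rows[[length(rows) + 1L]] <- g1
    rows[[length(rows) + 1L]] <- g2
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "helmet_radius") <- helmet_radius
  class(out) <- c("sensor_array", "data.frame")
  out
}

#' Tilt near-radial source orientations slightly tangential
#'
#' In a spherical conductor, a dipole oriented along the head-center radial
#' direction is magnetically silent, which makes standardized inverse maps
#' ill-posed at such sources. Orientations within `min_angle` of radial (with
#' respect to `center`) are tilted to exactly `min_angle` from radial, toward
#' the local anterior-posterior fold tangent.
#'
#' @param source_space A `source_space`.
#' @param center Conductor center, mm.
#' @param min_angle Minimum angle from radial, degrees.
#' @return The source space with adjusted unit orientations.
#' @export
regularize_orientations <- function(source_space, center = c(0, 0, 0),
                                    min_angle = 5) {
  ss <- source_space
  u <- normalize_rows(sweep(ss$positions, 2, center))
  o <- ss$orientations
  cosang <- abs(rowSums(o * u))
  thr <- cos(min_angle * pi / 180)
  fix <- which(cosang > thr)
  if (length(fix)) {
    for (i in fix) {
      ui <- u[i, ]
      # tangent toward +y (anterior), falling back to +z at the poles
      t <- c(0, 1, 0) - sum(c(0, 1, 0) * ui) * ui
      if (sum(t^2) < 1e-12) t <- c(0, 0, 1) - sum(c(0, 0, 1) * ui) * ui
      t <- t / sqrt(sum(t^2))
      s <- sign(sum(o[i, ] * ui))
      if (s == 0) s <- 1
      o[i, ] <- cos(min_angle * pi / 180) * s * ui +
        sin(min_angle * pi / 180) * t
    }
  }
  ss$orientations <- normalize_rows(o)
  ss
}

#' Build the MEG lead field for a source space and sensor array
#'
#' Computes, for every channel, the analytic spherical-conductor field of a
#' unit dipole at each source. The fixed-orientation gain (`gain`) contracts
#' the free three-component gain (`gain_free`) with the source orientations;
#' gradiometer rows are finite differences of the two constituent point
#' magnetometers divided by the baseline.
#'
#' @param source_space A `source_space` (all sources strictly inside the head
#'   sphere).
#' @param sensors A `sensor_array`.
#' @param head_radius Conductor radius, mm.
#' @param center Conductor center, mm.
#' @param store_free Keep the free-orientation gain (needed for dipole
#'   fitting)? Triples memory.
#' @return A `leadfield`: `gain` (n_channels x n_sources; T or T/m per nA.m),
#'   `gain_free` (n_channels x 3*n_sources or NULL, source-major x/y/z
#'   triplets), `sensors`, `source_space`, `head_radius`, `center`.
#' @export
build_leadfield <- function(source_space, sensors, head_radius = 90,
                            center = c(0, 0, 0), store_free = TRUE) {
  ss <- source_space
  pos <- ss$positions
  d <- row_norms(sweep(pos, 2, center))
  bad <- which(d >= head_radius)
  if (length(bad))
    stop("source(s) outside the head sphere: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  sd_ <- sqrt((sensors$x - center[1])^2 + (sensors$y - center[2])^2 +
              (sensors$z - center[3])^2)
  if (any(sd_ <= head_radius)) stop("sensor(s) inside the head sphere")

  n <- nrow(pos)
  nc <- nrow(sensors)
  gain_free <- matrix(0, nc, 3L * n)
  for (c_i in seq_len(nc)) {
    p <- c(sensors$x[c_i], sensors$y[c_i], sensors$z[c_i])
    o <- c(sensors$ox[c_i], sensors$oy[c_i], sensors$oz[c_i])
    if (sensors$kind[c_i] == "mag") {
      g <- sarvas_gain(pos, p, o, center)
    } else {
      b <- c(sensors$bx[c_i], sensors$by[c_i], sensors$bz[c_i])
      h <- sensors$pair_offset[c_i] / 2
      g_plus <- sarvas_gain(pos, p + h * b, o, center)
      g_minus <- sarvas_gain(pos, p - h * b, o, center)
      g <- (g_plus - g_minus) / (sensors$pair_offset[c_i] * 1e-3)
    }
    gain_free[c_i, ] <- as.vector(t(g))
  }
  ori_flat <- as.vector(t(ss$orientations))
  gain <- gain_free * matrix(ori_flat, nc, 3L * n, byrow = TRUE)
  gain <- gain[, seq(1, 3L * n, by = 3L)] +
    gain[, seq(2, 3L * n, by = 3L)] + gain[, seq(3, 3L * n, by = 3L)]
  structure(list(gain = gain,
                 gain_free = if (store_free) gain_free else NULL,
                 sensors = sensors, source_space = ss,
                 head_radius = head_radius, center = center,
                 cache = new.env(parent = emptyenv())),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("leadfield: %d channels x %d sources (free gain: %s)\n",
              nrow(x$gain), ncol(x$gain), !is.null(x$gain_free)))
  invisible(x)
}

#' Project a source activation to the sensors
#'
#' @param leadfield A `leadfield`.
#' @param activation n_sources x n_times matrix, nA.m.
#' @return n_channels x n_times matrix of sensor data.
#' @export
project_activation <- function(leadfield, activation) {
  if (is.null(dim(activation))) activation <- cbind(activation)
  if (nrow(activation) != ncol(leadfield$gain))
    stop("activation rows must match the number of sources")
  leadfield$gain %*% activation
}
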