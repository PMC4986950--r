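# Flame geometry and convective heat transport: wind-tilted flame angle,
# plume temperature along the plume axis, flame merging over many burning
# leaves, and intersection of the plume axis with crown cross-sections.

#' Flame segment
#'
#' A flame anchored at an origin height, with a length along its axis, an
#' angle from horizontal, the temperature sustained inside the flame
#' envelope, and the remaining heating time it can deliver.
#'
#' @param origin_height Height of the flame base above ground (m).
#' @param flame_length Along-axis flame length (m), >= 0.
#' @param angle Angle from horizontal (radians), in `(0, pi/2]`.
#' @param flame_temperature Temperature inside the flame (deg C).
#' @param duration_remaining Remaining heating time (s), >= 0.
#' @return A list of class `ffm_flame`.
#' @export
ffm_flame <- function(origin_height, flame_length, angle, flame_temperature,
                      duration_remaining) {
  stopifnot(flame_length >= 0, angle > 0, angle <= pi / 2 + 1e-9,
            duration_remaining >= 0)
  structure(list(origin_height = origin_height, flame_length = flame_length,
                 angle = min(angle, pi / 2),
                 flame_temperature = flame_temperature,
                 duration_remaining = duration_remaining),
            class = "ffm_flame")
}

#' Vertical extent of a flame
#' @param flame An [ffm_flame()].
#' @return Flame top height above ground (m): origin + length * sin(angle).
#' @export
flame_height <- function(flame) {
  flame$origin_height + flame$flame_length * sin(flame$angle)
}

#' Flame angle from wind, flame length and slope
#'
#' Buoyancy holds a flame vertical; wind shear tilts it over. The configured
#' relation balances the two as `angle = atan(g L / (c U^2))`, which is
#' vertical at zero wind and strictly decreasing in wind speed at fixed flame
#' length. Slope rotates the effective angle between the plume and the
#' overhead fuel column: downslope spread (negative slope) steepens it,
#' upslope spread flattens it. The result is clamped to
#' `[min_angle, pi/2]`.
#'
#' @param flame_length Flame length (m), >= 0.
#' @param wind_speed Wind speed at the flame (m/s, signed; the magnitude
#'   tilts the flame).
#' @param slope Ground slope (degrees, signed).
#' @param config An [ffm_config()] list.
#' @return Angle from horizontal in radians, in `(0, pi/2]`.
#' @examples
#' flame_angle(1, 0, 0)   # pi/2: vertical at zero wind on flat ground
#' @export
flame_angle <- function(flame_length, wind_speed, slope = 0,
                        config = ffm_config()) {
  co <- cfg_block(config, "flame_angle",
                  c("wind_coef", "slope_coef", "min_angle"))
  u <- abs(wind_speed)
  base <- ifelse(u <= 0 | flame_length <= 0,
                 pi / 2,
                 atan(9.81 * flame_length / (co$wind_coef * u^2)))
  base[flame_length <= 0 & u > 0] <- pi / 2  # a point source is not tilted
  ang <- base - co$slope_coef * slope * pi / 180
  pmin(pi / 2, pmax(co$min_angle, ang))
}

#' Plume temperature along the plume axis
#'
#' Inside the flame envelope the plume holds the flame temperature; beyond
#' the flame tip the temperature decays with distance along the axis
#' following the configured buoyant-plume power law, approaching ambient in
#' the far field and never dropping below it.
#'
#' @param distance Distance along the plume axis from the flame origin (m),
#'   >= 0.
#' @param flame An [ffm_flame()].
#' @param ambient Ambient air temperature (deg C).
#' @param config An [ffm_config()] list.
#' @return Plume air temperature (deg C).
#' @export
plume_temperature <- function(distance, flame, ambient,
                              config = ffm_config()) {
  co <- cfg_block(config, "plume", "decay_exponent")
  stopifnot(all(distance >= 0))
  L <- flame$flame_length
  if (L <= 0) return(rep(ambient, length(distance)))
  dT <- flame$flame_temperature - ambient
  inside <- distance <= L
  out <- numeric(length(distance))
  out[inside] <- flame$flame_temperature
  out[!inside] <- ambient + dT * (L / distance[!inside])^co$decay_exponent
  pmax(out, ambient)
}

#' Merged flame length from many burning leaves
#'
#' Individual leaf flames merge through heat transfer and air entrainment
#' into a larger flame. The configured merging law scales the per-leaf flame
#' length by `n ^ exponent` with exponent <= 1 (sublinear growth): zero for
#' nothing burning, the single-leaf length at n = 1, and monotone
#' non-decreasing in n.
#'
#' @param n_leaves Number of leaves burning, >= 0.
#' @param per_leaf_flame Flame length of one leaf (m).
#' @param config An [ffm_config()] list.
#' @return Merged flame length (m).
#' @export
merged_flame_length <- function(n_leaves, per_leaf_flame,
                                config = ffm_config()) {
  co <- cfg_block(config, "flame_merge", "exponent")
  stopifnot(all(n_leaves >= 0), co$exponent <= 1)
  ifelse(n_leaves <= 0, 0, per_leaf_flame * n_leaves^co$exponent)
}

#' Crown cross-section polygon
#'
#' The symmetric hexagonal cross-section implied by the five crown-envelope
#' parameters: base centre, base edge, top edge heights, crown top height and
#' crown width. Vertices are returned anticlockwise starting at the base
#' centre.
#'
#' @param stratum An [ffm_stratum()].
#' @param centre_x Horizontal position of the crown centreline (m).
#' @return A two-column matrix (x, z) of polygon vertices.
#' @export
crown_polygon <- function(stratum, centre_x = 0) {
  w2 <- stratum$crown_width / 2
  m <- rbind(
    c(0, stratum$crown_base_centre_height),
    c(w2, stratum$crown_base_edge_height),
    c(w2, stratum$crown_top_edge_height),
    c(0, stratum$crown_height),
    c(-w2, stratum$crown_top_edge_height),
    c(-w2, stratum$crown_base_edge_height)
  )
  if (any(!is.finite(m))) stop_invalid("degenerate crown polygon")
  m[, 1] <- m[, 1] + centre_x
  colnames(m) <- c("x", "z")
  m
}

# distances t >= 0 at which the ray p0 + t*(cos a, sin a) crosses the
# boundary of a convex polygon; returns numeric(0) on a miss
ray_polygon_crossings <- function(p0, angle, poly) {
  d <- c(cos(angle), sin(angle))
  n <- nrow(poly)
  ts <- numeric(0)
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1 else i + 1, ]
    e <- b - a
    denom <- d[1] * (-e[2]) - d[2] * (-e[1])
    if (abs(denom) < 1e-12) next  # parallel
    rhs <- a - p0
    t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / denom
    s <- (d[1] * rhs[2] - d[2] * rhs[1]) / denom
    if (t >= -1e-9 && s >= -1e-9 && s <= 1 + 1e-9) ts <- c(ts, max(t, 0))
  }
  sort(ts)
}

point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; zi <- poly[i, 2]
    xj <- poly[j, 1]; zj <- poly[j, 2]
    if ((zi > p[2]) != (zj > p[2]) &&
        p[1] < (xj - xi) * (p[2] - zi) / (zj - zi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Plume pathway through a crown
#'
#' The chord of the plume axis through a crown cross-section: the potential
#' depth of foliage that the plume can ignite. The plume axis starts at the
#' flame origin and follows the flame angle; the pathway is reported as entry
#' and exit distances along the axis from the flame origin. A plume that
#' misses the crown (for example a wind-flattened plume passing under or
#' over it) has `path_length = 0`. A plume grazing the crown edge counts as
#' intersecting.
#'
#' @param flame An [ffm_flame()].
#' @param stratum An [ffm_stratum()] supplying the crown geometry.
#' @param plant_offset Horizontal offset (m) of the crown centreline from the
#'   flame origin, measured downwind.
#' @return A list of class `ffm_pathway` with `entry`, `exit` (distances
#'   along the plume axis, m) and `path_length = exit - entry` (0 on a miss).
#' @export
plume_pathway <- function(flame, stratum, plant_offset = 0) {
  poly <- crown_polygon(stratum, centre_x = plant_offset)
  p0 <- c(0, flame$origin_height)
  ts <- ray_polygon_crossings(p0, flame$angle, poly)
  if (length(ts) == 0) {
    entry <- exit <- 0
  } else if (length(ts) == 1 || point_in_polygon(p0, poly)) {
    # origin inside the crown: pathway runs from the origin to the far edge
    entry <- 0
    exit <- max(ts)
  } else {
    entry <- min(ts)
    exit <- max(ts)
  }
  structure(list(entry = entry, exit = exit,
                 path_length = max(0, exit - entry)),
            class = "ffm_pathway")
}
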