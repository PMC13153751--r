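# Task geometry: screen model, Archimedean reference spiral, target layouts,
# and the left-hand mirroring transform.

#' Screen geometry
#'
#' Physical screen footprint in millimeters, origin at the top-left corner
#' with y increasing downward. The default matches the 72.9 x 152.0 mm device
#' used for data collection.
#'
#' @param width_mm,height_mm screen extent in mm.
#' @return An object of class `screen_spec`.
#' @export
screen_spec <- function(width_mm = 72.9, height_mm = 152.0) {
  stopifnot(width_mm > 0, height_mm > 0)
  structure(list(width_mm = width_mm, height_mm = height_mm),
            class = "screen_spec")
}

#' Archimedean spiral specification
#'
#' The drag task's reference curve is an Archimedean spiral
#' r(theta) = pitch * theta / (2*pi), traced from the center outward.
#' Pitch and turn count are configuration choices; the stroke width shown to
#' the user is 4.4 mm. Chirality is as seen on screen (y pointing down):
#' `clockwise` for right-handed use, `counterclockwise` for mirrored
#' left-handed use.
#'
#' @param center_x,center_y spiral center in mm.
#' @param pitch radial growth per full turn, mm.
#' @param n_turns number of full turns (positive real).
#' @param chirality `"clockwise"` or `"counterclockwise"`.
#' @param stroke_width drawn stroke width in mm (display only).
#' @param screen a [screen_spec()]; the outermost radius must fit on screen.
#' @return An object of class `spiral_spec`.
#' @export
spiral_spec <- function(center_x = NULL, center_y = NULL, pitch = 8,
                        n_turns = 3, chirality = c("clockwise",
                                                   "counterclockwise"),
                        stroke_width = 4.4, screen = screen_spec()) {
  chirality <- match.arg(chirality)
  if (is.null(center_x)) center_x <- screen$width_mm / 2
  if (is.null(center_y)) center_y <- screen$height_mm / 2
  stopifnot(pitch > 0, n_turns > 0, stroke_width > 0)
  r_max <- pitch * n_turns
  if (center_x - r_max < 0 || center_x + r_max > screen$width_mm ||
      center_y - r_max < 0 || center_y + r_max > screen$height_mm)
    stopf("spiral radius %.1f mm does not fit inside the %.1f x %.1f mm screen",
          r_max, screen$width_mm, screen$height_mm)
  structure(list(center_x = center_x, center_y = center_y, pitch = pitch,
                 n_turns = n_turns, chirality = chirality,
                 stroke_width = stroke_width),
            class = "spiral_spec")
}

# Cartesian point(s) on the centerline at polar angle theta (radians >= 0).
# Screen coordinates have y down; "clockwise" on screen means the y component
# grows with theta.
spiral_xy <- function(spec, theta) {
  r <- spec$pitch * theta / (2 * pi)
  sgn <- if (spec$chirality == "clockwise") 1 else -1
  cbind(x = spec$center_x + r * cos(theta),
        y = spec$center_y + sgn * r * sin(theta))
}

# Closed-form arc length of r = a*theta from 0 to theta.
spiral_arclen <- function(a, theta) {
  (a / 2) * (theta * sqrt(1 + theta^2) + asinh(theta))
}

#' Point on the spiral centerline at a given arc-length fraction
#'
#' `s` parameterizes the centerline by arc length: `s = 0` is the center,
#' `s = 1` the outer end (radius `pitch * n_turns`). The angle for a given
#' arc length is found by inverting the closed-form arc-length function on a
#' dense monotone table.
#'
#' @param spec a [spiral_spec()].
#' @param s numeric vector of arc-length fractions in `[0, 1]`.
#' @return A matrix with columns `x`, `y` (mm), one row per element of `s`.
#' @export
spiral_point <- function(spec, s) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stopf("arc-position parameter s must lie in [0, 1]")
  theta_max <- 2 * pi * spec$n_turns
  a <- spec$pitch / (2 * pi)
  grid <- seq(0, theta_max, length.out = 4096)
  len <- spiral_arclen(a, grid)
  theta <- stats::approx(len / len[length(len)], grid, xout = s,
                         ties = "ordered")$y
  spiral_xy(spec, theta)
}

#' Distance from points to the spiral centerline
#'
#' Minimum Euclidean distance from each query point to the Archimedean
#' centerline, accurate to well under 0.01 mm: a dense polyline locates the
#' nearest vertex, then the squared distance is minimized over the bracketing
#' angular interval with [stats::optimize()].
#'
#' @param spec a [spiral_spec()].
#' @param x,y query point coordinates in mm (vectors of equal length).
#' @return Numeric vector of distances in mm.
#' @export
distance_to_spiral <- function(spec, x, y) {
  stopifnot(length(x) == length(y))
  theta_max <- 2 * pi * spec$n_turns
  ng <- 1536L
  grid <- seq(0, theta_max, length.out = ng)
  pts <- spiral_xy(spec, grid)
  step <- grid[2] - grid[1]
  n <- length(x)
  out <- numeric(n)
  for (start in seq(1, n, by = 2048)) {           # bound memory for huge inputs
    sel <- start:min(n, start + 2047)
    D <- outer(x[sel], pts[, 1], "-")^2 + outer(y[sel], pts[, 2], "-")^2
    j <- max.col(-D, ties.method = "first")
    jm <- pmax(j - 1L, 1L); jp <- pmin(j + 1L, ng)
    ii <- seq_along(sel)
    dm <- D[cbind(ii, jm)]; d0 <- D[cbind(ii, j)]; dp <- D[cbind(ii, jp)]
    # parabolic refinement of the squared distance around the grid minimum
    denom <- dm - 2 * d0 + dp
    off <- ifelse(denom > 0, clamp(0.5 * (dm - dp) / denom, -1, 1), 0)
    theta <- clamp(grid[j] + off * step, 0, theta_max)
    pr <- spiral_xy(spec, theta)
    dref <- (pr[, 1] - x[sel])^2 + (pr[, 2] - y[sel])^2
    out[sel] <- sqrt(pmin(dref, dm, d0, dp))
  }
  out
}

#' Random tap-target layout
#'
#' Places `n` circular targets uniformly on the screen with a margin of one
#' radius from every edge, enforcing that consecutive targets are at least
#' one diameter apart center-to-center (the task shows each new target "at a
#' different location"). Deterministic given `seed`.
#'
#' @param n number of targets (>= 1).
#' @param screen a [screen_spec()].
#' @param seed integer RNG seed.
#' @param diameter target diameter in mm (default 14.6).
#' @return A data frame with columns `x`, `y`, `diameter`.
#' @export
sample_tap_targets <- function(n, screen = screen_spec(), seed = 1,
                               diameter = 14.6) {
  stopifnot(is_count(n))
  r <- diameter / 2
  if (screen$width_mm <= 2 * r || screen$height_mm <= 2 * r)
    stopf("screen %.1f x %.1f mm too small for %.1f mm targets",
          screen$width_mm, screen$height_mm, diameter)
  local_seed(seed, {
    xs <- numeric(n); ys <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        px <- stats::runif(1, r, screen$width_mm - r)
        py <- stats::runif(1, r, screen$height_mm - r)
        if (i == 1 || sqrt((px - xs[i - 1])^2 + (py - ys[i - 1])^2) >= diameter)
          break
      }
      xs[i] <- px; ys[i] <- py
    }
    data.frame(x = xs, y = ys, diameter = diameter)
  })
}

#' Mirror an execution for left-handed use
#'
#' Reflects all horizontal coordinates about the screen's vertical midline
#' (`x` becomes `screen_width - x`) in the touch stream and sub-event
#' targets, and flips the chirality of an attached reference spiral.
#' Timestamps, sensor streams, and every other field are untouched. The
#' transform is an involution.
#'
#' @param execution a `task_execution`.
#' @param screen_width screen width in mm.
#' @return The mirrored `task_execution`.
#' @export
mirror_for_left_hand <- function(execution, screen_width = 72.9) {
  stopifnot(inherits(execution, "task_execution"))
  execution$touch$x <- screen_width - execution$touch$x
  if (nrow(execution$sub_events) > 0)
    execution$sub_events$target_x <- screen_width - execution$sub_events$target_x
  sp <- attr(execution, "spiral")
  if (!is.null(sp)) {
    sp$center_x <- screen_width - sp$center_x
    sp$chirality <- if (sp$chirality == "clockwise") "counterclockwise"
                    else "clockwise"
    attr(execution, "spiral") <- sp
  }
  execution
}
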