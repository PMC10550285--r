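#' Rectangular open-field arena
#'
#' The arena is centred on the origin, so coordinates run in
#' `[-width/2, width/2] x [-height/2, height/2]` (cm). The default 80 x 80 cm
#' arena therefore spans -40..40 cm on both axes.
#'
#' @param width,height Arena extent in cm. Must be positive.
#' @return An object of class `arena` with fields `width` and `height`.
#' @examples
#' a <- arena()
#' a$width
#' @export
arena <- function(width = 80, height = 80) {
  stopifnot(is.numeric(width), is.numeric(height), length(width) == 1,
            length(height) == 1)
  if (!(width > 0 && height > 0)) {
    stop("arena dimensions must be positive", call. = FALSE)
  }
  structure(list(width = width, height = height), class = "arena")
}

in_arena <- function(arena, xy, tol = 1e-9) {
  abs(xy[, 1]) <= arena$width / 2 + tol & abs(xy[, 2]) <= arena$height / 2 + tol
}

#' Lay out a square grid of place-field centres
#'
#' Field centres equally tile the arena on an `n_side` x `n_side` lattice.
#' Centres sit at the midpoints of an `n_side`-fold partition of each axis, so
#' the lattice is symmetric about the arena centre and the nearest-neighbour
#' spacing is `width / n_side` (1 cm for the default CA3 layer, 2 cm for DG).
#'
#' @param arena An [arena()].
#' @param n_side Number of fields along each axis (6400 CA3 cells for
#'   `n_side = 80`, 1600 DG cells for `n_side = 40`).
#' @param layer Layer tag, `"CA3"` or `"DG"`.
#' @return A `place_grid`: list with `centers` (n x 2 matrix, cm), `psi`
#'   (preferred heading directions, radians; `NA` until assigned with
#'   [assign_preferred_directions()]), `n_side`, `layer`, `arena`.
#' @seealso [assign_preferred_directions()]
#' @export
build_grid <- function(arena, n_side, layer = c("CA3", "DG")) {
  layer <- match.arg(layer)
  if (!is.numeric(n_side) || length(n_side) != 1 || n_side < 1 ||
      n_side != round(n_side)) {
    stop("`n_side` must be a positive whole number", call. = FALSE)
  }
  sx <- arena$width / n_side
  sy <- arena$height / n_side
  ax <- -arena$width / 2 + sx * (seq_len(n_side) - 0.5)
  ay <- -arena$height / 2 + sy * (seq_len(n_side) - 0.5)
  ## row-major over y within x kept fixed: cell index i = (iy-1)*n_side + ix,
  ## i.e. x varies fastest.  Lattice neighbours at +-1 (x) and +-n_side (y).
  centers <- cbind(x = rep(ax, times = n_side), y = rep(ay, each = n_side))
  structure(
    list(centers = centers, psi = rep(NA_real_, n_side^2),
         n_side = as.integer(n_side), layer = layer, arena = arena),
    class = "place_grid"
  )
}

#' @export
print.place_grid <- function(x, ...) {
  cat(sprintf("<place_grid> %s layer: %d x %d fields, spacing %.2f cm, %s\n",
              x$layer, x$n_side, x$n_side, x$arena$width / x$n_side,
              if (all(is.na(x$psi))) "no preferred directions" else
                "preferred directions assigned"))
  invisible(x)
}

#' Semi-randomised preferred heading directions
#'
#' Within every 2 x 2 tile of the grid the four preferred directions are the
#' four cardinal angles \{0, 90, 180, 270\} degrees jointly rotated by a
#' single uniform random angle drawn per tile, then wrapped to `[0, 2*pi)`.
#' Across many tiles the marginal distribution of directions is uniform while
#' each tile still covers the full circle evenly.
#'
#' @param grid A `place_grid` with even `n_side`.
#' @param seed Integer seed; the assignment is reproducible given the seed.
#' @return The grid with `psi` filled in.
#' @export
assign_preferred_directions <- function(grid, seed) {
  stopifnot(inherits(grid, "place_grid"))
  n <- grid$n_side
  if (n %% 2 != 0) {
    stop("`n_side` must be even so that 2 x 2 tiles partition the grid",
         call. = FALSE)
  }
  base <- c(0, 0.5, 1, 1.5) * pi
  psi <- withr::with_seed(seed, {
    n_tiles <- (n / 2)^2
    xi <- stats::runif(n_tiles, 0, 2 * pi)
    p <- numeric(n^2)
    tile <- 0L
    for (ty in seq_len(n / 2)) {
      for (tx in seq_len(n / 2)) {
        tile <- tile + 1L
        ix <- 2L * (tx - 1L) + c(1L, 2L, 1L, 2L)
        iy <- 2L * (ty - 1L) + c(1L, 1L, 2L, 2L)
        idx <- (iy - 1L) * n + ix
        p[idx] <- (base + xi[tile]) %% (2 * pi)
      }
    }
    p
  })
  grid$psi <- psi
  grid
}

#' Straight-line (or stationary) trajectory sampled on the integration grid
#'
#' Positions follow `p(t) = start + speed * t * (cos(direction),
#' sin(direction))` and the heading equals `direction` throughout. A zero
#' speed yields a non-moving stimulus at `start` (used for tempotron
#' training). The path must stay inside the arena.
#'
#' @param start Numeric length-2 start position (cm).
#' @param direction Heading angle in radians.
#' @param speed Running speed in cm/s.
#' @param duration Duration in ms.
#' @param dt Time step in ms.
#' @param arena The [arena()] the path must remain inside.
#' @return A `trajectory`: list with `t` (ms), `pos` (n x 2, cm), `heading`
#'   (radians), `dt`, `arena`.
#' @examples
#' tr <- make_straight_trajectory(c(-20, 0), 0, 20, 2000, 1)
#' tail(tr$pos, 1)  # ends at (20, 0)
#' @export
make_straight_trajectory <- function(start, direction, speed, duration,
                                     dt = 0.1, arena = thetanet::arena()) {
  stopifnot(length(start) == 2, speed >= 0, duration > 0, dt > 0)
  tt <- seq(0, duration, by = dt)
  pos <- cbind(start[1] + speed * (tt / 1000) * cos(direction),
               start[2] + speed * (tt / 1000) * sin(direction))
  ok <- in_arena(arena, pos)
  if (!all(ok)) {
    stop(sprintf("trajectory leaves the arena at t = %.1f ms", tt[which(!ok)[1]]),
         call. = FALSE)
  }
  structure(
    list(t = tt, pos = pos, heading = rep(direction, length(tt)),
         dt = dt, arena = arena),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf(
    "<trajectory> %.0f ms at dt = %g ms; (%.1f, %.1f) -> (%.1f, %.1f) cm\n",
    x$t[n], x$dt, x$pos[1, 1], x$pos[1, 2], x$pos[n, 1], x$pos[n, 2]))
  invisible(x)
}

## shortest signed angular difference a - b, wrapped to (-pi, pi]
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

wrap_2pi <- function(x) x %% (2 * pi)
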