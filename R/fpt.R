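# First Passage Time: the time for the animal to enter and leave a circle of
# radius r centred on each relocation.  Motion between fixes is modelled as
# piecewise-linear at constant speed per step; crossing instants are found by
# exact segment-circle intersection with linear time interpolation.  Large
# passage times mark area-restricted search; the variance of log FPT across
# relocations, S(r) = Var[log t(r)], peaks at the characteristic scale of
# that search.

#' Radius grid for scale selection
#'
#' @param r_min,r_max Grid bounds in metres (`r_min > 0`).
#' @param step Grid step in metres.
#' @return Numeric vector of radii.
#' @export
radius_grid <- function(r_min = 300, r_max = 500, step = 10) {
  if (r_min <= 0 || step <= 0 || r_max < r_min)
    stop("need 0 < r_min <= r_max and step > 0", call. = FALSE)
  seq(r_min, r_max, by = step)
}

# First time (seconds, relative to the fix) at which the piecewise-linear
# path through (tt, xx, yy), walked from vertex `start` in direction `dir`
# (+1 forward, -1 backward), crosses the circle of radius r centred on the
# start vertex.  NA if the path ends inside the circle.
.first_crossing <- function(tt, xx, yy, start, dir, r) {
  n <- length(tt)
  cx <- xx[start]; cy <- yy[start]
  j <- start
  repeat {
    k <- j + dir
    if (k < 1 || k > n) return(NA_real_)
    ax <- xx[j] - cx; ay <- yy[j] - cy
    bx <- xx[k] - cx; by <- yy[k] - cy
    if (bx * bx + by * by > r * r) {
      # crossing inside this step: solve |a + s(b-a)|^2 = r^2, s in (0, 1]
      dx <- bx - ax; dy <- by - ay
      A <- dx * dx + dy * dy
      B <- 2 * (ax * dx + ay * dy)
      C <- ax * ax + ay * ay - r * r
      disc <- B * B - 4 * A * C
      disc <- max(disc, 0)
      s <- (-B + sqrt(disc)) / (2 * A)  # exit root (start is inside)
      tcross <- tt[j] + s * (tt[k] - tt[j])
      return(abs(tcross - tt[start]))
    }
    j <- k
  }
}

#' Per-fix passage times at one radius
#'
#' For each fix, the forward component is the elapsed time until the path
#' first leaves the circle of radius `r` centred on that fix; the backward
#' component is symmetric toward the track start.  `t(r)` is their sum, in
#' minutes; it is undefined at fixes where the track starts or ends before
#' crossing (in particular the first and last fix).  Time gaps are traversed
#' linearly at the implied constant speed.
#'
#' @param track A projected, filtered [new_track()] with >= 2 fixes.
#' @param r Circle radius in metres (> 0).
#' @return A tibble of class `fpt_series`: `fix`, `forward_min`,
#'   `backward_min`, `t_min`; the radius is in the `radius` attribute.
#' @export
passage_times <- function(track, r) {
  stopifnot(inherits(track, "fpt_track"))
  if (r <= 0) stop("radius must be > 0", call. = FALSE)
  fx <- track$fixes[track$fixes$valid, ]
  if (nrow(fx) < 2) stop("track has fewer than 2 valid fixes", call. = FALSE)
  if (anyNA(fx$x)) stop("track must be projected first", call. = FALSE)
  tt <- as.numeric(fx$timestamp)
  xx <- fx$x; yy <- fx$y
  n <- length(tt)
  fwd <- bwd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fwd[i] <- .first_crossing(tt, xx, yy, i, +1L, r)
    bwd[i] <- .first_crossing(tt, xx, yy, i, -1L, r)
  }
  out <- tibble::tibble(fix = seq_len(n),
                        forward_min = fwd / 60,
                        backward_min = bwd / 60,
                        t_min = (fwd + bwd) / 60)
  attr(out, "radius") <- r
  attr(out, "track_id") <- track$id
  class(out) <- c("fpt_series", class(out))
  out
}

#' Variance-of-log-FPT scale-selection profile
#'
#' S(r) is the sample variance (denominator n-1) of the natural log of
#' `t(r)` in minutes, over fixes where `t(r)` is defined; radii with fewer
#' than two defined fixes yield `NA`.
#'
#' @param track A projected, filtered [new_track()].
#' @param radii Radii in metres, e.g. from [radius_grid()].
#' @return A tibble of class `var_log_profile`: `r`, `s`, `n_defined`.
#' @export
var_log_fpt <- function(track, radii = radius_grid()) {
  if (is.unsorted(radii, strictly = TRUE) || any(radii <= 0))
    stop("radii must be strictly increasing and positive", call. = FALSE)
  rows <- lapply(radii, function(r) {
    t_min <- passage_times(track, r)$t_min
    ok <- !is.na(t_min)
    tibble::tibble(
      r = r,
      s = if (sum(ok) >= 2) stats::var(log(t_min[ok])) else NA_real_,
      n_defined = sum(ok))
  })
  out <- do.call(rbind, rows)
  attr(out, "track_id") <- track$id
  class(out) <- c("var_log_profile", class(out))
  out
}

#' Optimal radius: the S(r) peak
#'
#' @param profile A [var_log_fpt()] profile.
#' @return The radius (m) maximizing S(r); ties break toward the smallest
#'   radius; radii with undefined S are skipped.
#' @export
optimal_radius <- function(profile) {
  ok <- !is.na(profile$s)
  if (!any(ok)) stop("S(r) is undefined at every radius", call. = FALSE)
  p <- profile[ok, ]
  p$r[which.max(p$s)]  # which.max returns the first (smallest-r) maximum
}

#' Population mean optimal radius
#'
#' The cohort-level radius used for the final FPT calculation before
#' threshold classification.
#'
#' @param r_stars Numeric vector of per-track optimal radii (m).
#' @return A list with `mean` and `sd` (sample SD; 0 for a single value).
#' @export
population_radius <- function(r_stars) {
  if (!length(r_stars)) stop("no radii supplied", call. = FALSE)
  s <- if (length(r_stars) > 1) stats::sd(r_stars) else 0
  list(mean = mean(r_stars), sd = s)
}

#' Export FPT series and profiles as tidy CSV
#'
#' @param series_list List of [passage_times()] tibbles (possibly several
#'   radii and tracks).
#' @param profiles List of [var_log_fpt()] tibbles.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fpt_csv <- function(series_list, profiles, path) {
  ser <- do.call(rbind, lapply(series_list, function(s)
    data.frame(track = attr(s, "track_id"), fix = s$fix,
               radius = attr(s, "radius"), t_min = s$t_min,
               s_r = NA_real_)))
  pro <- do.call(rbind, lapply(profiles, function(p)
    data.frame(track = attr(p, "track_id"), fix = NA_integer_,
               radius = p$r, t_min = NA_real_, s_r = p$s)))
  utils::write.csv(rbind(ser, pro), path, row.names = FALSE)
  invisible(path)
}
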