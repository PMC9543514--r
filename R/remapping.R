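#' L1DL2 remapping angle
#'
#' The angle (degrees) at the dark-session place-field centre between the
#' vectors pointing to the two light-session centres:
#' \eqn{\cos^{-1}\left(\frac{\vec{DL_1}\cdot\vec{DL_2}}
#' {\lVert \vec{DL_1}\rVert\,\lVert \vec{DL_2}\rVert}\right)}.
#' A large angle means the dark field sits between two similar light fields
#' (little remapping); a smaller, consistent angle indicates a systematic
#' shift in darkness. The cosine is clamped to `[-1, 1]` before the arccos so
#' exactly collinear configurations do not produce NaN. Symmetric in
#' `com_l1` and `com_l2`.
#'
#' @param com_l1,com_d,com_l2 Field centres `c(x, y)` in cm for the first
#'   light, dark, and second light sessions.
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' l1dl2_angle(c(0, 0), c(10, 0), c(20, 0))  # collinear, D between: 180
#' l1dl2_angle(c(0, 0), c(10, 0), c(10, 10)) # perpendicular: 90
#' @export
l1dl2_angle <- function(com_l1, com_d, com_l2) {
  v1 <- as.numeric(com_l1) - as.numeric(com_d)
  v2 <- as.numeric(com_l2) - as.numeric(com_d)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    abort("Angle undefined: dark centre coincides with a light centre.",
          class = "placeremap_no_remap")
  }
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Euclidean distance between two place-field centres
#'
#' \eqn{\sqrt{(y_b-y_a)^2 + (x_b-x_a)^2}} in cm.
#'
#' @param a,b Points `c(x, y)` in cm.
#' @return Distance in cm.
#' @export
com_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 2L, length(b) == 2L, all(is.finite(c(a, b))))
  sqrt((b[2] - a[2])^2 + (b[1] - a[1])^2)
}

#' Summarise remapping across a cohort of units
#'
#' Takes tidy centre-of-mass data (one row per unit and session) and returns
#' per-unit L1DL2 angles and pairwise centre distances, plus cohort
#' aggregates (mean and SEM). Units lacking a field centre in any of the
#' three sessions are excluded and reported with a reason, mirroring the
#' per-cell angle's requirement that all three fields exist. Units whose dark
#' centre coincides with a light centre get `NA` angle with note
#' `"no_remap"` (the angle is undefined there), but keep their distances.
#'
#' @param coms A data frame with columns `unit_id`, `session` (values
#'   `"L1"`, `"D"`, `"L2"`), `x`, `y`.
#' @return A `remap_summary` object; `tidy()` gives the per-unit table,
#'   `glance()` the aggregates.
#' @examples
#' coms <- tibble::tibble(
#'   unit_id = rep("u1", 3), session = c("L1", "D", "L2"),
#'   x = c(20, 30, 20), y = c(20, 28, 21))
#' glance(remap_summary(coms))
#' @export
remap_summary <- function(coms) {
  coms <- as_tibble(coms)
  stopifnot(all(c("unit_id", "session", "x", "y") %in% names(coms)))
  if (!nrow(coms)) abort("No centre-of-mass rows supplied.")
  wide <- tidyr::pivot_wider(coms, id_cols = "unit_id",
                             names_from = "session",
                             values_from = c("x", "y"))
  needed <- c("x_L1", "y_L1", "x_D", "y_D", "x_L2", "y_L2")
  for (col in setdiff(needed, names(wide))) wide[[col]] <- NA_real_
  complete <- stats::complete.cases(wide[needed])
  excluded <- tibble(unit_id = wide$unit_id[!complete],
                     reason = "missing field in >= 1 session")
  wide <- wide[complete, ]
  units <- purrr::pmap_dfr(wide, function(unit_id, x_L1, y_L1, x_D, y_D,
                                          x_L2, y_L2, ...) {
    l1 <- c(x_L1, y_L1); d <- c(x_D, y_D); l2 <- c(x_L2, y_L2)
    ang <- tryCatch(l1dl2_angle(l1, d, l2),
                    placeremap_no_remap = function(e) NA_real_)
    tibble(unit_id = unit_id,
           angle_deg = ang,
           d_l1d_cm = com_distance(l1, d),
           d_l1l2_cm = com_distance(l1, l2),
           d_dl2_cm = com_distance(d, l2),
           note = if (is.na(ang)) "no_remap" else "")
  })
  structure(list(units = units, excluded = excluded), class = "remap_summary")
}

mean_sem <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  tibble(n = n,
         mean = if (n) mean(x) else NA_real_,
         sem = if (n > 1) sd(x) / sqrt(n) else NA_real_)
}

#' @export
tidy.remap_summary <- function(x, ...) x$units

#' @export
glance.remap_summary <- function(x, ...) {
  u <- x$units
  ang <- mean_sem(u$angle_deg)
  d1 <- mean_sem(u$d_l1d_cm)
  d2 <- mean_sem(u$d_l1l2_cm)
  d3 <- mean_sem(u$d_dl2_cm)
  tibble(n_units = nrow(u), n_excluded = nrow(x$excluded),
         n_angle = ang$n,
         angle_mean_deg = ang$mean, angle_sem_deg = ang$sem,
         d_l1d_mean_cm = d1$mean, d_l1d_sem_cm = d1$sem,
         d_l1l2_mean_cm = d2$mean, d_l1l2_sem_cm = d2$sem,
         d_dl2_mean_cm = d3$mean, d_dl2_sem_cm = d3$sem)
}

#' @export
autoplot.remap_summary <- function(object, ...) {
  u <- object$units
  ggplot2::ggplot(u, ggplot2::aes(.data$angle_deg)) +
    ggplot2::geom_histogram(binwidth = 15, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "L1DL2 angle (degrees)", y = "units")
}

#' @export
print.remap_summary <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0("<remap_summary> %d units (%d excluded): angle %.1f ",
                     "+/- %.1f deg, dL1D %.1f cm\n"),
              g$n_units, g$n_excluded, g$angle_mean_deg, g$angle_sem_deg,
              g$d_l1d_mean_cm))
  invisible(x)
}
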