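#' Worm-like-chain contours and persistence-length estimation
#'
#' Synthetic contour generation plus the tangent-angle-correlation fit used
#' to estimate persistence lengths from traced chain contours (as applied to
#' AFM traces of silicified bundles).  The 2D convention,
#' `<cos theta(s)> = exp(-s / (2 L_p))`, is the default because surface-
#' adsorbed, equilibrated chains are two-dimensional; the 3D convention
#' drops the factor 2.
#'
#' @name wlc
NULL

#' Generate a discrete worm-like-chain contour
#'
#' 2D: successive tangent angles perform a Gaussian walk with per-step
#' variance `step / L_p`.  3D: the tangent vector receives isotropic
#' Gaussian transverse kicks of variance `step / L_p` per axis and is
#' renormalised, giving `<cos theta(s)> = exp(-s/L_p)` for `step << L_p`.
#'
#' @param L_p persistence length (nm); `Inf` gives a straight line.
#' @param contour_length total arc length (nm).
#' @param step arc-length discretisation (nm), `step << L_p`.
#' @param seed integer seed.
#' @param convention `"2D"` or `"3D"`.
#' @return a `wlc_contour`: matrix of points (nm) with attributes `step`
#'   and `convention`.
#' @export
generate_wlc <- function(L_p, contour_length, step, seed = 1L,
                         convention = c("2D", "3D")) {
  convention <- match.arg(convention)
  stopifnot(L_p > 0, contour_length > 0, step > 0, step < contour_length)
  set.seed(seed)
  n_seg <- round(contour_length / step)
  if (convention == "2D") {
    sd_ang <- if (is.finite(L_p)) sqrt(step / L_p) else 0
    ang <- cumsum(c(0, stats::rnorm(n_seg - 1, 0, sd_ang)))
    pts <- cbind(c(0, cumsum(step * cos(ang))),
                 c(0, cumsum(step * sin(ang))))
  } else {
    sd_kick <- if (is.finite(L_p)) sqrt(step / L_p) else 0
    t_vec <- c(1, 0, 0)
    tangents <- matrix(0, n_seg, 3)
    tangents[1, ] <- t_vec
    for (i in seq_len(n_seg - 1)) {
      # transverse Gaussian kick, then renormalise
      k <- stats::rnorm(3, 0, sd_kick)
      k <- k - sum(k * t_vec) * t_vec
      t_vec <- t_vec + k
      t_vec <- t_vec / sqrt(sum(t_vec^2))
      tangents[i + 1, ] <- t_vec
    }
    pts <- rbind(0, apply(tangents * step, 2, cumsum))
  }
  structure(pts, step = step, convention = convention, class = "wlc_contour")
}

#' Resample a traced contour to equal arc-length spacing
#'
#' Linear interpolation along the cumulative arc length; traced contours
#' have uneven spacing, and the correlation fit assumes a constant step.
#'
#' @param points matrix of contour points (2 or 3 columns, nm).
#' @param step target spacing (nm).
#' @return a `wlc_contour` with constant spacing.
#' @export
resample_contour <- function(points, step) {
  points <- as.matrix(points)
  d <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(d))
  s_new <- seq(0, s[length(s)], by = step)
  out <- vapply(seq_len(ncol(points)),
                function(k) stats::approx(s, points[, k], xout = s_new)$y,
                numeric(length(s_new)))
  structure(out, step = step, convention = if (ncol(points) == 2) "2D" else "3D",
            class = "wlc_contour")
}

contour_cos_by_sep <- function(points, max_sep) {
  segs <- diff(as.matrix(points))
  lens <- sqrt(rowSums(segs^2))
  t_hat <- segs / lens
  n <- nrow(t_hat)
  vapply(seq_len(max_sep), function(k) {
    idx <- seq_len(n - k)
    mean(rowSums(t_hat[idx, , drop = FALSE] * t_hat[idx + k, , drop = FALSE]))
  }, numeric(1))
}

#' Estimate persistence length from contours
#'
#' Pools the tangent-tangent correlation `<cos theta(s)>` over all contours
#' for separations up to half the (shortest) contour length and fits
#' `log <cos theta(s)>` against `s` by least squares through the origin;
#' the slope is `-1/(2 L_p)` (2D) or `-1/L_p` (3D).  The standard error is
#' a bootstrap over contours.
#'
#' @param contours a `wlc_contour` or list of them (equal step assumed;
#'   uneven traces should pass through [resample_contour()] first).
#' @param convention `"2D"` or `"3D"`; defaults to the contours' attribute.
#' @param max_fraction largest separation as a fraction of contour length.
#' @param n_boot bootstrap replicates.
#' @param seed seed for the bootstrap resampling.
#' @param lp_sentinel value reported for an effectively straight input
#'   (non-negative fitted slope).
#' @return a `wlc_fit`: `persistence_length_nm`, `se_nm`, `convention`,
#'   `n_contours`, and the pooled correlation table.
#' @export
estimate_lp <- function(contours, convention = NULL, max_fraction = 0.5,
                        n_boot = 200L, seed = 1L, lp_sentinel = 1e6) {
  if (inherits(contours, "wlc_contour")) contours <- list(contours)
  stopifnot(length(contours) >= 1)
  step <- attr(contours[[1]], "step")
  if (is.null(convention)) convention <- attr(contours[[1]], "convention")
  fac <- if (convention == "2D") 2 else 1
  n_min <- min(vapply(contours, nrow, integer(1))) - 1L
  max_sep <- floor(n_min * max_fraction)
  if (max_sep < 3) stop("fit error: fewer than 3 usable separations")
  cmat <- t(vapply(contours, contour_cos_by_sep, numeric(max_sep),
                   max_sep = max_sep))
  if (length(contours) == 1L) cmat <- matrix(cmat, nrow = 1)
  s <- step * seq_len(max_sep)

  fit_one <- function(rows) {
    cbar <- colMeans(cmat[rows, , drop = FALSE])
    use <- cbar > 0
    if (sum(use) < 3) return(NA_real_)
    slope <- sum(s[use] * log(cbar[use])) / sum(s[use]^2)
    if (slope >= -1 / (fac * lp_sentinel)) lp_sentinel else -1 / (fac * slope)
  }
  lp_hat <- fit_one(seq_along(contours))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    fit_one(sample(seq_along(contours), replace = TRUE))
  }, numeric(1))
  se <- stats::sd(boots, na.rm = TRUE)
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(persistence_length_nm = lp_hat, se_nm = se,
                 ci_nm = ci, convention = convention,
                 n_contours = length(contours),
                 correlation = data.frame(s_nm = s, mean_cos = colMeans(cmat))),
            class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf("<wlc_fit> L_p = %.1f +/- %.1f nm (%s convention, %d contours)\n",
              x$persistence_length_nm, x$se_nm, x$convention, x$n_contours))
  invisible(x)
}

#' Write / read contours as CSV (one file per chain)
#'
#' @param contour a `wlc_contour` (or plain point matrix).
#' @param path CSV path; columns `x_nm`, `y_nm` (and `z_nm` for 3D).
#' @return the path (write) or a `wlc_contour` (read; resample before
#'   fitting if the trace spacing is uneven).
#' @export
write_contour_csv <- function(contour, path) {
  m <- as.matrix(contour)
  colnames(m) <- c("x_nm", "y_nm", "z_nm")[seq_len(ncol(m))]
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path))
  d <- sqrt(rowSums(diff(m)^2))
  structure(unname(m), step = stats::median(d),
            convention = if (ncol(m) == 2) "2D" else "3D",
            class = "wlc_contour")
}

#' Extract brush chains from a trajectory as 3D contours
#'
#' One contour per (chain, frame): the anchor core bead followed by the
#' chain beads, usable with [estimate_lp()] under the 3D convention after
#' [resample_contour()].
#'
#' @param traj a `cg_trajectory` of a brush system.
#' @param frames frame indices (default: analysis window).
#' @param resample_step resampling arc step (nm); NULL to skip resampling.
#' @return list of `wlc_contour`s.
#' @export
brush_contours <- function(traj, frames = NULL, resample_step = 1.0) {
  topo <- traj$topology
  if (is.null(topo$grafts)) stop("topology has no grafted chains")
  if (is.null(frames)) frames <- analysis_window(traj)
  chains <- split(topo$beads$bead_id[topo$beads$chain_id > 0],
                  topo$beads$chain_id[topo$beads$chain_id > 0])
  out <- list()
  for (f in frames) {
    pos <- frame_positions(traj, f)
    for (ch in chains) {
      pts <- pos[ch, , drop = FALSE]
      out[[length(out) + 1]] <- if (is.null(resample_step))
        structure(pts, step = NA_real_, convention = "3D",
                  class = "wlc_contour")
      else resample_contour(pts, resample_step)
    }
  }
  out
}
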