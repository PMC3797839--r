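#' Default analysis thresholds
#'
#' The complete set of thresholds driving segmentation, classification and
#' drug-stage labeling. The shipped defaults are the published operating
#' point of the method, so classification can run without refitting:
#' 4.7 mm spatial spread (movement vs lingering, about one body length),
#' 12 degrees body-orientation angular spread (rotation vs fixed), 13 degrees
#' velocity-direction angular spread (curved vs straight), 10 mm
#' distance-from-wall central-zone boundary, and the circling-stage criteria
#' `p_rot > 0.85` or a rotational episode exceeding 360 degrees. All are
#' re-derivable from data with [derive_threshold()] /
#' [partition_arena_zones()].
#'
#' Arrests of a smoothed real-valued signal are never exactly zero, so
#' arrests are defined by tolerance bands: `eps_v` (speed) and `eps_omega`
#' (angular velocities). The defaults sit about three standard deviations
#' above the noise floor of the corresponding derivative estimators under
#' typical tracking noise (0.2 mm position, 3 degree axis-angle at 25 Hz
#' with the default smoothing), so arrests are detected promptly without
#' being faked by noise. Threshold comparisons are strict: a spread equal
#' to the threshold does not count as above it.
#'
#' @param d_ling mm; spatial-spread threshold separating movement segments
#'   from lingering.
#' @param theta_ling deg; body-orientation angular-spread threshold
#'   separating rotation from fixed orientation.
#' @param psi_str deg; velocity-direction angular-spread threshold separating
#'   curved from straight paths.
#' @param central_boundary mm distance-from-wall bounding the central zone.
#' @param wall_boundary mm distance-from-wall below which frames are wall
#'   contact.
#' @param eps_v mm/s arrest tolerance on speed.
#' @param eps_omega deg/s arrest tolerance on angular velocities.
#' @param p_rot_circ unitless in (0,1); rotational-mode time-share criterion
#'   for the circling stage.
#' @param theta_circ deg; cumulative single-episode rotation criterion for
#'   the circling stage.
#' @return an object of class `threshold_set`.
#' @export
threshold_set <- function(d_ling = 4.7, theta_ling = 12, psi_str = 13,
                          central_boundary = 10, wall_boundary = 3,
                          eps_v = 2, eps_omega = 10,
                          p_rot_circ = 0.85, theta_circ = 360) {
  vals <- c(d_ling, theta_ling, psi_str, central_boundary, wall_boundary,
            eps_v, eps_omega, p_rot_circ, theta_circ)
  stopifnot(all(vals > 0), p_rot_circ < 1)
  structure(list(d_ling = d_ling, theta_ling = theta_ling,
                 psi_str = psi_str, central_boundary = central_boundary,
                 wall_boundary = wall_boundary, eps_v = eps_v,
                 eps_omega = eps_omega, p_rot_circ = p_rot_circ,
                 theta_circ = theta_circ),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Segmentation thresholds:\n",
      sprintf("  movement vs lingering (D_ling):      %g mm\n", x$d_ling),
      sprintf("  rotation vs fixed (Theta_ling):      %g deg\n", x$theta_ling),
      sprintf("  curved vs straight (Psi_str):        %g deg\n", x$psi_str),
      sprintf("  central-zone boundary:               %g mm from wall\n",
              x$central_boundary),
      sprintf("  wall boundary:                       %g mm from wall\n",
              x$wall_boundary),
      sprintf("  arrest tolerances: %g mm/s (speed), %g deg/s (angular)\n",
              x$eps_v, x$eps_omega),
      sprintf("  circling stage: p_rot > %g or episode > %g deg\n",
              x$p_rot_circ, x$theta_circ), sep = "")
  invisible(x)
}

#' Write / read a threshold set as YAML
#' @param thr a [threshold_set()].
#' @param path file path.
#' @return `read_threshold_yaml` returns a [threshold_set()].
#' @export
write_threshold_yaml <- function(thr, path) {
  yaml::write_yaml(unclass(thr), path)
  invisible(path)
}

#' @rdname write_threshold_yaml
#' @export
read_threshold_yaml <- function(path) {
  do.call(threshold_set, yaml::read_yaml(path))
}

#' Extract inter-arrest segments of a signal
#'
#' An arrest is a maximal run of frames with `|signal| <= eps`; inter-arrest
#' segments are the maximal runs strictly between two arrests. Leading and
#' trailing runs not bounded by arrests on both sides are flagged
#' `bounded = FALSE` and are excluded from threshold fitting (but can still
#' be classified).
#'
#' @param signal numeric series (`NA` treated as arrest-breaking gaps).
#' @param eps arrest tolerance, same units as `signal`.
#' @param include_partial keep unbounded leading/trailing segments.
#' @return data.frame with 1-based inclusive `start`, `end`, `length`,
#'   `bounded` columns, in temporal order.
#' @export
extract_inter_arrest_segments <- function(signal, eps,
                                          include_partial = FALSE) {
  above <- !is.na(signal) & abs(signal) > eps
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), bounded = logical()))
  arrest_before <- keep > 1L & !vapply(keep, function(i)
    i > 1L && is.na(signal[starts[i] - 1L]), logical(1))
  arrest_after <- keep < length(r$values) & !vapply(keep, function(i)
    i < length(r$values) && is.na(signal[ends[i] + 1L]), logical(1))
  out <- data.frame(start = starts[keep], end = ends[keep],
                    length = r$lengths[keep],
                    bounded = arrest_before & arrest_after)
  if (!include_partial) out <- out[out$bounded, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spatial spread of a point set
#'
#' The maximal Euclidean distance between any two points (the diameter of
#' the set). Computed exactly via the convex hull. A single point has
#' spread 0.
#'
#' @param x,y coordinates, mm.
#' @return maximal pairwise distance, mm.
#' @export
spatial_spread <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 1L, length(y) == n)
  if (n == 1L) return(0)
  pts <- unique(cbind(x, y))
  if (nrow(pts) == 1L) return(0)
  if (nrow(pts) > 3L) {
    h <- grDevices::chull(pts[, 1L], pts[, 2L])
    pts <- pts[h, , drop = FALSE]
  }
  d <- stats::dist(pts)
  max(d)
}

#' Angular spread of an unwrapped angle series
#'
#' `max - min` of the series, which must already be unwrapped (see
#' [unwrap_angle()]); multi-turn rotations therefore yield spreads above
#' 360 degrees.
#'
#' @param angles unwrapped angle series, degrees.
#' @return spread, degrees.
#' @export
angular_spread <- function(angles) {
  stopifnot(length(angles) >= 1L)
  max(angles) - min(angles)
}

#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Expectation-maximization for a `k`-component univariate Gaussian mixture,
#' run to a log-likelihood tolerance of `tol` (at most `max_iter`
#' iterations), taking the best of `n_restarts` quantile-spread
#' initializations. Deterministic given `seed`. Restarts in which a
#' component's standard deviation collapses below `1e-6` of the data range
#' are discarded; if all restarts degenerate, an error is raised.
#'
#' @param values numeric observations; requires `length(values) >= 10 * k`.
#' @param k number of components (2 or 3).
#' @param seed integer RNG seed for the restart initializations.
#' @param n_restarts number of EM restarts.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @return an object of class `gaussian_mixture_fit` with `weights`,
#'   `means`, `sds` (components sorted by ascending mean), `loglik`, `bic`,
#'   `converged`, `k`, `n`, `seed`.
#' @export
fit_gaussian_mixture <- function(values, k = 2, seed = 1, n_restarts = 10,
                                 tol = 1e-8, max_iter = 500) {
  stopifnot(k %in% c(2, 3))
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 10 * k)
    stop(sprintf("need at least %d observations for k = %d", 10L * k, k))
  rng <- range(x)
  sd_floor <- 1e-6 * max(diff(rng), .Machine$double.eps)
  set.seed(seed)
  inits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    probs <- if (r == 1L) (2 * seq_len(k) - 1) / (2 * k)
             else sort(stats::runif(k))
    inits[[r]] <- list(
      means = as.numeric(stats::quantile(x, probs)),
      sds = rep(max(stats::sd(x) / k, sd_floor), k),
      weights = rep(1 / k, k))
  }
  best <- NULL
  for (init in inits) {
    fit <- em_1d(x, init, tol, max_iter, sd_floor)
    if (is.null(fit)) next  # degenerate restart
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("all EM restarts degenerated (component sd collapsed)")
  o <- order(best$means)
  npar <- 3 * k - 1
  structure(list(k = k, weights = best$weights[o], means = best$means[o],
                 sds = best$sds[o], loglik = best$loglik,
                 bic = -2 * best$loglik + npar * log(n),
                 converged = best$converged, n = n, seed = seed),
            class = "gaussian_mixture_fit")
}

em_1d <- function(x, init, tol, max_iter, sd_floor) {
  n <- length(x)
  k <- length(init$means)
  mu <- init$means; sg <- init$sds; w <- init$weights
  ll_old <- -Inf; converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sg[j]),
                   numeric(n))
    tot <- rowSums(dens)
    if (any(tot <= 0 | !is.finite(tot))) return(NULL)
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk < .Machine$double.eps)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    if (any(sg < sd_floor)) return(NULL)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(means = mu, sds = sg, weights = w, loglik = ll, converged = converged)
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat(sprintf("%d-component Gaussian mixture (n = %d, loglik = %.3f%s)\n",
              x$k, x$n, x$loglik,
              if (x$converged) "" else ", NOT converged"))
  for (j in seq_len(x$k))
    cat(sprintf("  w = %.3f, mean = %.4g, sd = %.4g\n",
                x$weights[j], x$means[j], x$sds[j]))
  invisible(x)
}

#' Intersection point of two weighted Gaussian components
#'
#' The segmentation threshold of the method: the x-value at which the two
#' weighted component densities `w_i N(x; mu_i, sd_i)` and
#' `w_j N(x; mu_j, sd_j)` intersect, i.e. the root of a quadratic (after
#' taking logs) lying strictly between the two component means. The
#' equal-variance case reduces to a linear equation. If no root lies between
#' the means, an error reporting both roots is raised unless
#' `fallback = TRUE`, in which case the argmin of the summed weighted
#' density on a 10,000-point grid between the means is returned (robust
#' under heavy overlap).
#'
#' @param fit a [fit_gaussian_mixture()] result.
#' @param pair indices of the two components (after mean-sorting).
#' @param fallback use the density-minimum grid scan when the quadratic has
#'   no root between the means.
#' @return the threshold value.
#' @export
mixture_intersection <- function(fit, pair = c(1, 2), fallback = FALSE) {
  stopifnot(length(pair) == 2, all(pair %in% seq_len(fit$k)),
            pair[1] != pair[2])
  i <- pair[1]; j <- pair[2]
  m1 <- fit$means[i]; m2 <- fit$means[j]
  s1 <- fit$sds[i]; s2 <- fit$sds[j]
  w1 <- fit$weights[i]; w2 <- fit$weights[j]
  if (isTRUE(all.equal(c(m1, s1, w1), c(m2, s2, w2))))
    stop("components are identical: no unique intersection")
  if (m1 == m2) stop("component means coincide: no threshold between them")
  lo <- min(m1, m2); hi <- max(m1, m2)
  # log w1 - log s1 - (x-m1)^2/(2 s1^2) = log w2 - log s2 - (x-m2)^2/(2 s2^2)
  if (abs(s1 - s2) < 1e-12 * max(s1, s2)) {
    x <- (m1 + m2) / 2 + s1^2 * log(w1 / w2) / (m2 - m1)
    roots <- x
  } else {
    a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
    b <- m1 / s1^2 - m2 / s2^2
    cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(w1 / w2) +
      log(s2 / s1)
    disc <- b^2 - 4 * a * cc
    if (disc < 0) roots <- numeric(0)
    else roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > lo & roots < hi]
  if (length(inside) == 1L) return(inside)
  if (length(inside) > 1L) return(inside[which.min(abs(inside - (lo + hi) / 2))])
  if (fallback) {
    grid <- seq(lo, hi, length.out = 10000L)
    dens <- w1 * stats::dnorm(grid, m1, s1) + w2 * stats::dnorm(grid, m2, s2)
    return(grid[which.min(dens)])
  }
  stop(sprintf(
    "no intersection between component means (%.4g, %.4g); roots: %s",
    lo, hi,
    if (length(roots)) paste(signif(roots, 6), collapse = ", ") else "none"))
}

#' Derive a segmentation threshold from per-fly spread distributions
#'
#' For each fly, fits a Gaussian mixture to its spread values and computes
#' the intersection point between mixture components; the per-fly
#' intersections are then averaged (unweighted) across flies. For
#' body-rotation spreads the left (noise/body-wobble) peak is sometimes
#' better described by two Gaussians; with `k_policy = "bic"` the component
#' count (2 vs 3) is chosen per fly by BIC and the intersection between the
#' two *rightmost* components is used, so the threshold always separates
#' pronounced rotations from the wobble peak(s).
#'
#' @param per_fly_values list of numeric vectors, one per fly.
#' @param k components per fly when `k_policy = "fixed"`.
#' @param k_policy `"fixed"` or `"bic"` (choose 2 vs 3 per fly by BIC).
#' @param pair component pair for the intersection; default the two
#'   rightmost components of the selected fit.
#' @param seed integer; per-fly fits use `seed + fly index`.
#' @param ... passed to [fit_gaussian_mixture()].
#' @return list with `threshold` (averaged), `per_fly` (data.frame of
#'   per-fly k and intersections) and `fits` (list of mixture fits).
#'   Errors if more than half of the flies fail to fit.
#' @export
derive_threshold <- function(per_fly_values, k = 2,
                             k_policy = c("fixed", "bic"), pair = NULL,
                             seed = 1, ...) {
  k_policy <- match.arg(k_policy)
  stopifnot(length(per_fly_values) >= 1L)
  fits <- vector("list", length(per_fly_values))
  cuts <- rep(NA_real_, length(per_fly_values))
  ks <- rep(NA_integer_, length(per_fly_values))
  for (f in seq_along(per_fly_values)) {
    res <- tryCatch({
      fit <- if (k_policy == "bic") {
        f2 <- fit_gaussian_mixture(per_fly_values[[f]], 2, seed + f, ...)
        f3 <- fit_gaussian_mixture(per_fly_values[[f]], 3, seed + f, ...)
        if (f3$bic < f2$bic) f3 else f2
      } else fit_gaussian_mixture(per_fly_values[[f]], k, seed + f, ...)
      p <- if (is.null(pair)) c(fit$k - 1L, fit$k) else pair
      list(fit = fit, cut = mixture_intersection(fit, p, fallback = TRUE))
    }, error = function(e) e)
    if (inherits(res, "error")) next
    fits[[f]] <- res$fit
    cuts[f] <- res$cut
    ks[f] <- res$fit$k
  }
  ok <- !is.na(cuts)
  if (sum(ok) < length(cuts) / 2)
    stop("mixture fitting failed for more than half of the flies")
  list(threshold = mean(cuts[ok]),
       per_fly = data.frame(fly = seq_along(cuts), k = ks,
                            intersection = cuts),
       fits = fits)
}

#' Fit a complete threshold set from per-fly kinematic series
#'
#' Re-derives the data-intrinsic segmentation thresholds from tracked
#' sessions, one kinematic series per fly: the spatial-spread threshold
#' (movement vs lingering) from speed inter-arrest segments, the
#' body-orientation angular-spread threshold (rotation vs fixed) from body
#' angular-velocity segments (per-fly 2-vs-3-component choice by BIC, two
#' rightmost components), the path-direction angular-spread threshold
#' (curved vs straight) from velocity-direction angular-velocity segments
#' within central-zone progression segments, and the arena-zone boundaries
#' from pooled distances-from-wall of progression-segment frames. Arrest
#' tolerances and stage criteria are carried over from `init`.
#'
#' A threshold whose spread distribution cannot support a mixture fit (too
#' few segments, or no distinct regimes) falls back to its `init` value
#' with a warning rather than failing the whole set.
#'
#' @param kins list of [compute_kinematics()] results, one per fly.
#' @param arena an [arena_geometry()].
#' @param init a [threshold_set()] supplying tolerances and stage criteria.
#' @param seed integer seed for the EM restarts.
#' @param fit_zones also re-derive the arena-zone boundaries (needs
#'   sessions that actually visit all three zones).
#' @return list with `thresholds` (a [threshold_set()]), `fits` (per-fly
#'   mixture fits per threshold) and `zones` (a `zone_partition`, or `NULL`).
#' @export
fit_threshold_set <- function(kins, arena, init = threshold_set(),
                              seed = 1, fit_zones = TRUE) {
  stopifnot(length(kins) >= 1L)
  per_fly <- function(kin, what) {
    vals <- numeric(0)
    for (s in unique(stats::na.omit(kin$segment_id[kin$valid]))) {
      idx <- which(kin$valid & !is.na(kin$segment_id) & kin$segment_id == s)
      if (what == "spatial") {
        segs <- extract_inter_arrest_segments(kin$v_c[idx], init$eps_v)
        for (r in seq_len(nrow(segs))) {
          sub <- idx[segs$start[r]:segs$end[r]]
          vals <- c(vals, spatial_spread(kin$x_s[sub], kin$y_s[sub]))
        }
      } else if (what == "rotation") {
        segs <- extract_inter_arrest_segments(kin$omega_b[idx],
                                              init$eps_omega)
        for (r in seq_len(nrow(segs))) {
          sub <- idx[segs$start[r]:segs$end[r]]
          vals <- c(vals, angular_spread(kin$alpha_b_s[sub]))
        }
      } else { # path direction, within central-zone progression segments
        vseg <- extract_inter_arrest_segments(kin$v_c[idx], init$eps_v)
        for (r in seq_len(nrow(vseg))) {
          sub <- idx[vseg$start[r]:vseg$end[r]]
          if (spatial_spread(kin$x_s[sub], kin$y_s[sub]) <= init$d_ling)
            next
          d <- distance_from_wall(kin$x_s[sub], kin$y_s[sub], arena)
          if (stats::median(d) < init$central_boundary) next
          cseg <- extract_inter_arrest_segments(kin$omega_v[sub],
                                                init$eps_omega)
          for (q in seq_len(nrow(cseg))) {
            av <- kin$alpha_v[sub[cseg$start[q]:cseg$end[q]]]
            av <- av[!is.na(av)]
            if (length(av)) vals <- c(vals, angular_spread(av))
          }
        }
      }
    }
    vals
  }
  try_derive <- function(what, fallback, ...) {
    tryCatch(derive_threshold(lapply(kins, per_fly, what), ...),
             error = function(e) {
               warning(sprintf(
                 "%s threshold could not be fitted (%s); keeping %g",
                 what, conditionMessage(e), fallback), call. = FALSE)
               list(threshold = fallback, per_fly = NULL, fits = NULL)
             })
  }
  spatial <- try_derive("spatial", init$d_ling, k = 2, seed = seed)
  rot <- try_derive("rotation", init$theta_ling, k_policy = "bic",
                    seed = seed + 1000L)
  path <- try_derive("path", init$psi_str, k = 2, seed = seed + 2000L)
  dpool <- unlist(lapply(kins, function(kin) {
    out <- numeric(0)
    for (s in unique(stats::na.omit(kin$segment_id[kin$valid]))) {
      idx <- which(kin$valid & !is.na(kin$segment_id) & kin$segment_id == s)
      vseg <- extract_inter_arrest_segments(kin$v_c[idx], init$eps_v,
                                            include_partial = TRUE)
      for (r in seq_len(nrow(vseg))) {
        sub <- idx[vseg$start[r]:vseg$end[r]]
        if (spatial_spread(kin$x_s[sub], kin$y_s[sub]) > init$d_ling)
          out <- c(out, distance_from_wall(kin$x_s[sub], kin$y_s[sub],
                                           arena))
      }
    }
    out
  }))
  zones <- if (fit_zones) partition_arena_zones(dpool, seed = seed + 3000L)
           else NULL
  thr <- threshold_set(
    d_ling = spatial$threshold, theta_ling = rot$threshold,
    psi_str = path$threshold,
    central_boundary = if (is.null(zones)) init$central_boundary
                       else unname(zones$boundaries["central"]),
    wall_boundary = if (is.null(zones)) init$wall_boundary
                    else unname(zones$boundaries["wall"]),
    eps_v = init$eps_v, eps_omega = init$eps_omega,
    p_rot_circ = init$p_rot_circ, theta_circ = init$theta_circ)
  list(thresholds = thr,
       fits = list(spatial = spatial, rotation = rot, path = path),
       zones = zones)
}

#' Partition the arena into wall, near-wall and central zones
#'
#' Fits a 3-component Gaussian mixture to distances-from-wall of
#' progression-segment frames pooled across flies. The intersection between
#' the leftmost and middle components bounds the wall zone; the intersection
#' between the middle and rightmost components bounds the central zone.
#' Behavior in the central zone, away from walls, is the part most likely to
#' reflect endogenous constraints rather than the arena boundary.
#'
#' @param distances_from_wall pooled `d_i` values, mm (see
#'   [distance_from_wall()]).
#' @param seed RNG seed for the EM restarts.
#' @param ... passed to [fit_gaussian_mixture()].
#' @return object of class `zone_partition`: `boundaries` (wall, central; mm
#'   ascending), `labels`, and the underlying `fit`.
#' @export
partition_arena_zones <- function(distances_from_wall, seed = 1, ...) {
  fit <- fit_gaussian_mixture(distances_from_wall, k = 3, seed = seed, ...)
  gaps <- diff(fit$means)
  if (gaps[1] < max(fit$sds[1:2]) || gaps[2] < max(fit$sds[2:3]))
    stop("zone components are not separated (occupancy may not cover ",
         "three zones); no boundary is reported")
  wall <- mixture_intersection(fit, c(1, 2), fallback = TRUE)
  central <- mixture_intersection(fit, c(2, 3), fallback = TRUE)
  structure(list(boundaries = c(wall = wall, central = central),
                 labels = c("wall", "near_wall", "central"), fit = fit),
            class = "zone_partition")
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf(
    "Arena zones (distance from wall): wall < %.3g mm <= near-wall < %.3g mm <= central\n",
    x$boundaries["wall"], x$boundaries["central"]))
  invisible(x)
}
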