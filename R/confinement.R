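#' Slit confinement geometry
#'
#' An idealized rectangular slit: two parallel walls a distance `width` apart,
#' with the slit long axis along x and the acceptance region
#' `0 <= y <= width`. The slit is treated as unbounded along its long axis
#' (experimental slits are tens of micrometres long, two orders of magnitude
#' beyond the mean fibril contour length, so end effects are negligible).
#'
#' @param width slit width w, nm (> 0).
#' @return object of class `slit`.
#' @export
slit <- function(width) {
  if (length(width) != 1L || is.na(width) || width <= 0)
    stop("slit width must be a positive length", call. = FALSE)
  structure(list(width = as.numeric(width)), class = "slit")
}

#' @export
print.slit <- function(x, ...) {
  cat(sprintf("<slit> width %g nm, walls at y = 0 and y = %g\n",
              x$width, x$width))
  invisible(x)
}

#' Place a fibril at random inside a slit
#'
#' Applies a rigid motion: rotation by an angle uniform on [0, 2*pi) about
#' the fibril's center of mass (arc-length-weighted centroid), then placement
#' of that center of mass at a transverse coordinate uniform on [0, w]. The
#' longitudinal coordinate is irrelevant for an unbounded slit and is set
#' to 0. Internal geometry (contour length, kink angles, signs) is unchanged.
#'
#' @param fibril a [fibril_chain()].
#' @param slit a [slit()].
#' @return the transformed `fibril_chain`.
#' @export
place_random <- function(fibril, slit) {
  stopifnot(inherits(fibril, "fibril_chain"), inherits(slit, "slit"))
  com <- chain_centroid(fibril$vertices)
  angle <- stats::runif(1, 0, 2 * pi)
  target <- c(0, stats::runif(1, 0, slit$width))
  transform_chain(fibril, angle = angle, center = com, shift = target - com)
}

#' Does a placed fibril fit entirely inside the slit?
#'
#' The slit cross-section is convex and the chain is made of straight
#' segments, so the whole backbone lies between the walls if and only if
#' every vertex does.
#'
#' @param fibril a placed [fibril_chain()].
#' @param slit a [slit()].
#' @return logical.
#' @export
fits <- function(fibril, slit) {
  y <- fibril$vertices[, 2]
  all(y >= 0 & y <= slit$width)
}

#' Accept/reject simulation of fibrils adsorbed in a slit
#'
#' The entropic-selectivity ("topological filter") experiment: fibrils are
#' drawn from the unconfined population model, placed at a uniformly random
#' orientation and transverse position, and kept only if the whole backbone
#' fits between the walls. The accepted sub-population is what the slit
#' would collect if confinement selected among pre-existing conformations
#' without deforming them.
#'
#' @param model a [fibril_model()] describing the proposal (unconfined)
#'   population.
#' @param slit a [slit()].
#' @param n_accept_target number of accepted fibrils to collect (>= 1).
#' @param max_proposals proposal budget before giving up.
#' @param seed optional integer seed.
#' @return object of class `confined_ensemble`: list with `fibrils`
#'   (accepted, placed chains), `n_proposed`, `n_accepted`,
#'   `acceptance_fraction`, `slit`, `seed`.
#' @examples
#' set.seed(7)
#' ens <- simulate_confined(fibril_model(), slit(750), n_accept_target = 200)
#' ens$acceptance_fraction
#' @export
simulate_confined <- function(model, slit, n_accept_target = 10000L,
                              max_proposals = 200L * n_accept_target,
                              seed = NULL) {
  stopifnot(inherits(model, "fibril_model"), inherits(slit, "slit"))
  if (n_accept_target < 1L)
    stop("n_accept_target must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  accepted <- vector("list", n_accept_target)
  n_acc <- 0L
  n_prop <- 0L
  while (n_acc < n_accept_target && n_prop < max_proposals) {
    n_prop <- n_prop + 1L
    f <- place_random(sample_fibril(model), slit)
    if (fits(f, slit)) {
      n_acc <- n_acc + 1L
      f$id <- n_acc
      accepted[[n_acc]] <- f
    }
  }
  if (n_acc == 0L)
    stop("no fibril accepted within max_proposals; ",
         "the slit is too tight for this population", call. = FALSE)
  if (n_acc < n_accept_target) {
    warning(sprintf("only %d of %d target fibrils accepted within %d proposals",
                    n_acc, n_accept_target, max_proposals))
    accepted <- accepted[seq_len(n_acc)]
  }
  structure(list(fibrils = accepted,
                 n_proposed = n_prop,
                 n_accepted = n_acc,
                 acceptance_fraction = n_acc / n_prop,
                 slit = slit,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "confined_ensemble")
}

#' @export
print.confined_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<confined_ensemble> w = %g nm: %d accepted of %d ",
                     "proposed (acceptance %.3f)\n"),
              x$slit$width, x$n_accepted, x$n_proposed,
              x$acceptance_fraction))
  invisible(x)
}

#' Closed-form order parameter of confined rigid rods
#'
#' For a kink-free rigid rod of length L placed with uniform random
#' orientation and uniform transverse center position in a slit of width w,
#' the probability of fitting at angle theta from the slit axis is
#' `max(0, w - L |sin(theta)|) / w`. Averaging cos(2 theta) over accepted
#' configurations gives the 2D nematic order parameter; for L <= w this
#' evaluates in closed form to `(L/3) / (pi w / 2 - L)`. For L > w the
#' acceptance-weighted average is computed by numerical quadrature over the
#' orientations that can fit.
#'
#' @param L rod length, nm (> 0).
#' @param w slit width, nm (> 0).
#' @return S_2D of the accepted rod ensemble.
#' @examples
#' rod_s2d_closed_form(600, 750)
#' rod_s2d_closed_form(750, 750)  # 1 / (3 * (pi/2 - 1))
#' @export
rod_s2d_closed_form <- function(L, w) {
  if (length(L) != 1L || is.na(L) || L <= 0 ||
      length(w) != 1L || is.na(w) || w <= 0)
    stop("L and w must be positive lengths", call. = FALSE)
  if (L <= w) return((L / 3) / (pi * w / 2 - L))
  rod_s2d_quadrature(L, w)
}

#' Quadrature cross-check of the rod order parameter
#'
#' Integrates the acceptance-weighted orientation density numerically; agrees
#' with [rod_s2d_closed_form()] for L <= w and extends to L > w.
#'
#' @inheritParams rod_s2d_closed_form
#' @return S_2D of the accepted rod ensemble.
#' @export
rod_s2d_quadrature <- function(L, w) {
  if (L <= 0 || w <= 0) stop("L and w must be positive", call. = FALSE)
  acc <- function(th) pmax(0, w - L * sin(th)) / w
  num <- stats::integrate(function(th) cos(2 * th) * acc(th), 0, pi / 2,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(acc, 0, pi / 2, rel.tol = 1e-10)$value
  if (den == 0)
    stop("no orientation of this rod fits the slit", call. = FALSE)
  num / den
}

#' Acceptance probability of a random rigid rod in a slit
#'
#' Fraction of uniform (orientation, transverse position) placements of a
#' rod of length L that fit a slit of width w; `1 - 2 L / (pi w)` for
#' L <= w, by quadrature otherwise.
#'
#' @inheritParams rod_s2d_closed_form
#' @return acceptance probability in [0, 1].
#' @export
rod_acceptance <- function(L, w) {
  if (L <= 0 || w <= 0) stop("L and w must be positive", call. = FALSE)
  if (L <= w) return(1 - 2 * L / (pi * w))
  acc <- function(th) pmax(0, w - L * sin(th)) / w
  stats::integrate(acc, 0, pi / 2, rel.tol = 1e-10)$value / (pi / 2)
}

#' Length-weighted combination of per-ratio order parameters
#'
#' Simulated S_2D values are obtained at a discrete set of L/w ratios; the
#' population-level S_2D weights each ratio by the probability mass that the
#' contour-length distribution (scaled by w) assigns to its bin.
#'
#' Bin edges are midpoints between consecutive sorted ratios; the outer
#' edges extend outwards by half the adjacent gap (clamped at 0), so length
#' mass far outside the evaluated ratio range is not silently attributed to
#' the extreme bins. A single ratio covers the whole support.
#'
#' @param ratios numeric vector of L/w ratios at which S_2D was evaluated.
#' @param s2d_values S_2D per ratio, same length.
#' @param length_law contour length distribution (see [fibril_model()]).
#' @param w slit width, nm.
#' @return weighted mean S_2D.
#' @export
s2d_weighted <- function(ratios, s2d_values, length_law, w) {
  if (length(ratios) != length(s2d_values) || length(ratios) == 0L)
    stop("ratios and s2d_values must be non-empty and matched", call. = FALSE)
  if (any(ratios <= 0)) stop("ratios must be positive", call. = FALSE)
  check_law(length_law, "length_law")
  ord <- order(ratios)
  r <- ratios[ord]
  s <- s2d_values[ord]
  K <- length(r)
  edges <- if (K == 1L) c(0, Inf) else {
    mids <- (r[-K] + r[-1]) / 2
    c(max(0, r[1] - (r[2] - r[1]) / 2), mids, r[K] + (r[K] - r[K - 1]) / 2)
  }
  mass <- diff(law_cdf(length_law, edges * w))
  if (sum(mass) <= 0)
    stop("length distribution has no mass over the supplied ratios",
         call. = FALSE)
  sum(s * mass) / sum(mass)
}
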