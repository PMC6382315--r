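#' Detect kinks on a traced backbone
#'
#' A kink is an interior vertex whose turning angle exceeds the visibility
#' threshold; bends shallower than about 20 degrees cannot be reliably
#' distinguished from the smooth curvature of a traced fibril, hence the
#' default. The bend sign follows the contour: +1 for a bend to the right,
#' -1 to the left (the sign flips when the traversal direction is reversed).
#'
#' @param vertices two-column coordinate matrix (nm) or a [fibril_chain()].
#' @param threshold minimum turning angle in degrees (>= 0) for a bend to
#'   count as a kink.
#' @return data.frame with columns `index`, `angle` (degrees), `sign`;
#'   zero rows when the chain has fewer than 3 vertices or no bend exceeds
#'   the threshold.
#' @export
detect_kinks <- function(vertices, threshold = 20) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    stop("threshold must be a non-negative angle in degrees", call. = FALSE)
  if (inherits(vertices, "fibril_chain")) vertices <- vertices$vertices
  ta <- turning_angles(vertices)
  ta[ta$angle > threshold, , drop = FALSE]
}

#' Normalized mean square radius of gyration of a backbone
#'
#' Computes (Rg/L)^2 = (1/(N L^2)) sum_i |r_i - r_cm|^2 over N points
#' resampled at equal arc-length spacing along the contour, so that mass is
#' distributed uniformly along the backbone regardless of where the traced
#' vertices sit. A straight rod gives 1/12 in the continuum limit; folding
#' contracts the chain and lowers the value.
#'
#' @param vertices two-column coordinate matrix (nm) or a [fibril_chain()].
#' @param resample_step arc-length spacing in nm (> 0); the chain is sampled
#'   at `N = ceiling(L / resample_step) + 1` points.
#' @return dimensionless (Rg/L)^2.
#' @examples
#' rod <- rbind(c(0, 0), c(600, 0))
#' rg_norm_sq(rod, resample_step = 0.5)  # ~ 1/12
#' @export
rg_norm_sq <- function(vertices, resample_step = 5) {
  if (length(resample_step) != 1L || is.na(resample_step) ||
      resample_step <= 0)
    stop("resample_step must be a positive length", call. = FALSE)
  if (inherits(vertices, "fibril_chain")) vertices <- vertices$vertices
  v <- as.matrix(vertices)
  seg <- vertex_segment_lengths(v)
  L <- sum(seg)
  if (!is.finite(L) || L <= 0)
    stop("degenerate chain: zero contour length", call. = FALSE)
  s <- c(0, cumsum(seg))
  # tolerate float jitter in L so rigid motions cannot change the point count
  t <- seq(0, L, length.out = ceiling(L / resample_step - 1e-9) + 1L)
  x <- stats::approx(s, v[, 1], xout = t)$y
  y <- stats::approx(s, v[, 2], xout = t)$y
  mean((x - mean(x))^2 + (y - mean(y))^2) / L^2
}

#' Segment orientation distribution and 2D nematic order parameter
#'
#' Each straight segment of every backbone contributes its orientation angle
#' theta relative to the director, folded to [-90, 90) degrees, weighted by
#' its arc length (so the histogram is the per-unit-contour orientation
#' density). The order parameter is the length-weighted mean
#' `S_2D = <cos(2 theta)>`: 0 for an isotropic population, 1 for perfect
#' alignment along the director, -1 for perfect transverse alignment.
#'
#' @param fibrils list of [fibril_chain()] objects.
#' @param director director orientation in radians from the x-axis (default
#'   the slit long axis, 0).
#' @param n_bins number of histogram bins over the 180-degree range (>= 2).
#' @param n_boot if > 0, number of bootstrap resamples (over fibrils) used
#'   for 95% confidence bounds on the histogram densities and on S_2D.
#' @return list with `s2d`, `od` (data.frame `mid`, `density`, and bootstrap
#'   bounds `lower`/`upper` when requested), `s2d_ci` (when requested), and
#'   `total_length` (nm).
#' @export
orientation_statistics <- function(fibrils, director = 0, n_bins = 36,
                                   n_boot = 0) {
  if (length(fibrils) == 0L)
    stop("empty population", call. = FALSE)
  if (n_bins < 2L) stop("n_bins must be at least 2", call. = FALSE)
  per <- lapply(fibrils, function(f) {
    v <- if (inherits(f, "fibril_chain")) f$vertices else as.matrix(f)
    d <- diff(v)
    th <- atan2(d[, 2], d[, 1]) * 180 / pi - director * 180 / pi
    th <- ((th + 90) %% 180) - 90
    list(theta = th, w = sqrt(rowSums(d^2)))
  })
  breaks <- seq(-90, 90, length.out = n_bins + 1L)
  binw <- 180 / n_bins
  one <- function(idx) {
    th <- unlist(lapply(per[idx], `[[`, "theta"))
    w <- unlist(lapply(per[idx], `[[`, "w"))
    dens <- unname(tapply(w, cut(th, breaks, include.lowest = TRUE),
                          sum, default = 0)) / (sum(w) * binw)
    list(s2d = sum(w * cos(2 * th * pi / 180)) / sum(w), dens = dens)
  }
  full <- one(seq_along(per))
  od <- data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                   density = full$dens)
  out <- list(s2d = full$s2d, od = od, total_length =
                sum(unlist(lapply(per, function(p) sum(p$w)))))
  if (n_boot > 0) {
    n <- length(per)
    boots <- replicate(n_boot, one(sample.int(n, n, replace = TRUE)),
                       simplify = FALSE)
    dm <- do.call(rbind, lapply(boots, `[[`, "dens"))
    out$od$lower <- apply(dm, 2, stats::quantile, 0.025)
    out$od$upper <- apply(dm, 2, stats::quantile, 0.975)
    out$s2d_ci <- stats::quantile(vapply(boots, `[[`, numeric(1), "s2d"),
                                  c(0.025, 0.975), names = FALSE)
  }
  out
}

# Per-fibril kink table: either the generator's own annotation or a fresh
# detection pass at the visibility threshold.
fibril_kinks <- function(f, kinks = c("detect", "annotated"), threshold = 20) {
  kinks <- match.arg(kinks)
  if (kinks == "annotated" && inherits(f, "fibril_chain"))
    return(data.frame(index = f$kink_indices, angle = f$kink_angles,
                      sign = f$signs))
  detect_kinks(f, threshold)
}

#' Morphology summary of a fibril population
#'
#' Computes the per-population conformational descriptors reported in AFM
#' single-fibril studies: mean contour length `mean_L`; mean kink number
#' `mean_nk`; mean kink (turning) angle `mean_kink_angle`, overall and per
#' kink-count class (`mean_kink_angle_by_nk`, classes 1-3 by default);
#' mean inverse kink density `mean_inverse_kink_density`
#' `= 1 / <n_k / L>` (the inverse of the mean kink density, NA for a
#' kink-free population); mean segment length
#' `mean_segment_length = <L / (n_k + 1)>`; normalized mean square radius of
#' gyration `mean_rg_norm_sq`; the orientation distribution and `s2d`; and
#' the bend-direction sign statistics (two-kink sign product and
#' `<|sum s_i|>` per class).
#'
#' @param fibrils list of [fibril_chain()] objects (or coordinate matrices).
#' @param threshold kink visibility threshold in degrees (used when
#'   `kinks = "detect"`).
#' @param resample_step arc-length step for the radius of gyration, nm.
#' @param director,n_bins passed to [orientation_statistics()].
#' @param kinks `"detect"` (default; re-detect kinks from the polyline, as
#'   for traced data) or `"annotated"` (trust the generator's kink labels,
#'   appropriate for simulated ensembles).
#' @param n_boot bootstrap resamples for the sign statistics (0 to skip CIs).
#' @param nk_classes kink-count classes for the per-class mean angle.
#' @return object of class `morphology_summary` (a list; see Details).
#' @export
conformation_summary <- function(fibrils, threshold = 20, resample_step = 5,
                                 director = 0, n_bins = 36,
                                 kinks = c("detect", "annotated"),
                                 n_boot = 0, nk_classes = 1:3) {
  if (length(fibrils) == 0L) stop("empty population", call. = FALSE)
  kinks <- match.arg(kinks)
  ktabs <- lapply(fibrils, fibril_kinks, kinks = kinks, threshold = threshold)
  L <- vapply(fibrils, contour_length, numeric(1))
  n_k <- vapply(ktabs, nrow, integer(1))
  per_fibril <- data.frame(
    id = vapply(seq_along(fibrils), function(i) {
      f <- fibrils[[i]]
      id <- if (inherits(f, "fibril_chain")) f$id else NA_integer_
      if (is.na(id)) i else as.integer(id)
    }, integer(1)),
    L = L, n_k = n_k,
    mean_kink_angle = vapply(ktabs, function(k)
      if (nrow(k)) mean(k$angle) else NA_real_, numeric(1)),
    kink_density = n_k / L,
    segment_length = L / (n_k + 1),
    rg_norm_sq = vapply(fibrils, rg_norm_sq, numeric(1),
                        resample_step = resample_step))
  all_angles <- unlist(lapply(ktabs, function(k) k$angle))
  by_nk <- vapply(nk_classes, function(cl) {
    sel <- n_k == cl
    if (!any(sel)) return(NA_real_)
    mean(unlist(lapply(ktabs[sel], function(k) k$angle)))
  }, numeric(1))
  names(by_nk) <- nk_classes
  ori <- orientation_statistics(fibrils, director = director, n_bins = n_bins)
  signs_list <- lapply(ktabs, function(k) as.integer(k$sign))
  sign_prod <- if (sum(n_k == 2L) > 0L)
    sign_product_stats(signs_list[n_k == 2L], n_boot = n_boot) else NULL
  sum_classes <- intersect(2:4, unique(n_k))
  sign_sums <- lapply(sum_classes, function(cl)
    sign_sum_abs(signs_list[n_k == cl], n_boot = n_boot))
  names(sign_sums) <- sum_classes
  structure(list(
    n_fibrils = length(fibrils),
    mean_L = mean(L),
    mean_nk = mean(n_k),
    mean_kink_angle = if (length(all_angles)) mean(all_angles) else NA_real_,
    mean_kink_angle_by_nk = by_nk,
    mean_inverse_kink_density =
      if (mean(per_fibril$kink_density) > 0)
        1 / mean(per_fibril$kink_density) else NA_real_,
    mean_segment_length = mean(per_fibril$segment_length),
    mean_rg_norm_sq = mean(per_fibril$rg_norm_sq),
    s2d = ori$s2d,
    od = ori$od,
    sign_product = sign_prod,
    sign_sum_abs_by_nk = sign_sums,
    per_fibril = per_fibril),
    class = "morphology_summary")
}

#' @export
print.morphology_summary <- function(x, ...) {
  cat("<morphology_summary>", x$n_fibrils, "fibrils\n")
  cat(sprintf("  <L> = %.1f nm   <n_k> = %.3f   <theta_k> = %s deg\n",
              x$mean_L, x$mean_nk,
              if (is.na(x$mean_kink_angle)) "NA"
              else sprintf("%.1f", x$mean_kink_angle)))
  cat(sprintf("  <rho_k>^-1 = %s nm   <L_seg> = %.1f nm\n",
              if (is.na(x$mean_inverse_kink_density)) "NA"
              else sprintf("%.1f", x$mean_inverse_kink_density),
              x$mean_segment_length))
  cat(sprintf("  <(Rg/L)^2> = %.4f   S_2D = %.4f\n",
              x$mean_rg_norm_sq, x$s2d))
  if (!is.null(x$sign_product))
    cat(sprintf("  <s1 s2> = %.3f (p_hat = %.3f)\n",
                x$sign_product$mean, x$sign_product$p_hat))
  invisible(x)
}

# Extract sign vectors from a mixed list of fibril_chains / sign vectors.
as_sign_list <- function(fibrils) {
  lapply(fibrils, function(f) {
    if (inherits(f, "fibril_chain")) f$signs else as.integer(f)
  })
}

#' Two-kink bend-sign product statistics
#'
#' For fibrils with exactly two kinks, the product `s1 * s2` is +1 when both
#' kinks bend to the same side and -1 otherwise, so its mean m ties directly
#' to the nearest-neighbour persistence probability through
#' `m = p - (1 - p)`, i.e. `p = (m + 1) / 2`. Under the random-walk null
#' (p = 0.5) the mean is 0 and the variance 1.
#'
#' @param fibrils list of two-kink [fibril_chain()] objects, or a list of
#'   length-2 sign vectors.
#' @param n_boot bootstrap resamples (over fibrils) for the standard error
#'   and 95% CI of `p_hat`; 0 to skip.
#' @return list with `mean` (<s1 s2>), `variance`, `p_hat`, `n`, and when
#'   bootstrapped `p_se`, `p_ci`.
#' @export
sign_product_stats <- function(fibrils, n_boot = 1000) {
  signs <- as_sign_list(fibrils)
  if (length(signs) == 0L)
    stop("no two-kink fibrils in the population", call. = FALSE)
  if (any(lengths(signs) != 2L))
    stop("sign_product_stats needs the two-kink class only", call. = FALSE)
  prod2 <- vapply(signs, function(s) s[1] * s[2], numeric(1))
  m <- mean(prod2)
  out <- list(mean = m, variance = mean((prod2 - m)^2),
              p_hat = p_from_sign_product(m), n = length(prod2))
  if (n_boot > 0 && length(prod2) >= 2L) {
    bs <- bootstrap_ci(prod2, function(x) p_from_sign_product(mean(x)),
                       n_boot = n_boot)
    out$p_se <- bs$se
    out$p_ci <- c(bs$lower, bs$upper)
  }
  out
}

#' Invert the sign-product relation for the persistence probability
#'
#' With m = <s1 s2> over the two-kink class, `m = p - (1 - p)` gives
#' `p = (m + 1) / 2`; the variance of the +/-1-valued product is `1 - m^2`.
#'
#' @param m mean two-kink sign product in [-1, 1].
#' @return persistence probability p.
#' @examples
#' p_from_sign_product(0.30)  # 0.65
#' @export
p_from_sign_product <- function(m) {
  if (any(abs(m) > 1)) stop("a +/-1 product mean must lie in [-1, 1]",
                            call. = FALSE)
  (m + 1) / 2
}

#' @rdname p_from_sign_product
#' @return `sign_product_variance`: variance `1 - m^2` of the +/-1 product.
#' @export
sign_product_variance <- function(m) {
  if (any(abs(m) > 1)) stop("a +/-1 product mean must lie in [-1, 1]",
                            call. = FALSE)
  1 - m^2
}

#' Theoretical mean two-kink sign product
#'
#' `<s1 s2> = p - (1 - p) = 2p - 1` under the nearest-neighbour persistence
#' model; 0 under the random-walk null p = 0.5.
#'
#' @param p persistence probability in [0, 1].
#' @return expected product of the two bend signs.
#' @export
sign_product_theory <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  2 * p - 1
}

#' Mean absolute sign sum of a kink-count class
#'
#' `<|sum_i s_i|>` over fibrils of a given kink count: the net bend
#' imbalance, invariant under per-fibril traversal reversal (which flips all
#' signs at once).
#'
#' @param fibrils list of [fibril_chain()] objects or sign vectors, all of
#'   the same kink count.
#' @param n_boot bootstrap resamples for a 95% CI; 0 to skip.
#' @return list with `mean`, `n`, and when bootstrapped `se`, `ci`.
#' @export
sign_sum_abs <- function(fibrils, n_boot = 1000) {
  signs <- as_sign_list(fibrils)
  if (length(signs) == 0L) stop("empty kink-count class", call. = FALSE)
  if (length(unique(lengths(signs))) != 1L)
    stop("all fibrils must share the same kink count", call. = FALSE)
  vals <- vapply(signs, function(s) abs(sum(s)), numeric(1))
  out <- list(mean = mean(vals), n = length(vals))
  if (n_boot > 0 && length(vals) >= 2L) {
    bs <- bootstrap_ci(vals, mean, n_boot = n_boot)
    out$se <- bs$se
    out$ci <- c(bs$lower, bs$upper)
  }
  out
}

#' Exact mean absolute sign sum under the persistence model
#'
#' Closed forms for the expected net bend imbalance `<|sum_i s_i|>` of a
#' fibril whose bend signs follow the nearest-neighbour persistence chain:
#' `2p` for 2 kinks, `2p^2 + 1` for 3, `4p^3 - 4p^2 + 4p` for 4. For more
#' kinks the exact value is obtained by enumerating all `2^(n_k - 1)`
#' agreement patterns between consecutive signs, pattern probability
#' `p^a (1-p)^(n_k - 1 - a)` with `a` agreements.
#'
#' @param n_k kink count (>= 2).
#' @param p persistence probability in [0, 1].
#' @param method `"closed_form"` (default; falls back to enumeration for
#'   n_k > 4) or `"enumeration"`.
#' @return expected `<|sum s_i|>`.
#' @examples
#' sign_sum_theory(2, 0.65)  # 1.30
#' sign_sum_theory(4, 0.65)  # 2.0085
#' @export
sign_sum_theory <- function(n_k, p,
                            method = c("closed_form", "enumeration")) {
  method <- match.arg(method)
  if (length(n_k) != 1L || is.na(n_k) || n_k < 2)
    stop("n_k must be at least 2", call. = FALSE)
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must lie in [0, 1]", call. = FALSE)
  n_k <- as.integer(n_k)
  if (method == "closed_form" && n_k <= 4L)
    return(switch(n_k - 1L,
                  2 * p,                       # n_k = 2
                  2 * p^2 + 1,                 # n_k = 3
                  4 * p^3 - 4 * p^2 + 4 * p))  # n_k = 4
  sign_sum_enumeration(n_k, p)
}

# Exact enumeration over all agreement patterns of the sign chain. |sum s_i|
# does not depend on the first sign, so fix s1 = +1 and enumerate the
# 2^(n_k - 1) agree/disagree patterns.
sign_sum_enumeration <- function(n_k, p) {
  m <- n_k - 1L
  if (m > 20L)
    stop("enumeration over 2^(n_k - 1) patterns is impractical for n_k > 21",
         call. = FALSE)
  grid <- as.matrix(expand.grid(rep(list(c(1, -1)), m)))
  vals <- apply(grid, 1L, function(g) abs(sum(cumprod(c(1, g)))))
  n_agree <- rowSums(grid == 1)
  probs <- p^n_agree * (1 - p)^(m - n_agree)
  # 0^0 = 1 handles the degenerate p = 0 / p = 1 chains
  sum(vals * probs)
}

#' Onsager excluded area of a thin rigid rod
#'
#' In two dimensions the excluded area of two thin rigid rods of length L at
#' isotropic relative orientation is `2 L^2 / pi` (the average over the
#' relative angle gamma of `L^2 |sin gamma|`). When the substrate area
#' available per fibril falls below this, fibril-fibril interactions can no
#' longer be neglected.
#'
#' @param L rod length, nm (> 0).
#' @return excluded area in nm^2.
#' @export
excluded_area_rod <- function(L) {
  if (any(L <= 0)) stop("L must be positive", call. = FALSE)
  2 * L^2 / pi
}

#' @rdname excluded_area_rod
#' @param area_per_fibril substrate area available per fibril, nm^2 (> 0).
#' @return `interaction_flag`: TRUE when `area_per_fibril < 2 L^2 / pi`
#'   (the dilute-deposition assumption fails).
#' @export
interaction_flag <- function(area_per_fibril, L) {
  if (any(area_per_fibril <= 0)) stop("area must be positive", call. = FALSE)
  area_per_fibril < excluded_area_rod(L)
}

#' Percentile bootstrap over per-fibril values
#'
#' Resamples the per-fibril values with replacement (the fibril is the
#' resampling unit) and returns the percentile confidence interval of the
#' statistic, as used for error bars on single-fibril summary statistics.
#'
#' @param values numeric vector of per-fibril values (length >= 2).
#' @param statistic function mapping a numeric vector to a scalar.
#' @param n_boot number of resamples (>= 100).
#' @param conf confidence level.
#' @return list with `estimate`, `lower`, `upper`, `se`.
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 1000,
                         conf = 0.95) {
  if (length(values) < 2L)
    stop("need at least 2 values to bootstrap", call. = FALSE)
  if (n_boot < 100L) stop("n_boot must be at least 100", call. = FALSE)
  n <- length(values)
  reps <- vapply(seq_len(n_boot), function(i)
    statistic(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  list(estimate = statistic(values), lower = qs[1], upper = qs[2],
       se = stats::sd(reps))
}
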