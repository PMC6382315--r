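#' Generative model of a kinked-fibril population
#'
#' Describes the statistical law from which single fibrils are drawn:
#' a contour-length distribution, a probability mass function for the number
#' of kinks, a kink (turning) angle law, a rule partitioning the contour into
#' segments, and the nearest-neighbour bend-direction persistence.
#'
#' The defaults emulate the unconfined population of TEMPO-oxidised cellulose
#' nanofibrils used throughout this package: contour lengths uniform on
#' [550, 650] nm (mean 600 nm), kink-count probabilities
#' (0.21, 0.45, 0.26, 0.05, 0.03) for 0..4 kinks (expected kink number 1.24),
#' every kink at a fixed 65 degree turning angle, random segment partition,
#' and persistence p = 0.65 (a kink bends to the same side as its predecessor
#' with probability 0.65).
#'
#' Distribution laws are lists with a `type` field:
#' \describe{
#'   \item{length_law}{`list(type = "uniform", min, max)`,
#'     `list(type = "lognormal", meanlog, sdlog)`, or
#'     `list(type = "fixed", value)` (nm).}
#'   \item{kink_angle_law}{`list(type = "fixed", value)` or
#'     `list(type = "uniform", min, max)` (degrees, within (0, 180)).}
#' }
#'
#' @param length_law contour length distribution (nm), see Details.
#' @param kink_pmf numeric vector of probabilities for 0, 1, 2, ... kinks;
#'   non-negative, summing to 1.
#' @param kink_angle_law turning-angle distribution (degrees), see Details.
#' @param partition_law `"random"` (breakpoints uniform on the contour, i.e.
#'   segment fractions flat-Dirichlet) or `"equal"` (all segments equal).
#' @param persistence_p probability in [0, 1] that a kink bends in the same
#'   direction as the previous kink.
#'
#' @return object of class `fibril_model`.
#' @examples
#' m <- fibril_model()
#' expected_kink_count(m$kink_pmf)  # 1.24
#' @export
fibril_model <- function(length_law = list(type = "uniform",
                                           min = 550, max = 650),
                         kink_pmf = c(0.21, 0.45, 0.26, 0.05, 0.03),
                         kink_angle_law = list(type = "fixed", value = 65),
                         partition_law = c("random", "equal"),
                         persistence_p = 0.65) {
  partition_law <- match.arg(partition_law)
  kink_pmf <- as.numeric(kink_pmf)
  if (any(kink_pmf < 0) || abs(sum(kink_pmf) - 1) > 1e-8)
    stop("kink_pmf must be non-negative and sum to 1", call. = FALSE)
  if (!is.numeric(persistence_p) || persistence_p < 0 || persistence_p > 1)
    stop("persistence_p must lie in [0, 1]", call. = FALSE)
  check_law(length_law, "length_law", positive = TRUE)
  check_law(kink_angle_law, "kink_angle_law", angle = TRUE)
  structure(list(length_law = length_law,
                 kink_pmf = kink_pmf,
                 kink_angle_law = kink_angle_law,
                 partition_law = partition_law,
                 persistence_p = persistence_p),
            class = "fibril_model")
}

check_law <- function(law, what, positive = FALSE, angle = FALSE) {
  if (!is.list(law) || is.null(law$type))
    stop(sprintf("%s must be a list with a `type` field", what), call. = FALSE)
  ok <- switch(law$type,
    uniform = !is.null(law$min) && !is.null(law$max) && law$min <= law$max,
    fixed = !is.null(law$value),
    lognormal = !is.null(law$meanlog) && !is.null(law$sdlog),
    FALSE)
  if (!ok)
    stop(sprintf("malformed %s of type '%s'", what, law$type), call. = FALSE)
  if (angle) {
    hi <- if (law$type == "fixed") law$value else law$max
    lo <- if (law$type == "fixed") law$value else law$min
    if (hi >= 180 || lo < 0)
      stop(sprintf("%s must stay within (0, 180) degrees", what),
           call. = FALSE)
  }
  invisible(law)
}

#' @export
print.fibril_model <- function(x, ...) {
  cat("<fibril_model>\n")
  cat("  length_law:     ", format_law(x$length_law), " nm\n", sep = "")
  cat("  kink_pmf:       ", paste(x$kink_pmf, collapse = ", "),
      "  (<n_k> = ", expected_kink_count(x$kink_pmf), ")\n", sep = "")
  cat("  kink_angle_law: ", format_law(x$kink_angle_law), " deg\n", sep = "")
  cat("  partition_law:  ", x$partition_law, "\n", sep = "")
  cat("  persistence_p:  ", x$persistence_p, "\n", sep = "")
  invisible(x)
}

format_law <- function(law) {
  switch(law$type,
    uniform = sprintf("uniform(%g, %g)", law$min, law$max),
    fixed = sprintf("fixed %g", law$value),
    lognormal = sprintf("lognormal(meanlog=%g, sdlog=%g)",
                        law$meanlog, law$sdlog))
}

draw_law <- function(law, n = 1L) {
  switch(law$type,
    uniform = stats::runif(n, law$min, law$max),
    fixed = rep.int(law$value, n),
    lognormal = stats::rlnorm(n, law$meanlog, law$sdlog))
}

law_cdf <- function(law, q) {
  switch(law$type,
    uniform = stats::punif(q, law$min, law$max),
    fixed = as.numeric(q >= law$value),
    lognormal = stats::plnorm(q, law$meanlog, law$sdlog))
}

#' Expected kink number under a kink-count pmf
#'
#' @param kink_pmf probabilities of 0, 1, 2, ... kinks.
#' @return `sum(n * pmf(n))`; 1.24 for the default unconfined pmf.
#' @export
expected_kink_count <- function(kink_pmf) {
  kink_pmf <- as.numeric(kink_pmf)
  if (any(kink_pmf < 0) || abs(sum(kink_pmf) - 1) > 1e-8)
    stop("kink_pmf must be non-negative and sum to 1", call. = FALSE)
  sum((seq_along(kink_pmf) - 1) * kink_pmf)
}

#' Draw a bend-direction sign sequence
#'
#' Signs follow a two-state Markov chain: the first kink bends left or right
#' with equal probability, and each subsequent kink bends to the same side as
#' its predecessor with probability `p` (nearest-neighbour persistence).
#'
#' @param n_k number of kinks (>= 0).
#' @param p persistence probability in [0, 1].
#' @return integer vector of length `n_k` over {-1, +1}.
#' @examples
#' set.seed(1); sample_signs(3, 1)  # persistence 1 forces agreement
#' @export
sample_signs <- function(n_k, p) {
  if (length(n_k) != 1L || is.na(n_k) || n_k < 0)
    stop("n_k must be a non-negative count", call. = FALSE)
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must lie in [0, 1]", call. = FALSE)
  n_k <- as.integer(n_k)
  if (n_k == 0L) return(integer(0))
  first <- if (stats::runif(1) < 0.5) -1L else 1L
  if (n_k == 1L) return(first)
  same <- stats::runif(n_k - 1L) < p
  as.integer(first * cumprod(c(1L, ifelse(same, 1L, -1L))))
}

#' Partition a contour length into segments
#'
#' Splits a contour of length `L` into `n_k + 1` strictly positive segment
#' lengths. The `"random"` law places `n_k` independent uniform breakpoints
#' on [0, L] and returns the spacings (equivalently, segment fractions from a
#' flat Dirichlet); the `"equal"` law returns `n_k + 1` equal segments.
#'
#' @param L contour length, nm (> 0).
#' @param n_k number of kinks (>= 0).
#' @param partition_law `"random"` or `"equal"`.
#' @return numeric vector of `n_k + 1` lengths summing to `L`.
#' @export
sample_segment_lengths <- function(L, n_k,
                                   partition_law = c("random", "equal")) {
  partition_law <- match.arg(partition_law)
  if (length(L) != 1L || is.na(L) || L <= 0)
    stop("L must be a positive length", call. = FALSE)
  if (length(n_k) != 1L || is.na(n_k) || n_k < 0)
    stop("n_k must be a non-negative count", call. = FALSE)
  n_k <- as.integer(n_k)
  if (n_k == 0L) return(L)
  if (partition_law == "equal") return(rep.int(L / (n_k + 1), n_k + 1L))
  diff(c(0, sort(stats::runif(n_k, 0, L)), L))
}

#' Realize a fibril geometry from segments, angles and signs
#'
#' Builds the backbone polyline by dead reckoning: starting at `origin` with
#' direction `heading`, each segment advances the current position, and at
#' each kink the heading turns by the kink angle, clockwise for sign +1
#' (a bend to the right of travel) and counter-clockwise for sign -1.
#'
#' @param segment_lengths positive segment lengths, nm.
#' @param kink_angles turning angles in degrees, one fewer than segments.
#' @param signs bend signs (-1/+1), same length as `kink_angles`.
#' @param origin starting vertex, nm.
#' @param heading initial direction, radians from the x-axis.
#' @param id optional fibril identifier.
#' @return a [fibril_chain()].
#' @examples
#' fc <- build_polyline(c(100, 100), kink_angles = 90, signs = 1L)
#' sqrt(sum((fc$vertices[3, ] - fc$vertices[1, ])^2))  # 100 * sqrt(2)
#' @export
build_polyline <- function(segment_lengths, kink_angles = numeric(),
                           signs = integer(), origin = c(0, 0), heading = 0,
                           id = NA_integer_) {
  n_seg <- length(segment_lengths)
  if (length(kink_angles) != n_seg - 1L || length(signs) != n_seg - 1L)
    stop("need exactly one kink angle and sign per interior joint ",
         "(length(segment_lengths) - 1)", call. = FALSE)
  if (any(segment_lengths <= 0))
    stop("segment lengths must be strictly positive", call. = FALSE)
  turn <- -as.numeric(signs) * kink_angles * pi / 180
  headings <- heading + cumsum(c(0, turn))
  x <- origin[1] + cumsum(c(0, segment_lengths * cos(headings)))
  y <- origin[2] + cumsum(c(0, segment_lengths * sin(headings)))
  n_k <- n_seg - 1L
  fibril_chain(cbind(x, y),
               kink_indices = if (n_k > 0L) seq_len(n_k) + 1L else integer(),
               kink_angles = kink_angles, signs = as.integer(signs), id = id)
}

#' Draw a single fibril from a population model
#'
#' Contour length, kink count, kink angles, bend signs and segment partition
#' are drawn from the model's laws and realized as a polyline at the origin
#' with heading 0 (random placement in a slit happens separately).
#'
#' @param model a [fibril_model()].
#' @param id optional fibril identifier.
#' @return a [fibril_chain()].
#' @export
sample_fibril <- function(model, id = NA_integer_) {
  stopifnot(inherits(model, "fibril_model"))
  L <- draw_law(model$length_law)
  n_k <- sample.int(length(model$kink_pmf), 1L, prob = model$kink_pmf) - 1L
  segs <- sample_segment_lengths(L, n_k, model$partition_law)
  angles <- if (n_k > 0L) draw_law(model$kink_angle_law, n_k) else numeric()
  signs <- sample_signs(n_k, model$persistence_p)
  build_polyline(segs, angles, signs, id = id)
}

#' Draw a population of fibrils
#'
#' @param model a [fibril_model()].
#' @param n number of fibrils.
#' @param seed optional integer seed for reproducibility.
#' @return list of [fibril_chain()] objects with ids `1:n`.
#' @export
sample_population <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) sample_fibril(model, id = i))
}
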