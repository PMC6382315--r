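#' Fibril backbone as a 2D polyline with kink annotation
#'
#' A `fibril_chain` is an ordered open polyline of vertices in the plane
#' (coordinates in nm), the coarse-grained trace of a single nanofibril
#' backbone. Interior vertices may be annotated as kinks: sharp localized
#' bends between otherwise straight, stiff segments. Each kink carries a
#' turning angle (degrees; 0 = collinear continuation, 180 = complete
#' fold-back) and a bend-direction sign: +1 for a bend to the right of the
#' direction of travel, -1 for a bend to the left.
#'
#' @param vertices numeric matrix with two columns (x, y) in nm, one row per
#'   vertex; at least two rows, consecutive rows distinct.
#' @param kink_indices integer vector of interior vertex indices (in
#'   `2:(nrow(vertices) - 1)`) that are kinks, strictly increasing.
#' @param kink_angles numeric vector of turning angles in degrees, one per
#'   kink, each strictly inside (0, 180).
#' @param signs integer vector of bend directions, one per kink, each -1 or +1.
#' @param id optional identifier carried through I/O.
#'
#' @return An object of class `fibril_chain`: a list with elements
#'   `vertices`, `kink_indices`, `kink_angles`, `signs`, `id`, and the cached
#'   contour length `L` (nm).
#' @examples
#' fc <- fibril_chain(rbind(c(0, 0), c(100, 0), c(100, 100)),
#'                    kink_indices = 2L, kink_angles = 90, signs = -1L)
#' fc$L
#' @export
fibril_chain <- function(vertices, kink_indices = integer(),
                         kink_angles = numeric(), signs = integer(),
                         id = NA_integer_) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 2L)
    stop("`vertices` must have two columns (x, y)", call. = FALSE)
  if (nrow(vertices) < 2L)
    stop("a fibril needs at least 2 vertices", call. = FALSE)
  seg <- sqrt(rowSums(diff(vertices)^2))
  if (any(seg == 0))
    stop("consecutive vertices must be distinct", call. = FALSE)
  n_k <- length(kink_indices)
  if (length(kink_angles) != n_k || length(signs) != n_k)
    stop("kink_indices, kink_angles and signs must have equal length",
         call. = FALSE)
  if (n_k > 0L) {
    kink_indices <- as.integer(kink_indices)
    if (is.unsorted(kink_indices, strictly = TRUE) ||
        any(kink_indices < 2L) || any(kink_indices > nrow(vertices) - 1L))
      stop("kink_indices must be strictly increasing interior vertex indices",
           call. = FALSE)
    if (any(kink_angles <= 0 | kink_angles >= 180))
      stop("kink angles must lie strictly in (0, 180) degrees", call. = FALSE)
    signs <- as.integer(signs)
    if (any(abs(signs) != 1L))
      stop("signs must be -1 or +1", call. = FALSE)
  }
  structure(
    list(vertices = unname(vertices),
         kink_indices = as.integer(kink_indices),
         kink_angles = as.numeric(kink_angles),
         signs = as.integer(signs),
         id = id,
         L = sum(seg)),
    class = "fibril_chain")
}

#' @export
print.fibril_chain <- function(x, ...) {
  cat(sprintf("<fibril_chain> %d vertices, L = %.1f nm, %d kink%s",
              nrow(x$vertices), x$L, length(x$kink_indices),
              if (length(x$kink_indices) == 1L) "" else "s"))
  if (length(x$kink_angles))
    cat(sprintf(" (angles %s deg)",
                paste(formatC(x$kink_angles, digits = 3), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Number of kinks of a fibril
#' @param chain a `fibril_chain`.
#' @return integer kink count.
#' @export
n_kinks <- function(chain) length(chain$kink_indices)

#' Contour length of a polyline
#' @param vertices two-column coordinate matrix, or a `fibril_chain`.
#' @return total arc length in nm.
#' @export
contour_length <- function(vertices) {
  if (inherits(vertices, "fibril_chain")) return(vertices$L)
  sum(sqrt(rowSums(diff(as.matrix(vertices))^2)))
}

# Straight-segment lengths between consecutive vertices.
vertex_segment_lengths <- function(vertices) {
  sqrt(rowSums(diff(as.matrix(vertices))^2))
}

# Arc-length-weighted centroid of a polyline (uniform mass along the contour:
# each straight segment contributes its midpoint weighted by its length).
chain_centroid <- function(vertices) {
  v <- as.matrix(vertices)
  w <- vertex_segment_lengths(v)
  mid <- (v[-1, , drop = FALSE] + v[-nrow(v), , drop = FALSE]) / 2
  colSums(mid * w) / sum(w)
}

#' Turning angles and bend signs at interior vertices
#'
#' For each interior vertex the turning angle between the incoming and
#' outgoing direction is reported in degrees, together with the bend
#' direction: +1 for a right bend (clockwise heading change while following
#' the contour), -1 for a left bend, 0 where the three points are collinear.
#'
#' @param vertices two-column coordinate matrix (>= 3 rows for a non-empty
#'   result).
#' @return data.frame with columns `index` (vertex index), `angle` (degrees,
#'   in `[0, 180]`) and `sign`.
#' @export
turning_angles <- function(vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  if (n < 3L)
    return(data.frame(index = integer(), angle = numeric(), sign = integer()))
  a <- v[2:(n - 1), , drop = FALSE] - v[1:(n - 2), , drop = FALSE]
  b <- v[3:n, , drop = FALSE] - v[2:(n - 1), , drop = FALSE]
  cross <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  dot <- rowSums(a * b)
  ang <- atan2(abs(cross), dot) * 180 / pi
  data.frame(index = 2:(n - 1), angle = ang, sign = -sign(cross))
}

#' Reverse the traversal direction of a fibril
#'
#' Traversal direction is an artefact of tracing; reversing it preserves the
#' contour length and every kink angle while flipping every bend sign (a
#' right bend becomes a left bend when walked backwards).
#'
#' @param chain a `fibril_chain`.
#' @return the reversed `fibril_chain`.
#' @export
reverse_chain <- function(chain) {
  stopifnot(inherits(chain, "fibril_chain"))
  n <- nrow(chain$vertices)
  ord <- rev(seq_along(chain$kink_indices))
  fibril_chain(chain$vertices[n:1, , drop = FALSE],
               kink_indices = (n + 1L - chain$kink_indices)[ord],
               kink_angles = chain$kink_angles[ord],
               signs = -chain$signs[ord],
               id = chain$id)
}

# Apply a rigid motion: rotate by `angle` (radians, counter-clockwise) about
# `center`, then translate by `shift`. Kink annotation is untouched.
transform_chain <- function(chain, angle = 0, center = c(0, 0),
                            shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  v <- sweep(chain$vertices, 2L, center) %*% t(R)
  v <- sweep(v, 2L, center + shift, `+`)
  out <- chain
  out$vertices <- v
  out
}
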