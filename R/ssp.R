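# ---- Spatial semantic pointers ----------------------------------------------
#
# phi(x) = IDFT{ exp(i A x) } with a conjugate-symmetric encoding matrix A so
# that the result is real. d is required odd: the row structure is then one
# all-zero DC row plus (d-1)/2 +/- pairs, with no Nyquist special case. Under
# the package's DFT convention (1/d on the inverse) every point encoding has
# unit Euclidean norm.

#' Create an SSP encoder
#'
#' @param d SSP dimensionality (odd; the reference configuration uses 181).
#' @param m dimensionality of the encoded variable (2 for planar arenas).
#' @param length_scale positive scalar; phase rows are drawn uniformly from
#'   `[-pi/length_scale, pi/length_scale]^m` for the random style, so the
#'   similarity kernel's main lobe has half-width about `length_scale`.
#' @param seed integer seed; encoders are deterministic in `(d, m, seed, style)`.
#' @param style `"random"` (default) or `"hexagonal"` (m = 2 only): wave-vector
#'   triplets at 120 degree separation across several scales, giving grid-cell
#'   firing maps with hexagonal symmetry downstream.
#' @param domain_bounds m x 2 matrix of (lower, upper) per axis; defaults to
#'   `[-1.2, 1.2]` per axis (a unit-radius arena with margin).
#' @param n_scales,scale_range hexagonal style only: number of spatial-frequency
#'   modules and their magnitude range in rad/unit.
#' @return An object of class `ssp_encoder` with fields `A` (d x m), `A_half`
#'   (the free half-spectrum rows), `d`, `m`, `length_scale`, `domain_bounds`.
#' @export
ssp_encoder <- function(d, m, length_scale = 0.15, seed = 1L,
                        style = c("random", "hexagonal"),
                        domain_bounds = NULL,
                        n_scales = 4L, scale_range = NULL) {
  style <- match.arg(style)
  d <- as.integer(d); m <- as.integer(m)
  if (d %% 2L == 0L) stop("d must be odd")
  if (m < 1L) stop("m must be >= 1")
  if (length_scale <= 0) stop("length_scale must be positive")
  if (style == "hexagonal" && m != 2L)
    stop("hexagonal style is only supported for m = 2")
  h <- (d - 1L) %/% 2L
  A_half <- with_seed(seed, {
    if (style == "random") {
      matrix(stats::runif(h * m, -pi / length_scale, pi / length_scale),
             nrow = h, ncol = m)
    } else {
      if (is.null(scale_range)) scale_range <- pi / length_scale * c(0.25, 1)
      ks <- exp(seq(log(scale_range[1L]), log(scale_range[2L]),
                    length.out = n_scales))
      rows <- matrix(0, nrow = 0L, ncol = 2L)
      s <- 0L
      while (nrow(rows) < h) {
        k <- ks[(s %% n_scales) + 1L]
        th0 <- stats::runif(1L, 0, 2 * pi / 3)
        tri <- th0 + c(0, 2 * pi / 3, 4 * pi / 3)
        rows <- rbind(rows, k * cbind(cos(tri), sin(tri)))
        s <- s + 1L
      }
      rows[seq_len(h), , drop = FALSE]
    }
  })
  if (is.null(domain_bounds))
    domain_bounds <- cbind(rep(-1.2, m), rep(1.2, m))
  domain_bounds <- matrix(as.numeric(domain_bounds), ncol = 2L)
  A <- matrix(0, nrow = d, ncol = m)
  A[1L + seq_len(h), ] <- A_half
  A[d + 1L - seq_len(h), ] <- -A_half
  if (style == "hexagonal") {
    # record which frequency module each half-row belongs to (for grid-cell
    # encoders restricted to a single module)
    module <- ((seq_len(h) - 1L) %/% 3L) %% n_scales
  } else module <- NULL
  structure(list(A = A, A_half = A_half, d = d, m = m, h = h,
                 length_scale = length_scale, seed = as.integer(seed),
                 style = style, domain_bounds = domain_bounds,
                 module = module, n_scales = if (style == "hexagonal") n_scales),
            class = "ssp_encoder")
}

#' @export
print.ssp_encoder <- function(x, ...) {
  cat(sprintf("<ssp_encoder d=%d m=%d style=%s length_scale=%g>\n",
              x$d, x$m, x$style, x$length_scale))
  invisible(x)
}

#' Encode a point as a spatial semantic pointer
#'
#' @param enc an [ssp_encoder()].
#' @param x numeric vector of length `m` (or n x m matrix for many points).
#' @return numeric vector of length `d` (or d x n matrix).
#' @export
encode_ssp <- function(enc, x) {
  if (is.matrix(x)) {
    if (ncol(x) != enc$m) stop("x must have m columns")
    ph <- enc$A %*% t(x)                       # d x n phases
    sp <- exp(1i * ph)
    Re(stats::mvfft(sp, inverse = TRUE)) / enc$d
  } else {
    if (length(x) != enc$m) stop("x must have length m")
    if (!all(is.finite(x))) stop("x must be finite")
    ph <- drop(enc$A %*% x)
    Re(stats::fft(exp(1i * ph), inverse = TRUE)) / enc$d
  }
}

#' Fractional power of the encoder's base (spectrum-domain shift by x)
#'
#' Binding with `encode_ssp(enc, x)` shifts any SSP by `x`; exposed for
#' completeness and used internally by the path integrator.
#' @keywords internal
ssp_shift <- function(enc, v, x) bind(v, encode_ssp(enc, x))

# evaluation lattice over the encoder's domain: list(points [n x m], steps,
# axes); resolution is points per axis.
ssp_grid <- function(enc, resolution) {
  axes <- lapply(seq_len(enc$m), function(k)
    seq(enc$domain_bounds[k, 1L], enc$domain_bounds[k, 2L],
        length.out = resolution))
  pts <- as.matrix(expand.grid(axes))
  colnames(pts) <- NULL
  steps <- vapply(axes, function(a) a[2L] - a[1L], 0)
  list(points = pts, axes = axes, steps = steps,
       cell = prod(steps), resolution = resolution)
}

#' Similarity map of a vector over the encoder's domain
#'
#' Dot products of `v` against point encodings on a regular lattice; the
#' standard way to visualise a high-dimensional SSP.
#'
#' @param enc an encoder.
#' @param v numeric vector of length `d`.
#' @param resolution lattice points per axis (>= 2).
#' @return list with `points` (n x m), `values` (n), `axes`, and for m = 2 a
#'   `field` matrix (resolution x resolution, x varying along rows).
#' @export
similarity_map <- function(enc, v, resolution = 101L) {
  stopifnot(resolution >= 2L, length(v) == enc$d)
  g <- ssp_grid(enc, resolution)
  Phi <- encode_ssp(enc, g$points)             # d x n
  vals <- drop(crossprod(Phi, v))
  out <- list(points = g$points, values = vals, axes = g$axes)
  if (enc$m == 2L)
    out$field <- matrix(vals, nrow = resolution)
  out
}

#' Write a similarity map as a CSV lattice
#' @param map result of [similarity_map()].
#' @param path output file.
#' @export
similarity_map_csv <- function(map, path) {
  df <- as.data.frame(map$points)
  names(df) <- c("x", "y", "z")[seq_len(ncol(map$points))]
  df$value <- map$values
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Encode a region by integrating point encodings over an indicator set
#'
#' Riemann sum of `phi(x)` over the cells of an `n_quadrature`-per-axis lattice
#' whose centres satisfy the indicator, scaled by cell area/volume.
#'
#' @param enc an encoder.
#' @param indicator function taking an n x m matrix of points, returning a
#'   logical vector.
#' @param n_quadrature lattice points per axis.
#' @export
encode_region <- function(enc, indicator, n_quadrature = 101L) {
  g <- ssp_grid(enc, n_quadrature)
  keep <- indicator(g$points)
  if (!any(keep)) stop("indicator is nowhere true on the quadrature lattice")
  Phi <- encode_ssp(enc, g$points[keep, , drop = FALSE])
  rowSums(Phi) * g$cell
}

#' Fit the probability-readout normalisation constant
#'
#' The similarity kernel `phi(x) . phi(x0)` has mass `nu = integral of the
#' kernel` (about `length_scale^m` for the sinc limit), so the raw dot product
#' is first scaled by `1/nu` to make each kernel a unit-mass bump; the scalar
#' `xi` then corrects for the mass gained by clipping the kernel's negative
#' side lobes, chosen by bisection so that the rectified density of a single
#' point encoding integrates to one over the encoder's bounded domain (the
#' computable surrogate for the whole-space integral; the experiments live in
#' bounded arenas). `xi` comes out small and non-negative.
#'
#' @param enc an encoder.
#' @param resolution lattice points per axis (default 101 for m = 2; use a
#'   coarser lattice, e.g. 31, for m = 3).
#' @param tol target tolerance on the integral (default 1e-3).
#' @return An object of class `ssp_readout` holding `xi`, the kernel mass
#'   `nu`, the lattice and the precomputed encoding matrix of its points.
#' @export
fit_normalization <- function(enc, resolution = if (enc$m >= 3L) 31L else 101L,
                              tol = 1e-3) {
  g <- ssp_grid(enc, resolution)
  Phi <- encode_ssp(enc, g$points)             # d x n, reused by decode/density
  centre <- rowMeans(enc$domain_bounds)
  sims <- drop(crossprod(Phi, encode_ssp(enc, centre)))
  nu <- sum(sims) * g$cell                     # kernel mass on the lattice
  if (nu <= 0) stop("normalization failure: non-positive kernel mass")
  s <- sims / nu
  integral <- function(xi) sum(pmax(s - xi, 0)) * g$cell
  lo <- 0; hi <- max(s)
  if (integral(lo) < 1 || integral(hi) > 1)
    stop("normalization bisection bracket failure")
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (integral(mid) > 1) lo <- mid else hi <- mid
  }
  if (abs(integral((lo + hi) / 2) - 1) > tol)
    stop("normalization failed to reach the requested tolerance")
  structure(list(xi = (lo + hi) / 2, nu = nu, grid = g, Phi = Phi, enc = enc,
                 resolution = resolution),
            class = "ssp_readout")
}

#' Kernel-density probability readout
#'
#' `density_ssp(readout, M, x)` returns `max(phi(x) . M / nu - xi, 0)` with
#' `nu` the kernel mass and `xi` the rectification correction fitted by
#' [fit_normalization()]. When `M` is the mean of n point encodings this is a
#' sinc-kernel kernel-density estimate of the sample's distribution.
#'
#' @param readout an [fit_normalization()] result.
#' @param M memory/estimate vector of length `d`.
#' @param x a point (length m) or n x m matrix of points.
#' @param xi optional override of the readout's default correction, e.g. the
#'   result of [fit_xi()] for this particular `M`.
#' @export
density_ssp <- function(readout, M, x, xi = readout$xi) {
  enc <- readout$enc
  if (length(M) != enc$d) stop("encoder mismatch: M has wrong length")
  Phi <- encode_ssp(enc, if (is.matrix(x)) x else matrix(x, nrow = 1L))
  pmax(drop(crossprod(Phi, M)) / readout$nu - xi, 0)
}

#' Fit the rectification correction for a particular memory vector
#'
#' The correction scalar is defined relative to the estimate it rectifies:
#' `xi` is chosen so that the rectified field of `M` integrates to one over
#' the readout lattice. [fit_normalization()] stores the single-point value
#' as a default; use this for densities of sample means.
#'
#' @param readout a fitted readout; @param M vector of length `d`.
#' @export
fit_xi <- function(readout, M) {
  s <- drop(crossprod(readout$Phi, M)) / readout$nu
  cell <- readout$grid$cell
  f <- function(xi) sum(pmax(s - xi, 0)) * cell
  lo <- 0; hi <- max(s)
  if (f(lo) < 1) stop("normalization bisection bracket failure")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' MAP decode: the point whose rectified similarity to `v` is maximal
#'
#' Coarse lattice argmax refined by one quadratic-interpolation step per axis.
#' Invariant to positive rescaling of `v`. Ties break to the lowest lattice
#' index so decodes are deterministic.
#'
#' @param readout a fitted readout.
#' @param v vector of length `d`.
#' @return list `x` (decoded m-vector), `ok` (FALSE when the whole rectified
#'   field is zero, in which case the raw-similarity argmax is returned).
#' @export
map_decode <- function(readout, v) {
  if (all(v == 0)) stop("cannot decode the zero vector")
  g <- readout$grid
  vals <- drop(crossprod(readout$Phi, v))
  ok <- TRUE
  # rectified field empty: density zero everywhere for the normalised input
  if (max(vals) / readout$nu <= readout$xi * sqrt(sum(v^2))) ok <- FALSE
  best <- which.max(vals)                      # which.max takes first on ties
  res <- g$resolution
  m <- readout$enc$m
  idx <- arrayInd(best, rep(res, m))
  x <- numeric(m)
  for (k in seq_len(m)) {
    i <- idx[1L, k]
    x[k] <- g$axes[[k]][i]
    if (i > 1L && i < res) {
      # neighbours along axis k with other indices fixed
      stp <- res^(k - 1L)
      y0 <- vals[best - stp]; y1 <- vals[best]; y2 <- vals[best + stp]
      den <- y0 - 2 * y1 + y2
      if (den < 0) {
        off <- 0.5 * (y0 - y2) / den
        x[k] <- x[k] + max(-0.5, min(0.5, off)) * g$steps[k]
      }
    }
  }
  list(x = x, ok = ok)
}

#' Clean-up: project a vector onto the SSP manifold
#'
#' MAP decode followed by re-encoding; idempotent to lattice precision.
#'
#' @param readout a fitted readout.
#' @param v vector of length `d`.
#' @return list `ssp` (clean SSP), `x` (decoded point), `ok` (decode validity;
#'   when FALSE the raw input is passed through unchanged, flagged).
#' @export
cleanup_ssp <- function(readout, v) {
  dec <- map_decode(readout, v)
  if (!dec$ok)
    return(list(ssp = v, x = dec$x, ok = FALSE))
  list(ssp = encode_ssp(readout$enc, dec$x), x = dec$x, ok = TRUE)
}

#' Serialise an encoder to JSON
#' @param enc encoder; @param path file path.
#' @export
encoder_to_json <- function(enc, path) {
  jsonlite::write_json(
    list(d = enc$d, m = enc$m, seed = enc$seed, style = enc$style,
         length_scale = enc$length_scale,
         domain_bounds = enc$domain_bounds, A = enc$A),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an encoder back from JSON
#' @param path file written by [encoder_to_json()].
#' @export
encoder_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  enc <- ssp_encoder(x$d, x$m, x$length_scale, x$seed, x$style,
                     domain_bounds = x$domain_bounds)
  stopifnot(all(abs(enc$A - x$A) < 1e-12))  # reconstruction is deterministic
  enc
}
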