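# ---- Holographic reduced representation (HRR) algebra -----------------------
#
# Semantic pointers are plain numeric vectors; binding is circular convolution
# computed through the DFT, bundling is addition, and the approximate inverse
# is the index-reversal involution. The DFT convention throughout the package
# puts the 1/d factor on the inverse transform (R's fft convention), so a
# vector whose spectrum has unit modulus everywhere has unit Euclidean norm.

#' Create an empty vocabulary of semantic pointers
#'
#' A vocabulary owns the dimensionality and the random stream from which named
#' pointers are drawn, and guarantees name uniqueness.
#'
#' @param dimension pointer dimensionality `d` (>= 2).
#' @param seed integer seed for the vocabulary's private random stream.
#' @return An object of class `ssp_vocabulary`.
#' @export
vocabulary <- function(dimension, seed = 1L) {
  stopifnot(is.numeric(dimension), length(dimension) == 1L, dimension >= 2)
  v <- new.env(parent = emptyenv())
  v$dimension <- as.integer(dimension)
  v$seed <- as.integer(seed)
  v$symbols <- list()
  # private RNG state: draws are a deterministic function of (seed, draw count)
  v$draws <- 0L
  class(v) <- "ssp_vocabulary"
  v
}

#' @export
print.ssp_vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary d=%d, %d symbols: %s>\n", x$dimension,
              length(x$symbols), paste(names(x$symbols), collapse = ", ")))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw a random semantic pointer and register it in a vocabulary
#'
#' Non-unitary pointers are i.i.d. Gaussian, normalised to unit length.
#' Unitary pointers are built in the Fourier domain: i.i.d. uniform phases on
#' the upper half-spectrum, mirrored conjugate-symmetrically, so every DFT
#' coefficient has unit modulus and binding with the pointer preserves norms.
#'
#' @param vocab an [vocabulary()] object.
#' @param name symbol name, must be new to the vocabulary.
#' @param unitary draw a unitary pointer (default `TRUE`; discrete feature
#'   symbols are unitary by default so that map queries are norm-stable).
#' @return The new pointer (numeric vector of length `d`), invisibly also
#'   stored in `vocab`.
#' @export
random_pointer <- function(vocab, name, unitary = TRUE) {
  stopifnot(inherits(vocab, "ssp_vocabulary"))
  if (name %in% names(vocab$symbols))
    stop("name collision: '", name, "' already in vocabulary")
  d <- vocab$dimension
  vocab$draws <- vocab$draws + 1L
  p <- with_seed((vocab$seed %% 200000L) * 10007L + vocab$draws, {
    if (unitary) {
      unitary_pointer(d, runif(d %/% 2L, -pi, pi))
    } else {
      g <- rnorm(d)
      g / sqrt(sum(g^2))
    }
  })
  vocab$symbols[[name]] <- p
  p
}

# real d-vector whose DFT coefficients all have unit modulus; `phases` gives
# the free upper half-spectrum phases (length floor(d/2)). For even d the
# Nyquist coefficient must be real, so its phase is rounded to 0 or pi.
unitary_pointer <- function(d, phases) {
  h <- d %/% 2L
  stopifnot(length(phases) == h)
  spec <- complex(length.out = d)
  spec[1L] <- 1 + 0i
  spec[1L + seq_len(h)] <- exp(1i * phases)
  if (d %% 2L == 0L)  # Nyquist row self-conjugate: clamp to +/-1
    spec[h + 1L] <- if (Re(spec[h + 1L]) >= 0) 1 + 0i else -1 + 0i
  mir <- seq_len(ceiling(d / 2) - 1L)
  spec[d + 1L - mir] <- Conj(spec[1L + mir])
  Re(stats::fft(spec, inverse = TRUE)) / d
}

#' Retrieve a named pointer from a vocabulary
#' @param vocab a vocabulary.
#' @param name symbol name.
#' @export
vocab_get <- function(vocab, name) {
  p <- vocab$symbols[[name]]
  if (is.null(p)) stop("unknown symbol '", name, "'")
  p
}

#' Bind two semantic pointers (circular convolution)
#'
#' Computed in the Fourier domain as the Hadamard product of spectra;
#' commutative and associative to machine precision. On spatial semantic
#' pointers, binding adds the underlying variables.
#'
#' @param a,b numeric vectors of equal length.
#' @export
bind <- function(a, b) {
  if (length(a) != length(b)) stop("dimension mismatch in bind()")
  Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / length(a)
}

#' Bundle semantic pointers (element-wise sum)
#'
#' No renormalisation is applied: the raw sum is what the kernel-density
#' readout interprets as an (unnormalised) sum of kernels. Use [normalize_sp()]
#' when a unit vector is required.
#'
#' @param pointers a list of equal-length numeric vectors.
#' @export
bundle <- function(pointers) {
  if (!is.list(pointers) || length(pointers) == 0L)
    stop("bundle() needs a non-empty list of pointers")
  d <- length(pointers[[1L]])
  if (!all(vapply(pointers, length, 1L) == d))
    stop("dimension mismatch in bundle()")
  Reduce(`+`, pointers)
}

#' Normalise a vector to unit Euclidean length
#' @param v numeric vector; must have positive norm.
#' @export
normalize_sp <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize the zero vector")
  v / n
}

#' Approximate inverse (involution)
#'
#' Index reversal `[a_1, a_d, a_{d-1}, ..., a_2]`, equal to conjugating every
#' DFT coefficient. Exact inverse for unitary pointers; approximate otherwise.
#'
#' @param a numeric vector.
#' @export
sp_inverse <- function(a) {
  d <- length(a)
  if (d == 1L) return(a)
  c(a[1L], a[d:2L])
}

#' Similarity between semantic pointers
#'
#' @param a,b numeric vectors of equal length.
#' @param mode `"cosine"` (default) or `"dot"`.
#' @export
similarity <- function(a, b, mode = c("cosine", "dot")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("dimension mismatch in similarity()")
  s <- sum(a * b)
  if (mode == "dot") return(s)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  min(1, max(-1, s / (na * nb)))
}

#' Rank vocabulary symbols by similarity to a vector
#'
#' Dot-product cleanup over the whole vocabulary (or a subset of names).
#'
#' @param vocab a vocabulary.
#' @param v query vector.
#' @param names optional character vector restricting the candidates.
#' @param mode similarity mode passed to [similarity()].
#' @return named numeric vector of similarities, sorted decreasing.
#' @export
vocab_rank <- function(vocab, v, names = NULL, mode = "cosine") {
  syms <- vocab$symbols
  if (!is.null(names)) syms <- syms[names]
  s <- vapply(syms, function(p) similarity(p, v, mode), 0)
  sort(s, decreasing = TRUE)
}

#' Export a vocabulary to JSON
#' @param vocab a vocabulary.
#' @param path file path.
#' @export
vocab_to_json <- function(vocab, path) {
  jsonlite::write_json(
    list(dimension = vocab$dimension, seed = vocab$seed,
         symbols = vocab$symbols),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a vocabulary from JSON
#' @param path file path written by [vocab_to_json()].
#' @export
vocab_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- vocabulary(x$dimension, x$seed)
  for (nm in names(x$symbols)) v$symbols[[nm]] <- as.numeric(x$symbols[[nm]])
  v$draws <- length(v$symbols)
  v
}
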