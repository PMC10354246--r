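# ---- Minimal Neural Engineering Framework runtime ---------------------------
#
# Populations of LIF neurons encode vectors through gain/bias/encoder tuning
# (a_i = G[alpha_i e_i.x + beta_i]); vectors are decoded by ridge-regressed
# linear decoders; connections filter through a first-order synapse; dynamical
# systems are embedded via the tau*f(x)+x transform; PES and Voja adapt
# decoders and encoders online. Three fidelity tiers share the same
# semantics: "ideal" (no neurons), "rate", and "spiking".

#' LIF neuron parameters
#'
#' @param tau_rc membrane time constant (s).
#' @param tau_ref absolute refractory period (s).
#' @param max_rate_range firing-rate interval (Hz) sampled for per-neuron
#'   maximum rates (default 200-400 Hz).
#' @param active_proportion target fraction of neurons active for a random
#'   representative input (default 0.1); sets the intercept distribution.
#' @export
lif_params <- function(tau_rc = 0.02, tau_ref = 0.002,
                       max_rate_range = c(200, 400),
                       active_proportion = 0.1) {
  stopifnot(tau_rc > 0, tau_ref > 0, all(max_rate_range > 0),
            active_proportion > 0, active_proportion < 1)
  structure(list(tau_rc = tau_rc, tau_ref = tau_ref,
                 max_rate_range = max_rate_range,
                 active_proportion = active_proportion),
            class = "lif_params")
}

#' Steady-state LIF firing rate for a normalised input current
#'
#' Zero at or below the normalised threshold J = 1, otherwise
#' `1 / (tau_ref + tau_rc * log(1 + 1/(J-1)))`; continuous and non-decreasing.
#'
#' @param p [lif_params()].
#' @param J input current (scalar, vector or matrix).
#' @export
lif_rate <- function(p, J) {
  r <- J
  above <- J > 1 + 1e-12
  r[!above] <- 0
  jj <- J[above]
  r[above] <- 1 / (p$tau_ref + p$tau_rc * log1p(1 / (jj - 1)))
  r
}

#' Build a neuron population
#'
#' Gains and biases are solved per neuron so that firing starts at the
#' sampled intercept (along the encoder) and reaches the sampled maximum rate
#' at `e.x = 1`. Intercepts are the `(1 - active_proportion)` quantiles of
#' `e_i.x` over representative inputs, so about that fraction of neurons fire
#' for a random input.
#'
#' @param n neuron count.
#' @param dim represented dimensionality.
#' @param lif [lif_params()].
#' @param seed integer seed.
#' @param encoder_style `"uniform-sphere"` (random unit vectors),
#'   `"ssp-points"` (encoders are SSPs of random points in the arena:
#'   place-cell-like tuning; requires `enc`), `"grid-module"` (SSP encoders
#'   restricted to a single hexagonal frequency module: grid-cell tuning) or
#'   `"provided"` (pass `encoders`).
#' @param enc optional [ssp_encoder()] for the ssp styles.
#' @param encoders optional n x dim matrix for style "provided".
#' @param radius representational radius: inputs are scaled by 1/radius before
#'   encoding (default 1).
#' @param eval_sample number of representative inputs used to place intercepts.
#' @param active_proportion override the style default for the fraction of
#'   neurons active per input: `NULL` (default) means `lif$active_proportion`
#'   for the sparse ssp styles and spread intercepts for the others; a number
#'   forces that fixed proportion for any style.
#' @param rep_inputs optional matrix of representative inputs used for
#'   intercept placement instead of the style default (e.g. unit-norm keys
#'   for an associative memory).
#' @return object of class `nef_population`.
#' @export
nef_population <- function(n, dim, lif = lif_params(), seed = 1L,
                           encoder_style = c("uniform-sphere", "ssp-points",
                                             "grid-module", "provided"),
                           enc = NULL, encoders = NULL, radius = 1,
                           eval_sample = 500L, active_proportion = NULL,
                           rep_inputs = NULL) {
  encoder_style <- match.arg(encoder_style)
  stopifnot(n >= 1L)
  with_seed(seed, {
    E <- switch(encoder_style,
      "uniform-sphere" = {
        g <- matrix(stats::rnorm(n * dim), n, dim)
        g / sqrt(rowSums(g^2))
      },
      "ssp-points" = {
        stopifnot(!is.null(enc), enc$d == dim)
        pts <- sample_domain(enc, n)
        t(encode_ssp(enc, pts))
      },
      "grid-module" = {
        stopifnot(!is.null(enc), enc$style == "hexagonal", enc$d == dim)
        pts <- sample_domain(enc, n)
        Phi <- t(encode_ssp(enc, pts))         # n x d
        # keep only the Fourier components of one frequency module per neuron
        mods <- sample(unique(enc$module), n, replace = TRUE)
        t(vapply(seq_len(n), function(i) {
          keep <- which(enc$module == mods[i])
          spec <- stats::fft(Phi[i, ])
          mask <- complex(length.out = enc$d)
          mask[1L + keep] <- spec[1L + keep]
          mask[enc$d + 1L - keep] <- spec[enc$d + 1L - keep]
          v <- Re(stats::fft(mask, inverse = TRUE)) / enc$d
          v / sqrt(sum(v^2))
        }, numeric(dim)))
      },
      "provided" = {
        stopifnot(!is.null(encoders), nrow(encoders) == n,
                  ncol(encoders) == dim)
        encoders / sqrt(rowSums(encoders^2))
      })
    # representative inputs for intercept placement
    X <- if (!is.null(rep_inputs)) rep_inputs
    else if (encoder_style %in% c("uniform-sphere", "provided")) {
      g <- matrix(stats::rnorm(eval_sample * dim), eval_sample, dim)
      g <- g / sqrt(rowSums(g^2))
      g * stats::runif(eval_sample)^(1 / dim)     # uniform in the unit ball
    } else t(encode_ssp(enc, sample_domain(enc, eval_sample)))
    proj <- E %*% t(X) / radius                  # n x eval_sample
    # Sparse spatial populations (ssp encoders) place every intercept at the
    # (1 - active_proportion) quantile of the neuron's own drive, so about
    # that fraction of neurons fires for a random location. Low-dimensional
    # utility populations need heterogeneous intercepts spread over the
    # represented range or mid-range inputs fall in a dead zone; for those,
    # per-neuron quantile levels are drawn uniformly (mean activity ~ 0.5).
    probs <- if (!is.null(active_proportion))
      rep(1 - active_proportion, n)
    else if (encoder_style %in% c("ssp-points", "grid-module"))
      rep(1 - lif$active_proportion, n)
    else stats::runif(n, 0.05, 0.95)
    intercepts <- vapply(seq_len(n), function(i)
      stats::quantile(proj[i, ], probs = probs[i], names = FALSE), 0)
    intercepts <- pmin(intercepts, 0.95)
    max_rates <- stats::runif(n, lif$max_rate_range[1L], lif$max_rate_range[2L])
    # invert the rate function at e.x = 1 to get the current giving max_rate
    Jmax <- 1 + 1 / (exp((1 / max_rates - lif$tau_ref) / lif$tau_rc) - 1)
    gains <- (Jmax - 1) / (1 - intercepts)
    if (any(!is.finite(gains)) || any(gains <= 0))
      stop("unsatisfiable rate/intercept combination")
    biases <- 1 - gains * intercepts
    structure(list(n = as.integer(n), dim = as.integer(dim), encoders = E,
                   gains = gains, biases = biases, intercepts = intercepts,
                   max_rates = max_rates, lif = lif, radius = radius,
                   seed = as.integer(seed), encoder_style = encoder_style),
              class = "nef_population")
  })
}

# uniform sample over the encoder's rectangular domain
sample_domain <- function(enc, n) {
  m <- enc$m
  pts <- matrix(stats::runif(n * m), n, m)
  lo <- enc$domain_bounds[, 1L]; hi <- enc$domain_bounds[, 2L]
  sweep(sweep(pts, 2L, hi - lo, `*`), 2L, lo, `+`)
}

#' @export
print.nef_population <- function(x, ...) {
  cat(sprintf("<nef_population n=%d dim=%d encoders=%s>\n",
              x$n, x$dim, x$encoder_style))
  invisible(x)
}

#' Rate-mode activities of a population
#'
#' @param pop a population.
#' @param value represented vector (length `dim`) or matrix (rows = inputs).
#' @return rates in Hz: length-n vector, or n x n_inputs matrix.
#' @export
nef_rates <- function(pop, value) {
  if (is.matrix(value)) {
    if (ncol(value) != pop$dim) stop("dimension mismatch")
    J <- pop$gains * (pop$encoders %*% t(value) / pop$radius) + pop$biases
  } else {
    if (length(value) != pop$dim) stop("dimension mismatch")
    J <- pop$gains * drop(pop$encoders %*% value) / pop$radius + pop$biases
  }
  lif_rate(pop$lif, J)
}

#' Initialise spiking-neuron state for a population
#'
#' Membrane voltages start uniform in [0, 1): neurons with similar drive
#' would otherwise spike in lockstep and their noise would not average out
#' across the population.
#'
#' @param pop a population.
#' @param seed seed for the initial voltages (default: the population's).
#' @export
spiking_state <- function(pop, seed = pop$seed + 999L) {
  list(v = with_seed(seed, stats::runif(pop$n)), refractory = numeric(pop$n))
}

#' One spiking step
#'
#' Zero-order-hold membrane update with refractory clamping; emitted spikes
#' are scaled by 1/dt so their filtered average matches rates in Hz.
#'
#' @param pop population; @param st state from [spiking_state()];
#' @param value represented input vector; @param dt timestep (s).
#' @return list `spikes` (n-vector, 0 or 1/dt) and updated `state`.
#' @export
spiking_step <- function(pop, st, value, dt) {
  J <- pop$gains * drop(pop$encoders %*% value) / pop$radius + pop$biases
  tau_rc <- pop$lif$tau_rc
  # exact zero-order-hold update over the non-refractory part of the step
  st$refractory <- st$refractory - dt
  delta_t <- pmax(0, pmin(dt, dt - st$refractory))
  v <- st$v + (J - st$v) * -expm1(-delta_t / tau_rc)
  spiked <- v > 1
  spikes <- numeric(pop$n)
  spikes[spiked] <- 1 / dt
  if (any(spiked)) {
    # time left in the step after the threshold crossing
    t_over <- dt + tau_rc * log1p(-(v[spiked] - 1) / (J[spiked] - 1))
    st$refractory[spiked] <- pop$lif$tau_ref + t_over
  }
  v[spiked] <- 0
  v[v < 0] <- 0
  st$v <- v
  list(spikes = spikes, state = st)
}

#' Solve ridge-regressed decoders
#'
#' Least squares on the rate-mode activity matrix with L2 regularisation
#' `sigma = reg * max(activities)` added as `n_points * sigma^2` on the Gram
#' diagonal (the de-facto standard).
#'
#' @param pop population.
#' @param eval_points n_points x dim matrix of inputs.
#' @param targets n_points x dim_out matrix (or vector) of desired outputs.
#' @param reg relative regularisation (default 0.1).
#' @return n x dim_out decoder matrix.
#' @export
solve_decoders <- function(pop, eval_points, targets, reg = 0.1) {
  if (!is.matrix(targets)) targets <- matrix(targets, ncol = 1L)
  stopifnot(nrow(eval_points) == nrow(targets),
            nrow(eval_points) >= ncol(targets))
  Act <- t(nef_rates(pop, eval_points))        # n_points x n
  sigma <- reg * max(Act)
  G <- crossprod(Act) + diag(nrow(eval_points) * sigma^2, pop$n)
  U <- crossprod(Act, targets)
  D <- tryCatch(solve(G, U), error = function(e) {
    warning("rank-deficient activity matrix; minimum-norm solution used")
    MASS_ginv(G) %*% U
  })
  D
}

# small local pseudo-inverse (avoids a MASS dependency)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1L], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' First-order synapse state
#' @param dims number of filtered dimensions; @param tau time constant (s).
#' @export
synapse <- function(dims, tau = 0.05) {
  list(y = numeric(dims), tau = tau)
}

#' One exponential-filter step
#'
#' `y <- y * exp(-dt/tau) + (1 - exp(-dt/tau)) * input`; the steady state for
#' constant input equals the input.
#'
#' @param s synapse state; @param input vector; @param dt timestep (s).
#' @return updated synapse state (field `y` holds the filtered value).
#' @export
synapse_step <- function(s, input, dt) {
  a <- exp(-dt / s$tau)
  s$y <- s$y * a + (1 - a) * input
  s
}

#' Dynamics-principle transform
#'
#' To realise `xdot = f(x) + g(u)` through a first-order synapse with time
#' constant `tau`, the recurrent connection must compute `tau*f(x) + x` and
#' the input connection `tau*g(u)`.
#'
#' @param f,g functions on the represented space (`NULL` means zero).
#' @param tau synaptic time constant (s).
#' @return list of functions `recurrent(x)` and `input(u)`.
#' @export
dynamics_transform <- function(f = NULL, g = NULL, tau = 0.05) {
  list(
    recurrent = function(x) if (is.null(f)) x else tau * f(x) + x,
    input = function(u) if (is.null(g)) 0 * u else tau * g(u)
  )
}

#' PES decoder update
#'
#' `delta d_i = kappa * dt * scaled(a_i) * error`, with
#' `error = target - estimate` the signal to be minimised; equivalent to the
#' full-weight form under the encoder-decoder factorisation. Activities are
#' scaled by `a_ref / sum(a^2)` so the decoded estimate converges toward the
#' target at rate `kappa * a_ref` per second regardless of population size or
#' firing-rate distribution (an activity-normalised PES; the raw form's
#' effective rate would vary by orders of magnitude with sparsity).
#'
#' @param decoders n x dim_out matrix.
#' @param error length dim_out vector (target minus current estimate).
#' @param activities length n rates (Hz).
#' @param dt timestep (s).
#' @param kappa learning rate (default 1e-2).
#' @param a_ref reference rate (Hz, default 400: the top of the default
#'   max-rate range).
#' @return updated decoders.
#' @export
pes_update <- function(decoders, error, activities, dt, kappa = 1e-2,
                       a_ref = 400) {
  ss <- sum(activities^2)
  if (ss == 0) return(decoders)
  decoders + (kappa * dt * a_ref / ss) * outer(activities, error)
}

#' Voja encoder update
#'
#' `delta e_i = kappa * a_i * (x - e_i)` followed by renormalisation: only
#' active neurons move, and the moving neuron's encoder converges to the
#' input, sparsifying responses.
#'
#' @param encoders n x dim matrix (unit rows).
#' @param activities length n rates (Hz).
#' @param input_value represented vector (normalised internally).
#' @param dt timestep (s).
#' @param kappa learning rate (default 5e-3).
#' @return updated (renormalised) encoders.
#' @export
voja_update <- function(encoders, activities, input_value, dt, kappa = 5e-3) {
  nv <- sqrt(sum(input_value^2))
  if (nv > 0) input_value <- input_value / nv
  step <- kappa * dt * activities
  act <- which(step > 0)
  if (length(act) == 0L) return(encoders)      # inactive rows stay bit-exact
  E <- encoders
  moved <- E[act, , drop = FALSE] +
    step[act] * (matrix(input_value, length(act), ncol(E), byrow = TRUE) -
                   E[act, , drop = FALSE])
  E[act, ] <- moved / sqrt(rowSums(moved^2))
  E
}

#' Dense weight matrix of a factored connection
#'
#' `w_ij = alpha_j * e_j . d_i`: the outer-product factorisation relating
#' decoders of the source and encoders of the target.
#'
#' @param post target population; @param decoders n_pre x dim decoders.
#' @return n_pre x n_post weight matrix.
#' @export
connection_weights <- function(post, decoders) {
  decoders %*% t(post$gains * post$encoders)
}
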