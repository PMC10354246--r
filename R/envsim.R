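# ---- Synthetic environments and trajectories --------------------------------

#' Generate a band-limited random trajectory
#'
#' Per-axis Gaussian white noise is low-pass filtered at `cutoff` in the
#' frequency domain, rescaled so the path stays inside `0.95 * radius`, and
#' differentiated by forward differences (last value repeated). Deterministic
#' per seed.
#'
#' @param seed integer seed.
#' @param duration run length (s); the reference experiments use 120 s paths.
#' @param dt timestep (s, default 1e-3).
#' @param cutoff low-pass cutoff (Hz, default 0.2: the paths cross the arena a
#'   few times in two minutes, as in the reference figures).
#' @param radius arena radius (default 1).
#' @param m spatial dimensionality (2 or 3).
#' @return object of class `ssp_trajectory`: `times`, `positions` (n x m),
#'   `velocities` (n x m), `dt`.
#' @export
generate_trajectory <- function(seed, duration = 120, dt = 1e-3,
                                cutoff = 0.2, radius = 1, m = 2L) {
  n <- round(duration / dt)
  if (n < 10L) stop("duration/dt must be >= 10")
  if (cutoff >= 1 / (2 * dt)) stop("cutoff must be below the Nyquist frequency")
  pos <- with_seed(seed, {
    # integer harmonic mask, exactly conjugate-symmetric
    kk <- c(0L, seq_len(n - 1L))
    harm <- pmin(kk, n - kk)
    keep <- harm <= floor(cutoff * n * dt + 1e-9)
    sapply(seq_len(m), function(k) {
      w <- stats::rnorm(n)
      W <- stats::fft(w)
      W[!keep] <- 0
      Re(stats::fft(W, inverse = TRUE)) / n
    })
  })
  pos <- sweep(pos, 2L, colMeans(pos))
  r <- sqrt(rowSums(pos^2))
  if (max(r) == 0)
    stop("config error: duration too short for the cutoff (no harmonics kept)")
  pos <- pos * (0.95 * radius / max(r))
  vel <- rbind(diff(pos) / dt, matrix(0, 1L, m))
  vel[n, ] <- vel[n - 1L, ]
  structure(list(times = (seq_len(n) - 1L) * dt, positions = pos,
                 velocities = vel, dt = dt, radius = radius, m = m),
            class = "ssp_trajectory")
}

#' Write / read a trajectory as CSV (t, x, y[, z], vx, vy[, vz])
#' @param traj trajectory; @param path file path.
#' @export
trajectory_to_csv <- function(traj, path) {
  m <- traj$m
  df <- data.frame(t = traj$times)
  ax <- c("x", "y", "z")[seq_len(m)]
  for (k in seq_len(m)) df[[ax[k]]] <- traj$positions[, k]
  for (k in seq_len(m)) df[[paste0("v", ax[k])]] <- traj$velocities[, k]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trajectory_to_csv
#' @export
trajectory_from_csv <- function(path) {
  df <- utils::read.csv(path)
  ax <- intersect(c("x", "y", "z"), names(df))
  m <- length(ax)
  pos <- as.matrix(df[, ax])
  vel <- as.matrix(df[, paste0("v", ax)])
  dimnames(pos) <- dimnames(vel) <- NULL
  structure(list(times = df$t, positions = pos, velocities = vel,
                 dt = df$t[2L] - df$t[1L], radius = max(sqrt(rowSums(pos^2))),
                 m = m),
            class = "ssp_trajectory")
}

#' Generate a random environment
#'
#' Uniform landmark positions inside the arena; each landmark's feature
#' pointer is the binding of a colour and a shape symbol drawn from the
#' vocabulary (symbols are created on demand as COLOR1..., SHAPE1...).
#'
#' @param seed integer seed.
#' @param n_landmarks landmark count (the reference protocol uses 10).
#' @param m spatial dimensionality.
#' @param vocab a [vocabulary()]; composed feature pointers are registered in
#'   it under names like `"COLOR1*SHAPE2"`.
#' @param radius arena radius.
#' @return object of class `ssp_environment`: `landmarks` is a list of
#'   `list(name, position, pointer)`; `regions` a list of
#'   `list(name, indicator, pointer_name)`.
#' @export
make_environment <- function(seed, n_landmarks, m = 2L, vocab, radius = 1) {
  stopifnot(n_landmarks >= 0L)
  n_base <- max(2L, ceiling(sqrt(n_landmarks)))
  for (i in seq_len(n_base)) {
    for (pfx in c("COLOR", "SHAPE")) {
      nm <- paste0(pfx, i)
      if (!nm %in% names(vocab$symbols)) random_pointer(vocab, nm)
    }
  }
  pos <- with_seed(seed, {
    p <- matrix(0, n_landmarks, m)
    for (i in seq_len(n_landmarks)) {
      repeat {
        cand <- stats::runif(m, -radius, radius)
        if (sum(cand^2) <= radius^2) break
      }
      p[i, ] <- cand
    }
    p
  })
  combos <- with_seed(seed + 1L, {
    cc <- expand.grid(color = seq_len(n_base), shape = seq_len(n_base))
    cc[sample(nrow(cc), n_landmarks), , drop = FALSE]
  })
  landmarks <- lapply(seq_len(n_landmarks), function(i) {
    cn <- paste0("COLOR", combos$color[i]); sn <- paste0("SHAPE", combos$shape[i])
    nm <- paste0(cn, "*", sn)
    if (!nm %in% names(vocab$symbols))
      vocab$symbols[[nm]] <- bind(vocab_get(vocab, cn), vocab_get(vocab, sn))
    list(name = nm, position = pos[i, ], pointer = vocab$symbols[[nm]])
  })
  structure(list(m = m, radius = radius, landmarks = landmarks,
                 regions = list(), vocab = vocab, seed = as.integer(seed)),
            class = "ssp_environment")
}

#' The worked-example environment (three landmarks and a wall)
#'
#' A fixed planar arena: a blue square at (0.6, 0.2), a blue triangle at
#' (0.0, -0.6), an orange triangle at (-0.2, 0.2), and an L-shaped wall made
#' of the rectangles `[0.5, 1.1] x [-1.1, -0.95]` and `[0.95, 1.1] x [-1, -0.4]`.
#'
#' @param vocab a vocabulary; symbols BLUE, ORANGE, SQUARE, TRIANGLE, WALL are
#'   created if absent, and composed names (e.g. `"BLUE*SQUARE"`) registered.
#' @export
fig_environment <- function(vocab) {
  for (nm in c("BLUE", "ORANGE", "SQUARE", "TRIANGLE", "WALL"))
    if (!nm %in% names(vocab$symbols)) random_pointer(vocab, nm)
  mk <- function(a, b, x) {
    nm <- paste0(a, "*", b)
    if (!nm %in% names(vocab$symbols))
      vocab$symbols[[nm]] <- bind(vocab_get(vocab, a), vocab_get(vocab, b))
    list(name = nm, position = x, pointer = vocab$symbols[[nm]])
  }
  landmarks <- list(mk("BLUE", "SQUARE", c(0.6, 0.2)),
                    mk("BLUE", "TRIANGLE", c(0.0, -0.6)),
                    mk("ORANGE", "TRIANGLE", c(-0.2, 0.2)))
  wall_ind <- function(pts) {
    (pts[, 1L] >= 0.5 & pts[, 1L] <= 1.1 &
       pts[, 2L] >= -1.1 & pts[, 2L] <= -0.95) |
      (pts[, 1L] >= 0.95 & pts[, 1L] <= 1.1 &
         pts[, 2L] >= -1 & pts[, 2L] <= -0.4)
  }
  regions <- list(list(name = "WALL", indicator = wall_ind,
                       pointer = vocab_get(vocab, "WALL")))
  structure(list(m = 2L, radius = 1, landmarks = landmarks,
                 regions = regions, vocab = vocab, seed = NA_integer_),
            class = "ssp_environment")
}

#' Environment export/import as JSON
#' @param env environment; @param path file path.
#' @export
environment_to_json <- function(env, path) {
  jsonlite::write_json(
    list(m = env$m, radius = env$radius,
         landmarks = lapply(env$landmarks, function(l)
           list(name = l$name, position = l$position))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pass a velocity signal through a spiking neural channel
#'
#' Encodes the trajectory's velocities in a spiking population and decodes
#' them back through the synaptic filter, yielding the realistically noisy
#' velocity input the path integrator receives in the reference experiments.
#'
#' @param traj a trajectory.
#' @param pop_size neurons in the channel (default 500).
#' @param lif LIF parameters.
#' @param seed integer seed.
#' @param tau_syn synaptic filter time constant (s).
#' @param mode `"spiking"` (default) or `"rate"` (deterministic distortion
#'   only).
#' @return n x m matrix of decoded velocities on the trajectory's time base.
#' @export
noisy_velocity_channel <- function(traj, pop_size = 500L, lif = lif_params(),
                                   seed = 1L, tau_syn = 0.05,
                                   mode = c("spiking", "rate")) {
  mode <- match.arg(mode)
  stopifnot(pop_size >= 10L)
  m <- traj$m
  vmax <- max(sqrt(rowSums(traj$velocities^2)))
  rad <- max(vmax * 1.2, 1e-6)
  pop <- nef_population(pop_size, m, lif = lif, seed = seed,
                        encoder_style = "uniform-sphere", radius = rad)
  D <- with_seed(seed + 1L, {
    g <- matrix(stats::rnorm(1000L * m), 1000L, m)
    g <- g / sqrt(rowSums(g^2)) * stats::runif(1000L)^(1 / m)
    pts <- g * rad
    solve_decoders(pop, pts, pts)
  })
  n <- length(traj$times)
  if (mode == "rate") {
    rates <- nef_rates(pop, traj$velocities)   # n_neurons x n
    dec <- crossprod(rates, D)                 # n x m
  } else {
    st <- spiking_state(pop)
    dec <- matrix(0, n, m)
    dt <- traj$dt
    a <- exp(-dt / tau_syn)
    filt <- numeric(pop_size)
    # warm the filter up on the initial velocity (the channel was running
    # before the path started); removes an artificial onset transient
    for (i in seq_len(round(5 * tau_syn / dt))) {
      sp <- spiking_step(pop, st, traj$velocities[1L, ], dt)
      st <- sp$state
      filt <- filt * a + (1 - a) * sp$spikes
    }
    for (i in seq_len(n)) {
      sp <- spiking_step(pop, st, traj$velocities[i, ], dt)
      st <- sp$state
      filt <- filt * a + (1 - a) * sp$spikes
      dec[i, ] <- drop(crossprod(D, filt))
    }
  }
  dec
}
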