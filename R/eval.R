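# ---- Metrics, experiments, firing-map analysis ------------------------------

#' Similarity error between a true SSP and an estimate
#'
#' `1 - phi(x(t)) . phi_hat(x(t))`: zero for a perfect estimate, one for an
#' orthogonal one.
#'
#' @param true_ssp,estimate d-vectors.
#' @export
similarity_error <- function(true_ssp, estimate) {
  if (length(true_ssp) != length(estimate)) stop("dimension mismatch")
  1 - sum(true_ssp * estimate)
}

#' Absolute trajectory error
#'
#' Mean over timesteps of the Euclidean distance between the MAP estimate and
#' ground truth.
#'
#' @param truth,estimates n x m matrices on the same time base.
#' @export
ate <- function(truth, estimates) {
  stopifnot(nrow(truth) >= 1L, all(dim(truth) == dim(estimates)))
  mean(sqrt(rowSums((truth - estimates)^2)))
}

#' Time-integrated trajectory error
#'
#' `sum_t ||x_hat(t) - x(t)|| * dt`: the time integral of the per-timestep
#' Euclidean error; equals `ate * duration` for uniform errors.
#'
#' @param truth,estimates n x m matrices; @param dt uniform step between the
#'   rows (s).
#' @export
integrated_error <- function(truth, estimates, dt) {
  sum(sqrt(rowSums((truth - estimates)^2))) * dt
}

#' Convenience metrics for a [run_slam()] result
#' @param result a `slam_result`.
#' @return list `ate`, `integrated_error`, `mean_sim_error`.
#' @export
slam_metrics <- function(result) {
  dt_dec <- result$dt * result$decode_every
  list(ate = ate(result$truth, result$estimates),
       integrated_error = integrated_error(result$truth, result$estimates,
                                           dt_dec),
       mean_sim_error = mean(result$sim_error))
}

#' Run the localization benchmark (SLAM vs dead reckoning)
#'
#' For each seed: generate an environment (10 landmarks by default) and a
#' band-limited path, pass the velocity through the spiking channel, then run
#' the full model and the path-integrator-only model on identical inputs,
#' recording ATE and integrated error for both.
#'
#' @param n_seeds number of environment/path seeds.
#' @param duration path length (s; the reference protocol uses 120 s, the
#'   reduced-scale profile 60 s).
#' @param scale factor in (0, 1] multiplying neuron counts.
#' @param d SSP dimensionality (default 181).
#' @param m spatial dimensionality.
#' @param dt timestep (s).
#' @param n_landmarks landmarks per environment.
#' @param seed0 base seed; run i uses seed0 + i.
#' @param tier path-integrator tier.
#' @param length_scale encoder length scale.
#' @param decode_every steps between MAP decodes.
#' @param channel_neurons velocity-channel population size before scaling.
#' @param verbose print per-seed progress.
#' @return data frame with one row per seed: ATE and integrated error for the
#'   full model and for dead reckoning.
#' @export
run_localization_experiment <- function(n_seeds = 3L, duration = 60,
                                        scale = 0.25, d = 181L, m = 2L,
                                        dt = 1e-3, n_landmarks = 10L,
                                        seed0 = 0L, tier = "ideal",
                                        length_scale = 0.15,
                                        decode_every = 50L,
                                        channel_neurons = 500L,
                                        verbose = FALSE) {
  stopifnot(scale > 0, scale <= 1)
  enc <- ssp_encoder(d, m, length_scale = length_scale, seed = seed0 + 1L)
  readout <- fit_normalization(enc)
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    s <- seed0 + i
    ok <- tryCatch({
      vocab <- vocabulary(enc$d, seed = s)
      env <- make_environment(s, n_landmarks, m = m, vocab = vocab)
      traj <- generate_trajectory(s + 1000L, duration = duration, dt = dt,
                                  m = m)
      vel <- noisy_velocity_channel(traj, pop_size = max(50L, round(
        channel_neurons * scale)), seed = s + 2000L)
      res_slam <- run_slam(enc, env, traj, readout = readout,
                           velocities = vel, tier = tier,
                           n_am_neurons = max(50L, round(1000L * scale)),
                           decode_every = decode_every, seed = s,
                           n_neurons_per_vco = max(20L, round(500L * scale)))
      res_pi <- run_slam(enc, NULL, traj, readout = readout,
                         velocities = vel, tier = tier,
                         decode_every = decode_every, seed = s,
                         n_neurons_per_vco = max(20L, round(500L * scale)))
      ms <- slam_metrics(res_slam); mp <- slam_metrics(res_pi)
      rows[[i]] <- data.frame(seed = s, ate_slam = ms$ate, ate_pi = mp$ate,
                              int_slam = ms$integrated_error,
                              int_pi = mp$integrated_error)
      TRUE
    }, error = function(e) {
      message("seed ", s, " failed: ", conditionMessage(e))
      FALSE
    })
    if (verbose && ok) print(rows[[i]])
  }
  do.call(rbind, rows)
}

#' Occupancy-normalised firing map
#'
#' Bins activity (spike counts or rates) by the agent's binned position and
#' divides by occupancy time; bins never visited are NA.
#'
#' @param activity numeric vector, one value per sample (rate in Hz or spike
#'   indicator scaled by 1/dt).
#' @param positions n x 2 matrix of the agent's positions at the samples.
#' @param bins bins per axis (default 32).
#' @param bounds 2 x 2 matrix of axis bounds (defaults to data range).
#' @return list `map` (bins x bins mean activity), `occupancy`, `breaks_x`,
#'   `breaks_y`.
#' @export
firing_map <- function(activity, positions, bins = 32L, bounds = NULL) {
  stopifnot(length(activity) == nrow(positions), ncol(positions) == 2L)
  if (is.null(bounds))
    bounds <- rbind(range(positions[, 1L]), range(positions[, 2L]))
  bx <- seq(bounds[1L, 1L], bounds[1L, 2L], length.out = bins + 1L)
  by <- seq(bounds[2L, 1L], bounds[2L, 2L], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(positions[, 1L], bx, all.inside = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(positions[, 2L], by, all.inside = TRUE), 1L), bins)
  idx <- (iy - 1L) * bins + ix
  occ <- tabulate(idx, nbins = bins * bins)
  tot <- numeric(bins * bins)
  agg <- tapply(activity, idx, sum)
  tot[as.integer(names(agg))] <- agg
  mp <- tot / occ
  mp[occ == 0L] <- NA_real_
  list(map = matrix(mp, bins, bins), occupancy = matrix(occ, bins, bins),
       breaks_x = bx, breaks_y = by)
}

#' Count distinct firing fields in a rate map
#'
#' Thresholds the map at `frac` of its maximum and counts connected
#' components (4-neighbour flood fill), ignoring components smaller than
#' `min_cells`. A grid-cell-like map shows three or more regularly spaced
#' fields.
#'
#' @param map matrix from [firing_map()].
#' @param frac threshold fraction of the maximum (default 0.5).
#' @param min_cells minimum component size (default 2).
#' @export
count_fields <- function(map, frac = 0.5, min_cells = 2L) {
  m <- map
  m[is.na(m)] <- 0
  thr <- frac * max(m)
  lab <- matrix(0L, nrow(m), ncol(m))
  mask <- m > thr & thr > 0
  nf <- 0L
  for (start in which(mask & lab == 0L)) {
    nf <- nf + 1L
    stack <- start
    sz <- 0L
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- nf; sz <- sz + 1L
      r <- (p - 1L) %% nrow(m) + 1L; cc <- (p - 1L) %/% nrow(m) + 1L
      if (r > 1L) stack <- c(stack, p - 1L)
      if (r < nrow(m)) stack <- c(stack, p + 1L)
      if (cc > 1L) stack <- c(stack, p - nrow(m))
      if (cc < ncol(m)) stack <- c(stack, p + nrow(m))
    }
    if (sz < min_cells) {
      lab[lab == nf] <- -1L  # too small: mark visited, don't count
      nf <- nf - 1L
    }
  }
  nf
}

#' Heading-direction histogram of activity
#'
#' Bins activity by the heading angle of the velocity (16 sectors of 22.5
#' degrees by default) and reports the mean activity per sector plus the
#' circular concentration (resultant length) of the activity-weighted heading
#' distribution.
#'
#' @param activity per-sample activity.
#' @param velocities n x 2 matrix.
#' @param n_bins number of heading sectors.
#' @return list `counts` (summed activity per sector), `centers` (rad),
#'   `concentration` in [0, 1].
#' @export
heading_histogram <- function(activity, velocities, n_bins = 16L) {
  ang <- atan2(velocities[, 2L], velocities[, 1L]) %% (2 * pi)
  sec <- pmin(floor(ang / (2 * pi / n_bins)) + 1L, n_bins)
  counts <- numeric(n_bins)
  agg <- tapply(activity, sec, sum)
  counts[as.integer(names(agg))] <- agg
  w <- sum(activity)
  conc <- if (w > 0)
    sqrt(sum(activity * cos(ang))^2 + sum(activity * sin(ang))^2) / w else 0
  list(counts = counts,
       centers = (seq_len(n_bins) - 0.5) * 2 * pi / n_bins,
       concentration = conc)
}
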