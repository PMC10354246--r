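# ---- Landmark perception, associative environment map, loop closure ---------

#' Landmarks within the agent's field of view
#'
#' Ground-truth egocentric input: every landmark within `view_radius`
#' (closed ball) is returned with its exact displacement.
#'
#' @param env an `ssp_environment`.
#' @param x agent position (length m).
#' @param view_radius visibility radius (reference value: 0.3 x arena radius).
#' @return list of observations `list(index, name, pointer, displacement)`.
#' @export
observe <- function(env, x, view_radius = 0.3 * env$radius) {
  out <- list()
  for (i in seq_along(env$landmarks)) {
    l <- env$landmarks[[i]]
    disp <- l$position - x
    if (sqrt(sum(disp^2)) <= view_radius)
      out[[length(out) + 1L]] <- list(index = i, name = l$name,
                                      pointer = l$pointer,
                                      displacement = disp)
  }
  out
}

#' Egocentric (object-vector-cell) encoding of observations
#'
#' Encodes each in-view displacement as an SSP; optionally evaluates an OVC
#' population's activities on the attended landmark's egocentric SSP.
#'
#' @param enc an [ssp_encoder()].
#' @param obs observations from [observe()].
#' @param ovc_pop optional [nef_population()] with `dim = d`.
#' @param attended index into `obs` of the attended landmark (default 1).
#' @return list `ssps` (list of d-vectors, one per observation) and
#'   `activities` (rates for the attended SSP, or NULL).
#' @export
ovc_encode <- function(enc, obs, ovc_pop = NULL, attended = 1L) {
  ssps <- lapply(obs, function(o) encode_ssp(enc, o$displacement))
  act <- NULL
  if (!is.null(ovc_pop) && length(ssps) >= attended)
    act <- nef_rates(ovc_pop, ssps[[attended]])
  list(ssps = ssps, activities = act)
}

#' Allocentric binding (object-location stage)
#'
#' `phi_hat(x_i) = phi_hat(x) (*) phi(x_i - x)`: the self-position estimate
#' bound with the egocentric landmark SSP gives the allocentric landmark SSP
#' (exact when both inputs are clean, by the shift property).
#'
#' @param pi_estimate d-vector self-position SSP estimate.
#' @param egocentric d-vector egocentric landmark SSP.
#' @export
ol_bind <- function(pi_estimate, egocentric) bind(pi_estimate, egocentric)

#' Create a heteroassociative memory
#'
#' A rate-mode neuron population whose encoders adapt by Voja (so neurons
#' become selective for stored keys) and whose decoded output connection is
#' trained by PES against a target value. With the learning gate off, recall
#' is deterministic and parameters do not change.
#'
#' @param n neurons (reference configuration: 1,000).
#' @param key_dim,value_dim key/value dimensionalities (both `d` here).
#' @param lif LIF parameters.
#' @param seed integer seed.
#' @param kappa_pes,kappa_voja learning rates (defaults 1e-2 and 5e-3).
#' @return object of class `assoc_memory` (an environment, updated in place
#'   by [am_train_step()]).
#' @export
assoc_memory <- function(n, key_dim, value_dim = key_dim, lif = lif_params(),
                         seed = 1L, kappa_pes = 1e-2, kappa_voja = 5e-3) {
  # keys are unit vectors whose pairwise similarities are ~1/sqrt(d); sparse
  # intercepts (the model's stated 0.1 active proportion, placed on unit-norm
  # representative inputs) keep neurons key-selective so Voja specialisation
  # works and stored pairs do not blend
  keys_rep <- with_seed(seed + 31L, {
    g <- matrix(stats::rnorm(500L * key_dim), 500L, key_dim)
    g / sqrt(rowSums(g^2))
  })
  pop <- nef_population(n, key_dim, lif = lif, seed = seed,
                        encoder_style = "uniform-sphere",
                        active_proportion = lif$active_proportion,
                        rep_inputs = keys_rep)
  mem <- new.env(parent = emptyenv())
  mem$pop <- pop
  mem$decoders <- matrix(0, n, value_dim)
  mem$kappa_pes <- kappa_pes
  mem$kappa_voja <- kappa_voja
  mem$trained_s <- 0
  class(mem) <- "assoc_memory"
  mem
}

#' Recall from the associative memory
#'
#' Deterministic decoded output for a query key (keys are normalised before
#' encoding, matching training).
#'
#' @param mem an [assoc_memory()].
#' @param query key vector.
#' @export
am_recall <- function(mem, query) {
  nq <- sqrt(sum(query^2))
  if (nq > 0) query <- query / nq
  drop(crossprod(mem$decoders, nef_rates(mem$pop, query)))
}

#' One online training step (Voja on encoders, PES on decoders)
#'
#' Applied only while the learning gate is on (a landmark is attended);
#' modifies `mem` in place. The PES error is `value - recall`, so the decoded
#' output converges to the stored value; Voja pulls active neurons' encoders
#' toward the (normalised) key.
#'
#' @param mem an [assoc_memory()].
#' @param key key vector (e.g. a composed feature pointer).
#' @param value target value vector (e.g. the believed landmark-location SSP).
#' @param dt timestep (s).
#' @param gate logical learning gate (default TRUE).
#' @export
am_train_step <- function(mem, key, value, dt, gate = TRUE) {
  if (!gate) return(invisible(mem))
  nk <- sqrt(sum(key^2))
  if (nk > 0) key <- key / nk
  act <- nef_rates(mem$pop, key)
  recall <- drop(crossprod(mem$decoders, act))
  err <- value - recall
  mem$decoders <- pes_update(mem$decoders, err, act, dt, mem$kappa_pes)
  mem$pop$encoders <- voja_update(mem$pop$encoders, act, key, dt,
                                  mem$kappa_voja)
  mem$trained_s <- mem$trained_s + dt
  invisible(mem)
}

#' Rank vocabulary features against a reverse-memory recall
#'
#' For a memory trained location -> feature, recalls the feature vector for a
#' location (or region) query and ranks every candidate vocabulary pointer by
#' similarity.
#'
#' @param mem2 location->feature [assoc_memory()].
#' @param location_query d-vector (point SSP or region encoding).
#' @param vocab vocabulary of candidate feature pointers.
#' @param names optional candidate subset.
#' @param mode similarity mode (`"cosine"`, or `"dot"` — useful to detect an
#'   empty region, where the recall is near zero but still has a direction).
#' @return named similarity vector, sorted decreasing.
#' @export
reverse_recall <- function(mem2, location_query, vocab, names = NULL,
                           mode = "cosine") {
  rec <- am_recall(mem2, location_query)
  if (all(rec == 0)) {  # untrained memory: uniformly zero similarity
    nm <- if (is.null(names)) base::names(vocab$symbols) else names
    return(stats::setNames(numeric(length(nm)), nm))
  }
  vocab_rank(vocab, rec, names = names, mode = mode)
}

#' Vector-to-landmark query
#'
#' `phi_hat(x_i - x) = phi_hat(x)^(-1) (*) phi_hat(x_i)`: binding the inverse
#' of the self-position estimate with a recalled landmark location yields the
#' egocentric vector to that landmark.
#'
#' @param pi_estimate d-vector self-position SSP.
#' @param recalled_location d-vector landmark-location SSP (e.g. from
#'   [am_recall()]).
#' @export
vector_to_landmark <- function(pi_estimate, recalled_location) {
  bind(sp_inverse(pi_estimate), recalled_location)
}

#' Loop-closure correction
#'
#' When a landmark is in view and the map's recall for its key is confident
#' (maximum lattice similarity above `theta`), an alternative self-position
#' estimate is computed as `recall (*) egocentric^(-1)` and the correction is
#' `gamma * (phi_ME - pi_estimate)`. Otherwise the correction is zero and the
#' validity flag false.
#'
#' @param mem trained [assoc_memory()] (feature -> location).
#' @param key the in-view landmark's feature pointer (NULL when nothing is in
#'   view).
#' @param ovc_ssp egocentric SSP of that landmark.
#' @param pi_estimate current d-vector self-position estimate.
#' @param readout fitted [fit_normalization()] readout (for confidence).
#' @param theta confidence threshold on the recall's maximum lattice
#'   similarity (default 0.5).
#' @param gamma correction gain (default 0.2 per synaptic time constant).
#' @param recall optional precomputed recall for `key` (avoids recomputation).
#' @param confidence optional precomputed confidence value.
#' @return list `correction` (d-vector), `valid` (flag), `confidence`.
#' @export
loop_closure <- function(mem, key, ovc_ssp, pi_estimate, readout,
                         theta = 0.5, gamma = 0.2, recall = NULL,
                         confidence = NULL) {
  d <- length(pi_estimate)
  if (is.null(key))
    return(list(correction = numeric(d), valid = FALSE, confidence = 0))
  if (is.null(recall)) recall <- am_recall(mem, key)
  if (is.null(confidence))
    confidence <- if (all(recall == 0)) 0 else
      max(crossprod(readout$Phi, recall))
  if (confidence <= theta)
    return(list(correction = numeric(d), valid = FALSE,
                confidence = confidence))
  phi_me <- bind(recall, sp_inverse(ovc_ssp))
  list(correction = gamma * (phi_me - pi_estimate), valid = TRUE,
       confidence = confidence)
}

#' Export the learned map as JSON
#'
#' Decodes every vocabulary landmark key through the memory and records the
#' MAP location and confidence.
#'
#' @param mem trained memory; @param env environment (for key names);
#' @param readout fitted readout; @param path file path.
#' @export
map_to_json <- function(mem, env, readout, path) {
  entries <- lapply(env$landmarks, function(l) {
    rec <- am_recall(mem, l$pointer)
    conf <- if (all(rec == 0)) 0 else max(crossprod(readout$Phi, rec))
    dec <- if (all(rec == 0)) rep(NA_real_, env$m) else map_decode(readout, rec)$x
    list(key = l$name, location = dec, confidence = conf)
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- Full SLAM loop ---------------------------------------------------------

#' Run the full SLAM loop (or dead reckoning) over a trajectory
#'
#' Per timestep: the path integrator advances on the (optionally neural-noisy)
#' velocity; landmarks in view are observed, one attended per step
#' (round-robin); the attended landmark's egocentric SSP is bound with the
#' cleaned self-position estimate to form the allocentric target that trains
#' the feature->location memory (and optionally a location->feature reverse
#' memory); a confidence-gated loop-closure correction feeds back into the
#' oscillators. MAP decoding and confidence checks run every `decode_every`
#' steps (decodes between lattice evaluations reuse the last value).
#'
#' @param enc encoder.
#' @param env environment (`NULL` or zero landmarks gives pure dead
#'   reckoning).
#' @param traj trajectory providing the time base and ground truth.
#' @param readout fitted readout (defaults to `fit_normalization(enc)`).
#' @param velocities velocity input (defaults to the trajectory's exact
#'   velocities; pass the output of [noisy_velocity_channel()] for the
#'   realistic noisy input).
#' @param mem optional pre-made memory; by default one is created.
#' @param reverse_mem optional reverse memory to train location->feature.
#' @param correct enable loop closure (default TRUE when landmarks exist).
#' @param tier path-integrator tier ("ideal" or "rate").
#' @param n_am_neurons memory neurons (default 1000).
#' @param view_radius visibility radius (default 0.3 x arena radius).
#' @param theta,gamma loop-closure confidence threshold and gain.
#' @param theta_learn novelty gate: once a landmark's recall confidence
#'   exceeds this (default 0.7, a margin above `theta`), its association is
#'   considered stored and further map learning for that key is inhibited, so
#'   the map keeps the past estimate instead of tracking the drifting belief.
#'   `Inf` disables the gate (continuous learning).
#' @param decode_every steps between MAP decodes (default 50, i.e. every
#'   50 ms at dt = 1 ms).
#' @param tau_syn synaptic time constant.
#' @param seed seed for neural components.
#' @param n_neurons_per_vco rate tier only.
#' @param record_gc optional [nef_population()]; when given, its activities on
#'   the cleaned SSP are recorded at decode steps.
#' @param track_v2l optional landmark index: at every decode step, record the
#'   similarity error of the vector-to-landmark computation
#'   `1 - phi(x_i - x) . bind(inverse(phi_hat), recall(key_i))` for that
#'   landmark (high before the landmark is first mapped, low after).
#' @return object of class `slam_result`: per-decode-step `times`, `truth`,
#'   `estimates` (MAP decodes), `sim_error`, per-step `radii` range, the
#'   trained memories, and bookkeeping.
#' @export
run_slam <- function(enc, env, traj, readout = NULL, velocities = NULL,
                     mem = NULL, reverse_mem = NULL, correct = TRUE,
                     tier = "ideal", n_am_neurons = 1000L,
                     view_radius = NULL, theta = 0.5, gamma = 0.2,
                     theta_learn = 0.7, decode_every = 50L, tau_syn = 0.05,
                     seed = 1L, n_neurons_per_vco = 500L, record_gc = NULL,
                     track_v2l = NULL) {
  if (is.null(readout)) readout <- fit_normalization(enc)
  if (is.null(velocities)) velocities <- traj$velocities
  n_lm <- if (is.null(env)) 0L else length(env$landmarks)
  if (is.null(view_radius) && n_lm > 0L) view_radius <- 0.3 * env$radius
  if (n_lm == 0L) correct <- FALSE
  if (is.null(mem) && n_lm > 0L)
    mem <- assoc_memory(n_am_neurons, enc$d, enc$d, seed = seed + 17L)
  n <- length(traj$times)
  dt <- traj$dt
  pi_ <- pi_init(enc, traj$positions[1L, ], tier = tier, tau_syn = tau_syn,
                 seed = seed, n_neurons_per_vco = n_neurons_per_vco)
  dec_idx <- seq(1L, n, by = decode_every)
  n_dec <- length(dec_idx)
  est <- matrix(NA_real_, n_dec, traj$m)
  sim_err <- numeric(n_dec)
  gc_act <- if (!is.null(record_gc)) matrix(NA_real_, n_dec, record_gc$n)
  v2l_err <- if (!is.null(track_v2l)) rep(NA_real_, n_dec)
  # cached per-landmark confidence/recall, refreshed at decode cadence
  conf_cache <- rep(-Inf, max(n_lm, 1L))
  recall_cache <- vector("list", max(n_lm, 1L))
  frozen <- logical(max(n_lm, 1L))             # novelty gate per landmark
  correction <- NULL
  attend_ptr <- 0L
  clean_ssp <- assemble_ssp(pi_)
  k <- 0L
  for (i in seq_len(n)) {
    pi_ <- pi_step(pi_, velocities[i, ], dt, correction = correction)
    phi_hat <- assemble_ssp(pi_)
    at_decode <- (i - dec_idx[min(k + 1L, n_dec)] == 0L)
    if (at_decode) {
      k <- k + 1L
      cl <- cleanup_ssp(readout, phi_hat)
      clean_ssp <- cl$ssp
      est[k, ] <- cl$x
      sim_err[k] <- 1 - sum(encode_ssp(enc, traj$positions[i, ]) * phi_hat)
      if (!is.null(record_gc)) gc_act[k, ] <- nef_rates(record_gc, clean_ssp)
      if (!is.null(track_v2l)) {
        lt <- env$landmarks[[track_v2l]]
        rec_t <- am_recall(mem, lt$pointer)
        # the localization module's output for downstream binding is the
        # cleaned SSP (the raw oscillator vector leaves the SSP manifold
        # over time even when its MAP decode stays accurate)
        v2l <- vector_to_landmark(clean_ssp, rec_t)
        true_v <- encode_ssp(enc, lt$position - traj$positions[i, ])
        v2l_err[k] <- 1 - sum(true_v * v2l)
      }
    }
    correction <- NULL
    if (n_lm > 0L) {
      obs <- observe(env, traj$positions[i, ], view_radius)
      if (length(obs) > 0L) {
        attend_ptr <- attend_ptr + 1L
        o <- obs[[(attend_ptr %% length(obs)) + 1L]]
        ego <- encode_ssp(enc, o$displacement)
        target <- ol_bind(clean_ssp, ego)
        am_train_step(mem, o$pointer, target, dt, gate = !frozen[o$index])
        if (!is.null(reverse_mem))
          am_train_step(reverse_mem, target, o$pointer, dt,
                        gate = !frozen[o$index])
        if ((correct || !frozen[o$index]) &&
            (at_decode || !is.finite(conf_cache[o$index]))) {
          rec <- am_recall(mem, o$pointer)
          conf_cache[o$index] <- if (all(rec == 0)) 0 else
            max(crossprod(readout$Phi, rec))
          recall_cache[[o$index]] <- rec
          if (conf_cache[o$index] > theta_learn) frozen[o$index] <- TRUE
        }
        if (correct) {
          lc <- loop_closure(mem, o$pointer, ego, phi_hat, readout,
                             theta = theta, gamma = gamma,
                             recall = recall_cache[[o$index]],
                             confidence = conf_cache[o$index])
          if (lc$valid) correction <- lc$correction
        }
      }
    }
  }
  structure(list(times = traj$times[dec_idx], truth = traj$positions[dec_idx, ,
                                                                     drop = FALSE],
                 estimates = est, sim_error = sim_err, mem = mem,
                 reverse_mem = reverse_mem, radii = pi_radii(pi_),
                 gc_activities = gc_act, v2l_error = v2l_err,
                 decode_every = decode_every,
                 dt = dt, enc = enc, readout = readout),
            class = "slam_result")
}
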