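make_fig_world <- function(d = 61L, ell = 0.2, seed = 3L) {
  enc <- ssp_encoder(d, 2, length_scale = ell, seed = seed)
  vocab <- vocabulary(d, seed)
  env <- fig_environment(vocab)
  list(enc = enc, vocab = vocab, env = env)
}

test_that("observe returns exactly the landmarks inside the view ball", {
  w <- make_fig_world()
  expect_length(observe(w$env, c(-0.9, -0.9), 0.2), 0L)
  # closed ball: a landmark exactly at the radius is included
  obs <- observe(w$env, c(0.6, 0.2 - 0.3), 0.3)
  expect_true(any(vapply(obs, function(o) o$name == "BLUE*SQUARE", TRUE)))
  # brute-force distance check on a random environment
  vocab <- vocabulary(61, 5)
  env <- make_environment(5, 10, 2, vocab)
  x <- c(0, 0); r <- 0.45
  got <- sort(vapply(observe(env, x, r), function(o) o$index, 1L))
  want <- which(vapply(env$landmarks, function(l)
    sqrt(sum((l$position - x)^2)) <= r, TRUE))
  expect_identical(got, want)
  for (o in observe(env, x, r))
    expect_equal(o$displacement, env$landmarks[[o$index]]$position - x)
})

test_that("egocentric encoding and allocentric binding compose exactly", {
  w <- make_fig_world()
  ro <- fit_normalization(w$enc)
  x <- c(0.45, 0.1)
  obs <- observe(w$env, x, 0.3)
  expect_gt(length(obs), 0)
  ovc <- ovc_encode(w$enc, obs)
  o <- obs[[1L]]
  expect_equal(ovc$ssps[[1L]], encode_ssp(w$enc, o$displacement),
               tolerance = 1e-12)
  # landmark at the agent's position encodes to the identity pointer
  obs0 <- list(list(index = 1L, name = "x", pointer = NULL,
                    displacement = c(0, 0)))
  expect_equal(ovc_encode(w$enc, obs0)$ssps[[1L]],
               c(1, numeric(w$enc$d - 1L)), tolerance = 1e-12)
  # OVC neuron with encoder encode(delta) fires hardest at displacement delta
  delta <- c(0.1, -0.15)
  pop <- nef_population(1, w$enc$d, encoder_style = "provided",
                        encoders = matrix(encode_ssp(w$enc, delta), 1),
                        seed = 1)
  r_at <- nef_rates(pop, encode_ssp(w$enc, delta))
  set.seed(2)
  others <- replicate(20, nef_rates(pop, encode_ssp(w$enc, runif(2, -1, 1))))
  expect_true(all(r_at >= others))

  # ol_bind: exact allocentric location with clean inputs
  pi_ssp <- encode_ssp(w$enc, x)
  al <- ol_bind(pi_ssp, ovc$ssps[[1L]])
  expect_equal(al, encode_ssp(w$enc, w$env$landmarks[[o$index]]$position),
               tolerance = 1e-9)
  expect_equal(map_decode(ro, al)$x, w$env$landmarks[[o$index]]$position,
               tolerance = ro$grid$steps[1])
  expect_equal(ol_bind(pi_ssp, c(1, numeric(w$enc$d - 1L))), pi_ssp,
               tolerance = 1e-12)
})

test_that("associative memory learns the worked three-landmark map", {
  w <- make_fig_world(d = 181L, ell = 0.15, seed = 1)
  ro <- fit_normalization(w$enc)
  mem <- assoc_memory(250, 181, seed = 5)
  # gate off: bit-identical parameters
  d0 <- mem$decoders; e0 <- mem$pop$encoders
  am_train_step(mem, rand_unit(181), rand_unit(181), 1e-3, gate = FALSE)
  expect_identical(mem$decoders, d0)
  expect_identical(mem$pop$encoders, e0)

  # untrained recall is dissimilar to everything stored later
  vals <- lapply(w$env$landmarks, function(l) encode_ssp(w$enc, l$position))
  for (l in w$env$landmarks) {
    rec0 <- am_recall(mem, l$pointer)
    expect_true(all(vapply(vals, function(v)
      abs(sum(rec0 * v)) < 0.3, TRUE)))
  }

  # train each association for one simulated second, two passes
  for (pass in 1:2) for (i in 1:3) {
    key <- w$env$landmarks[[i]]$pointer
    for (s in 1:500) am_train_step(mem, key, vals[[i]], 1e-3)
  }
  for (i in 1:3) {
    rec <- am_recall(mem, w$env$landmarks[[i]]$pointer)
    expect_gt(similarity(rec, vals[[i]]), 0.9)
    expect_lt(sqrt(sum((map_decode(ro, rec)$x -
                          w$env$landmarks[[i]]$position)^2)), 0.05)
  }
  # compositional recall: bundled keys return (near) the bundle of values
  q <- am_recall(mem, bundle(list(w$env$landmarks[[1]]$pointer,
                                  w$env$landmarks[[2]]$pointer)))
  expect_gt(similarity(q, vals[[1]] + vals[[2]]), 0.8)
  sm <- similarity_map(w$enc, q, resolution = 61L)
  top <- sm$points[order(sm$values, decreasing = TRUE)[1:12], ]
  near1 <- apply(top, 1, function(p)
    sqrt(sum((p - w$env$landmarks[[1]]$position)^2)) < 0.15)
  near2 <- apply(top, 1, function(p)
    sqrt(sum((p - w$env$landmarks[[2]]$position)^2)) < 0.15)
  expect_true(any(near1) && any(near2))

  # Voja sparsification: encoders drawn onto the stored keys leave fewer
  # neurons responsive to arbitrary (novel) inputs than at initialization
  mem_fresh <- assoc_memory(250, 181, seed = 5)
  frac_rand <- function(m) {
    set.seed(99)
    mean(replicate(30, {
      g <- rnorm(181)
      mean(nef_rates(m$pop, g / sqrt(sum(g^2))) > 0)
    }))
  }
  expect_lt(frac_rand(mem), frac_rand(mem_fresh))
})

test_that("reverse memory ranks features for point and area queries", {
  w <- make_fig_world(d = 181L, ell = 0.15, seed = 2)
  # area queries need the reference memory size: key-location clusters must
  # outweigh decoder cross-talk from randomly co-active neurons
  mem2 <- assoc_memory(1000, 181, seed = 6)
  feats <- vapply(w$env$landmarks, function(l) l$name, "")
  set.seed(6)
  for (pass in 1:2) for (i in 1:3) {
    l <- w$env$landmarks[[i]]
    for (s in 1:500) {
      # keys jitter around the true location, as they would in an online run
      key <- encode_ssp(w$enc, l$position + rnorm(2, 0, 0.02))
      am_train_step(mem2, key, l$pointer, 1e-3)
    }
  }
  # point query: the landmark's own feature ranks first
  for (i in 1:3) {
    rk <- reverse_recall(mem2, encode_ssp(w$enc, w$env$landmarks[[i]]$position),
                         w$vocab, names = feats)
    expect_identical(names(rk)[1L], w$env$landmarks[[i]]$name)
  }
  # area query containing the blue square and orange triangle only
  area <- encode_region(w$enc, function(p)
    p[, 1] > -0.45 & p[, 1] < 0.85 & p[, 2] > -0.05 & p[, 2] < 0.45, 101L)
  rk <- reverse_recall(mem2, area, w$vocab, names = feats)
  expect_setequal(names(rk)[1:2], c("BLUE*SQUARE", "ORANGE*TRIANGLE"))
  # empty area: the recalled vector is small, so raw dot similarities are
  # weak for every feature (cosine would be misleading for a near-zero
  # recall, whose direction still lies in the span of trained values)
  empty <- encode_region(w$enc, function(p)
    p[, 1] > -1.1 & p[, 1] < -0.8 & p[, 2] > -1.1 & p[, 2] < -0.8, 101L)
  expect_lt(max(reverse_recall(mem2, empty, w$vocab, names = feats,
                               mode = "dot")), 0.3)
})

test_that("vector-to-landmark recovers the egocentric displacement", {
  w <- make_fig_world()
  ro <- fit_normalization(w$enc)
  x <- c(0.2, -0.1)
  xi_ <- w$env$landmarks[[2]]$position
  v2l <- vector_to_landmark(encode_ssp(w$enc, x), encode_ssp(w$enc, xi_))
  expect_lt(sqrt(sum((map_decode(ro, v2l)$x - (xi_ - x))^2)),
            ro$grid$steps[1])
  v0 <- vector_to_landmark(encode_ssp(w$enc, xi_), encode_ssp(w$enc, xi_))
  expect_lt(sqrt(sum(map_decode(ro, v0)$x^2)), ro$grid$steps[1])
})

test_that("loop closure gates on view and confidence, corrects toward truth", {
  w <- make_fig_world()
  ro <- fit_normalization(w$enc)
  mem <- assoc_memory(120, w$enc$d, seed = 7)
  out <- loop_closure(mem, NULL, NULL, encode_ssp(w$enc, c(0, 0)), ro)
  expect_false(out$valid)
  expect_equal(out$correction, numeric(w$enc$d))
  # untrained memory: low confidence, no correction
  key <- w$env$landmarks[[1]]$pointer
  ego <- encode_ssp(w$enc, c(0.1, 0.1))
  out2 <- loop_closure(mem, key, ego, encode_ssp(w$enc, c(0, 0)), ro)
  expect_false(out2$valid)
  # train the true association, offset the self-estimate, correct
  x_true <- c(0.5, 0.1)
  xl <- w$env$landmarks[[1]]$position
  val <- encode_ssp(w$enc, xl)
  for (s in 1:1500) am_train_step(mem, key, val, 1e-3)
  ego_t <- encode_ssp(w$enc, xl - x_true)
  pi_off <- encode_ssp(w$enc, x_true + c(0.15, -0.1))
  out3 <- loop_closure(mem, key, ego_t, pi_off, ro)
  expect_true(out3$valid)
  corrected <- pi_off + out3$correction / 0.2
  truth <- encode_ssp(w$enc, x_true)
  expect_gt(similarity(corrected, truth), similarity(pi_off, truth))
})

test_that("zero in-view time leaves all memory parameters untouched", {
  enc <- small_encoder()
  vocab <- vocabulary(enc$d, 8)
  env <- make_environment(8, 2, 2, vocab)
  # push both landmarks far outside the arena so nothing is ever in view
  env$landmarks[[1]]$position <- c(5, 5)
  env$landmarks[[2]]$position <- c(-5, 5)
  traj <- generate_trajectory(8, duration = 8, dt = 1e-3, m = 2)
  mem <- assoc_memory(80, enc$d, seed = 9)
  d0 <- mem$decoders; e0 <- mem$pop$encoders
  res <- run_slam(enc, env, traj, mem = mem, seed = 2)
  expect_identical(res$mem$decoders, d0)
  expect_identical(res$mem$pop$encoders, e0)
})

test_that("loop closure does not hurt when the map is exact", {
  enc <- small_encoder()
  ro <- fit_normalization(enc)
  for (s in 1:5) {
    vocab <- vocabulary(enc$d, 40 + s)
    env <- make_environment(40 + s, 6, 2, vocab)
    traj <- generate_trajectory(50 + s, duration = 8, dt = 1e-3, m = 2)
    set.seed(60 + s)
    # noise strong enough that dead reckoning visibly drifts within the run
    noisy <- traj$velocities + matrix(rnorm(length(traj$velocities), 0, 0.25),
                                      ncol = 2)
    pretrain <- function() {
      mem <- assoc_memory(150, enc$d, seed = 70 + s)
      for (l in env$landmarks) {
        val <- encode_ssp(enc, l$position)
        for (k in 1:1200) am_train_step(mem, l$pointer, val, 1e-3)
      }
      mem
    }
    res_c <- run_slam(enc, env, traj, readout = ro, velocities = noisy,
                      mem = pretrain(), correct = TRUE, theta_learn = 0,
                      seed = s)
    res_n <- run_slam(enc, env, traj, readout = ro, velocities = noisy,
                      mem = pretrain(), correct = FALSE, theta_learn = 0,
                      seed = s)
    err_c <- sqrt(rowSums((res_c$truth - res_c$estimates)^2))
    err_n <- sqrt(rowSums((res_n$truth - res_n$estimates)^2))
    # "never hurts" up to decode-lattice noise: mean within a tenth of a
    # lattice cell, per-step within one cell
    expect_lte(mean(err_c), mean(err_n) + ro$grid$steps[1] / 10)
    expect_true(all(err_c <= err_n + ro$grid$steps[1]))
  }
})

test_that("map export records decoded locations and confidences", {
  w <- make_fig_world()
  ro <- fit_normalization(w$enc)
  mem <- assoc_memory(150, w$enc$d, seed = 10)
  l <- w$env$landmarks[[1]]
  val <- encode_ssp(w$enc, l$position)
  for (k in 1:1500) am_train_step(mem, l$pointer, val, 1e-3)
  path <- tempfile(fileext = ".json")
  map_to_json(mem, w$env, ro, path)
  entries <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(entries), 3L)
  i <- which(entries$key == l$name)
  expect_lt(sqrt(sum((unlist(entries$location[i]) - l$position)^2)), 0.05)
  expect_gt(entries$confidence[i], 0.5)
})
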