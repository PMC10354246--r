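# ---- Velocity-controlled-oscillator path integrator -------------------------
#
# The self-position SSP phi(x(t)) evolves, coefficient-wise in the Fourier
# domain, as a bank of independent oscillators rotating at omega_j = A_j . xdot.
# The implemented dynamics add a radial attractor that makes the unit circle
# stable, so the assembled SSP stays near unit length:
#   dRe/dt = -omega*Im + (1 - r^2)/r * Re
#   dIm/dt =  omega*Re + (1 - r^2)/r * Im,   r = sqrt(Re^2 + Im^2).
# Only floor(d/2) oscillators are simulated; the conjugate half-spectrum and
# the DC term (pinned to 1) are reconstructed on assembly. The identical code
# path serves any variable dimension m.

#' Project a velocity onto oscillator frequencies
#'
#' `omega = A_half %*% xdot` (rad/s): linear in the velocity.
#'
#' @param enc an [ssp_encoder()].
#' @param xdot velocity vector of length m.
#' @export
velocity_to_frequencies <- function(enc, xdot) {
  if (length(xdot) != enc$m) stop("velocity dimension mismatch")
  drop(enc$A_half %*% xdot)
}

#' Stabilised oscillator vector field for one VCO
#'
#' @param omega frequency (rad/s); @param re,im oscillator state.
#' @return list `dre`, `dim` of time derivatives. On the unit circle the
#'   radial term vanishes and the field is the pure rotation.
#' @export
vco_derivative <- function(omega, re, im) {
  r2 <- re^2 + im^2
  if (any(r2 == 0)) stop("singular oscillator radius r = 0")
  k <- (1 - r2) / sqrt(r2)
  list(dre = -omega * im + k * re, dim = omega * re + k * im)
}

#' Initialise a path integrator at a known position
#'
#' Oscillator states are set to the upper half-spectrum of `F{phi(x0)}`
#' (all radii exactly 1).
#'
#' @param enc encoder.
#' @param x0 starting position (length m).
#' @param tier `"ideal"` (RK4 on the state equations) or `"rate"` (each VCO is
#'   a recurrently connected rate-mode neuron population).
#' @param n_neurons_per_vco rate tier only: neurons per oscillator population
#'   (the reference configuration's 45,000 path-integrator neurons split
#'   uniformly over the 90 VCOs of a d = 181 encoder gives 500 each).
#' @param tau_syn synaptic time constant for the rate tier (s).
#' @param lif LIF parameters for the rate tier.
#' @param seed seed for the rate-tier populations.
#' @return object of class `path_integrator`.
#' @export
pi_init <- function(enc, x0, tier = c("ideal", "rate"),
                    n_neurons_per_vco = 500L, tau_syn = 0.05,
                    lif = lif_params(), seed = 1L, omega_scale = NULL) {
  tier <- match.arg(tier)
  spec <- exp(1i * drop(enc$A_half %*% x0))
  pi_ <- list(enc = enc, tier = tier, h = enc$h,
              re = Re(spec), im = Im(spec), tau_syn = tau_syn)
  if (tier == "rate") {
    # One population per VCO representing (omega/omega_scale, Re, Im) at
    # radius 1.5, so both the frequency and the unit circle fit inside the
    # representational radius. Recurrent decoders realise tau*f + identity on
    # the oscillator dims; the omega dim is input-driven (filtered input).
    # All VCOs share tuning and decoders: the vector field is the same for
    # each, only omega differs, and omega is part of the represented state.
    # omega_scale: typical arena speeds are well below 1 unit/s, so scaling
    # by half the largest row norm keeps omega/omega_scale spread over the
    # represented range instead of crowded near zero
    if (is.null(omega_scale))
      omega_scale <- 0.5 * max(sqrt(rowSums(enc$A_half^2)))
    rad <- 1.5
    pop <- nef_population(n_neurons_per_vco, 3L, lif = lif, seed = seed,
                          encoder_style = "uniform-sphere", radius = rad)
    with_seed(seed + 1L, {
      # eval points concentrated where the dynamics live: the attractor
      # annulus r ~ 1 crossed with the represented frequency range
      npts <- 2000L
      th <- stats::runif(npts, 0, 2 * pi)
      rr <- stats::runif(npts, 0.6, 1.4)
      w <- stats::runif(npts, -1.1, 1.1)
      eval_pts <- cbind(w, rr * cos(th), rr * sin(th))
      targ <- t(apply(eval_pts, 1L, function(z) {
        dv <- vco_derivative(z[1L] * omega_scale, z[2L], z[3L])
        c(0, tau_syn * dv$dre + z[2L], tau_syn * dv$dim + z[3L])
      }))
      D <- solve_decoders(pop, eval_pts, targ)
    })
    pi_$pop <- pop
    pi_$decoders <- D
    pi_$omega_scale <- omega_scale
    # per-VCO filtered recurrent and input values (3-vectors)
    pi_$filt_rec <- rbind(0, pi_$re, pi_$im)    # 3 x h, seeded at the target
    pi_$filt_in <- matrix(0, 3L, enc$h)
    pi_$radius <- rad
  }
  class(pi_) <- "path_integrator"
  pi_
}

#' Advance the path integrator one timestep
#'
#' The ideal tier integrates the stabilised oscillator equations with RK4
#' (frequency and correction held constant over the step). The rate tier
#' steps every VCO population's recurrent loop through the synaptic filter.
#' A loop-closure `correction` (a d-vector, already scaled by the closure
#' gain) is injected as an input current on the half-spectrum components,
#' with rate `1/tau_syn` so a sustained correction acts like a first-order
#' pull toward the corrected estimate.
#'
#' @param pi_ a [pi_init()] object.
#' @param xdot velocity (length m).
#' @param dt timestep (s).
#' @param correction optional d-vector correction (e.g. from [loop_closure()]).
#' @return updated path integrator.
#' @export
pi_step <- function(pi_, xdot, dt, correction = NULL) {
  enc <- pi_$enc
  omega <- velocity_to_frequencies(enc, xdot)
  if (!is.null(correction)) {
    cs <- stats::fft(correction)
    c_re <- Re(cs[1L + seq_len(enc$h)]) / pi_$tau_syn
    c_im <- Im(cs[1L + seq_len(enc$h)]) / pi_$tau_syn
  } else {
    c_re <- 0; c_im <- 0
  }
  if (pi_$tier == "ideal") {
    deriv <- function(re, im) {
      r2 <- re^2 + im^2
      # clamp the radial gain near the origin: corrections can push an
      # oscillator through r ~ 0, where the exact field is singular
      k <- (1 - r2) / pmax(sqrt(r2), 0.1)
      list(dre = -omega * im + k * re + c_re,
           dim = omega * re + k * im + c_im)
    }
    k1 <- deriv(pi_$re, pi_$im)
    k2 <- deriv(pi_$re + dt / 2 * k1$dre, pi_$im + dt / 2 * k1$dim)
    k3 <- deriv(pi_$re + dt / 2 * k2$dre, pi_$im + dt / 2 * k2$dim)
    k4 <- deriv(pi_$re + dt * k3$dre, pi_$im + dt * k3$dim)
    pi_$re <- pi_$re + dt / 6 * (k1$dre + 2 * k2$dre + 2 * k3$dre + k4$dre)
    pi_$im <- pi_$im + dt / 6 * (k1$dim + 2 * k2$dim + 2 * k3$dim + k4$dim)
  } else {
    a <- exp(-dt / pi_$tau_syn)
    pop <- pi_$pop; D <- pi_$decoders
    x_rep <- pi_$filt_rec + pi_$filt_in         # 3 x h represented values
    rates <- nef_rates(pop, t(x_rep))           # n x h
    rec_out <- t(D) %*% rates                   # 3 x h decoded recurrent
    pi_$filt_rec <- pi_$filt_rec * a + (1 - a) * rec_out
    u <- rbind(omega / pi_$omega_scale, pi_$tau_syn * c_re,
               pi_$tau_syn * c_im)
    pi_$filt_in <- pi_$filt_in * a + (1 - a) * u
    x_now <- pi_$filt_rec + pi_$filt_in
    pi_$re <- x_now[2L, ]
    pi_$im <- x_now[3L, ]
  }
  pi_
}

#' Assemble the SSP estimate from the oscillator bank
#'
#' Mirrors the simulated half-spectrum into a conjugate-symmetric full
#' spectrum (DC term pinned to 1) and inverse-transforms; the result is real
#' by construction.
#'
#' @param pi_ path integrator.
#' @return d-vector estimate of `phi(x)`.
#' @export
assemble_ssp <- function(pi_) {
  d <- pi_$enc$d; h <- pi_$h
  spec <- complex(length.out = d)
  spec[1L] <- 1 + 0i
  spec[1L + seq_len(h)] <- complex(real = pi_$re, imaginary = pi_$im)
  spec[d + 1L - seq_len(h)] <- Conj(spec[1L + seq_len(h)])
  Re(stats::fft(spec, inverse = TRUE)) / d
}

#' Oscillator radii
#' @param pi_ path integrator.
#' @export
pi_radii <- function(pi_) sqrt(pi_$re^2 + pi_$im^2)

#' Grid-cell stage: clean-up plus population activities
#'
#' Applies [cleanup_ssp()] (MAP decode and re-encode) to the raw path
#' integrator output and evaluates the grid-cell population's rates on the
#' cleaned SSP. On decode failure the raw estimate passes through, flagged.
#'
#' @param gc an [nef_population()] whose `dim` equals the encoder's `d`
#'   (typically `ssp-points` or `grid-module` encoders).
#' @param pi_output d-vector from [assemble_ssp()].
#' @param readout fitted [fit_normalization()] readout.
#' @return list `ssp` (cleaned), `x` (decode), `ok` (flag), `activities`.
#' @export
gc_update <- function(gc, pi_output, readout) {
  cl <- cleanup_ssp(readout, pi_output)
  act <- nef_rates(gc, cl$ssp)
  list(ssp = cl$ssp, x = cl$x, ok = cl$ok, activities = act)
}

#' Dump path-integrator state as a data frame row
#' @param pi_ path integrator; @param t time (s).
#' @keywords internal
pi_state_row <- function(pi_, t) {
  data.frame(t = t, r_min = min(pi_radii(pi_)), r_max = max(pi_radii(pi_)))
}
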