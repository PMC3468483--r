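#' Simulate an FRR single-turnover transient
#'
#' Forward model [frr_forward()] plus additive Gaussian instrument noise
#' with standard deviation `noise_sd * fm`. With `noise_sd = 0` the output
#' equals the forward model exactly; identical seeds give bit-identical
#' output.
#'
#' @inheritParams frr_forward
#' @param flashlet_doses Per-flashlet doses, photons A^-2; the default is a
#'   100-flashlet saturating train (1e-4 photons A^-2 each, cumulative
#'   1e-2).
#' @param noise_sd Noise SD as a fraction of `fm` (>= 0).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An [frr_transient()] carrying the ground truth as the
#'   `truth` attribute.
#' @export
simulate_frr_transient <- function(fo, fm, sigma, p,
                                   flashlet_doses = rep(1e-4, 100),
                                   noise_sd = 0, seed = NULL) {
  .assert(.is_num(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  f <- frr_forward(fo, fm, sigma, p, flashlet_doses) # validates parameters
  if (noise_sd > 0) {
    f <- f + .with_seed_opt(seed, stats::rnorm(length(f), 0, noise_sd * fm))
  }
  out <- frr_transient(flashlet_doses, f)
  attr(out, "truth") <- list(fo = fo, fm = fm, sigma = sigma, p = p,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a PAM quenching protocol trace
#'
#' Builds a trace with a dark Fo window, a dark saturating pulse reaching
#' `fm`, an actinic phase in which Ft relaxes exponentially (time constant
#' `kinetics$tau`) from `fo` to the steady state implied by the targets,
#' and a light saturating pulse reaching `Fm' = fm / (1 + npq_true)`. The
#' final `kinetics$ft_window` seconds of the actinic phase are held exactly
#' at the steady-state `Ft = Fm' (1 - phi_true)` so that noiseless marker
#' extraction recovers `npq_true` and `phi_true` exactly.
#'
#' @param fo,fm Dark-adapted landmarks, `0 < fo < fm`.
#' @param npq_true Target NPQ (>= 0).
#' @param phi_true Target effective quantum yield, in `[0, 1)`.
#' @param kinetics List: `tau` (Ft relaxation time constant, s, default 20),
#'   `dark_s` (dark window, default 60), `actinic_s` (actinic phase,
#'   default 120), `ft_window` (steady-state window, default 10),
#'   `pulse_s` (pulse width, default 1), `dt` (sampling step, default 1).
#' @param noise_sd Additive Gaussian noise SD as a fraction of `fm`.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A [pam_trace()] carrying the ground truth as the `truth`
#'   attribute.
#' @export
simulate_pam_protocol <- function(fo, fm, npq_true, phi_true,
                                  kinetics = list(), noise_sd = 0,
                                  seed = NULL) {
  .assert(.is_num(fo) && .is_num(fm) && fo > 0 && fo < fm, "need 0 < fo < fm")
  .assert(.is_num(npq_true) && npq_true >= 0, "npq_true must be >= 0")
  .assert(.is_num(phi_true) && phi_true >= 0 && phi_true < 1,
          "phi_true must lie in [0, 1)")
  .assert(.is_num(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  k <- utils::modifyList(list(tau = 20, dark_s = 60, actinic_s = 120,
                              ft_window = 10, pulse_s = 1, dt = 1), kinetics)
  fm_prime <- fm / (1 + npq_true)
  ft_ss <- fm_prime * (1 - phi_true)
  if (fo > fm_prime) {
    stop("inconsistent targets: quenching this strong would push Ft above Fm'",
         call. = FALSE)
  }

  t_dark <- seq(0, k$dark_s - k$dt, by = k$dt)
  f_dark <- rep(fo, length(t_dark))
  t_fm <- k$dark_s + seq(0, k$pulse_s, by = k$dt / 2)
  f_fm <- rep(fm, length(t_fm))
  act_on <- max(t_fm) + k$dt
  t_act <- act_on + seq(0, k$actinic_s - k$dt, by = k$dt)
  rel <- ft_ss + (fo - ft_ss) * exp(-(t_act - act_on) / k$tau)
  ## hold the tail of the actinic phase exactly at steady state
  rel[t_act > max(t_act) - k$ft_window] <- ft_ss
  t_fmp <- max(t_act) + k$dt + seq(0, k$pulse_s, by = k$dt / 2)
  f_fmp <- rep(fm_prime, length(t_fmp))
  t_post <- max(t_fmp) + seq(k$dt, 30, by = k$dt)
  f_post <- fo + (ft_ss - fo) * exp(-(t_post - max(t_fmp)) / k$tau)

  time <- c(t_dark, t_fm, t_act, t_fmp, t_post)
  f <- c(f_dark, f_fm, rel, f_fmp, f_post)
  if (noise_sd > 0) {
    f <- f + .with_seed_opt(seed, stats::rnorm(length(f), 0, noise_sd * fm))
  }
  events <- data.frame(
    event = c("fo_window", "fm_pulse", "actinic", "ft_window",
              "fmprime_pulse", "post_actinic"),
    start = c(0, min(t_fm), act_on, max(t_act) - k$ft_window + k$dt,
              min(t_fmp), min(t_post)),
    end = c(max(t_dark), max(t_fm), max(t_act), max(t_act), max(t_fmp),
            max(t_post))
  )
  out <- pam_trace(time, f, events)
  attr(out, "truth") <- list(fo = fo, fm = fm, npq = npq_true,
                             phi_psii = phi_true, fm_prime = fm_prime,
                             ft = ft_ss, noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a Clark-electrode oxygen trace
#'
#' Piecewise-linear O2 concentration: light segments rise at
#' `(ag - rd) * chl / 3600` umol O2 L^-1 s^-1, dark segments fall at
#' `rd * chl / 3600`, optionally with a transient post-illumination burst
#' (uptake at `burst$factor` times the steady dark rate for
#' `burst$duration` seconds after each light-to-dark transition). Additive
#' Gaussian noise on concentration.
#'
#' @param ag Gross photosynthesis, umol O2 mg chl a^-1 h^-1 (>= 0).
#' @param rd Dark respiration, umol O2 mg chl a^-1 h^-1 (>= 0, positive
#'   convention).
#' @param chl mg chl a L^-1 (> 0).
#' @param segment_plan data.frame with columns `phase`
#'   (`"dark"`/`"light"`) and `duration` (s); default dark 120 s, light
#'   300 s, dark 300 s.
#' @param noise_sd Gaussian noise SD on O2, umol O2 L^-1.
#' @param post_illumination_burst `NULL`, or list with `factor` (multiple
#'   of steady dark uptake) and `duration` (s).
#' @param o2_start Initial O2 concentration, umol O2 L^-1 (default 250).
#' @param dt Sampling interval, s (default 1).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An [oxygen_trace()] carrying the ground truth as the `truth`
#'   attribute.
#' @export
simulate_oxygen_trace <- function(ag, rd, chl,
                                  segment_plan = data.frame(
                                    phase = c("dark", "light", "dark"),
                                    duration = c(120, 300, 300)),
                                  noise_sd = 0,
                                  post_illumination_burst = NULL,
                                  o2_start = 250, dt = 1, seed = NULL) {
  .assert(.is_num(ag) && ag >= 0, "ag must be >= 0")
  .assert(.is_num(rd) && rd >= 0, "rd must be >= 0")
  .assert(.is_num(chl) && chl > 0, "chl must be > 0")
  .assert(is.data.frame(segment_plan) && nrow(segment_plan) > 0 &&
            all(c("phase", "duration") %in% names(segment_plan)),
          "segment_plan must be a non-empty data.frame with phase/duration")
  .assert(all(segment_plan$phase %in% c("dark", "light")),
          "segment phases must be 'dark' or 'light'")
  .assert(all(segment_plan$duration >= 5 * dt),
          "each segment needs at least 5 samples")
  if (!is.null(post_illumination_burst)) {
    .assert(is.list(post_illumination_burst) &&
              all(c("factor", "duration") %in% names(post_illumination_burst)),
            "post_illumination_burst needs factor and duration")
    .assert(post_illumination_burst$factor >= 1, "burst factor must be >= 1")
  }

  light_slope <- (ag - rd) * chl / 3600
  dark_slope <- -rd * chl / 3600

  time <- numeric(0); phase <- character(0); slope <- numeric(0)
  t_cursor <- 0
  prev_phase <- NA_character_
  for (i in seq_len(nrow(segment_plan))) {
    ph <- segment_plan$phase[i]
    tt <- seq(t_cursor, t_cursor + segment_plan$duration[i] - dt, by = dt)
    sl <- rep(if (ph == "light") light_slope else dark_slope, length(tt))
    if (ph == "dark" && identical(prev_phase, "light") &&
        !is.null(post_illumination_burst)) {
      in_burst <- tt < t_cursor + post_illumination_burst$duration
      sl[in_burst] <- -post_illumination_burst$factor * rd * chl / 3600
    }
    time <- c(time, tt); phase <- c(phase, rep(ph, length(tt)))
    slope <- c(slope, sl)
    t_cursor <- t_cursor + segment_plan$duration[i]
    prev_phase <- ph
  }
  o2 <- o2_start + c(0, cumsum(slope[-length(slope)] * diff(time)))
  if (noise_sd > 0) {
    o2 <- o2 + .with_seed_opt(seed, stats::rnorm(length(o2), 0, noise_sd))
  }
  out <- oxygen_trace(time, o2, phase, chl)
  attr(out, "truth") <- list(ag = ag, rd = rd, chl = chl,
                             burst = post_illumination_burst,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a 14C photosynthesis-irradiance experiment
#'
#' Rates follow the Jassby-Platt mean `pmax * tanh(alpha * e / pmax)`
#' multiplied by unit-mean lognormal noise of coefficient of variation
#' `noise_cv`.
#'
#' @param pmax Maximum rate, mg C mg chl a^-1 h^-1 (> 0).
#' @param alpha Initial slope (> 0).
#' @param e_grid Irradiances, umol photons m^-2 s^-1; default spans
#'   5-1500 umol photons m^-2 s^-1.
#' @param noise_cv Lognormal CV (>= 0).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return data.frame of class `pe_data` with columns `e`, `p`, carrying
#'   the ground truth as the `truth` attribute.
#' @export
simulate_pe_experiment <- function(pmax, alpha,
                                   e_grid = c(5, 10, 25, 50, 100, 250, 500,
                                              1000, 1500),
                                   noise_cv = 0, seed = NULL) {
  .assert(.is_num(pmax) && pmax > 0, "pmax must be > 0")
  .assert(.is_num(alpha) && alpha > 0, "alpha must be > 0")
  .assert(is.numeric(e_grid) && all(e_grid >= 0), "e_grid must be non-negative")
  .assert(.is_num(noise_cv) && noise_cv >= 0, "noise_cv must be >= 0")
  p <- pmax * tanh(alpha * e_grid / pmax)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    mult <- .with_seed_opt(
      seed, stats::rlnorm(length(p), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    p <- p * mult
  }
  out <- data.frame(e = e_grid, p = p)
  class(out) <- c("pe_data", "data.frame")
  attr(out, "truth") <- list(pmax = pmax, alpha = alpha, ek = pmax / alpha,
                             noise_cv = noise_cv, seed = seed)
  out
}

#' Specify a diel trajectory scenario
#'
#' Phenomenological description of how a photosynthetic parameter moves
#' over a light:dark cycle: a linear morning rise from `baseline` to
#' `baseline * peak_mult` reached at a mid-morning plateau, a falling phase
#' that mirrors the rising phase in time scaled by the afternoon
#' `depression` factor, and baseline at night. This encodes the
#' qualitative diel shapes seen in photoacclimating cultures (mid-morning
#' maximum, midday/afternoon depression, hysteresis between phases).
#'
#' @param parameters Named list; each element is a list with `baseline`
#'   (> 0), `peak_mult` (> 0, default 1), `depression` (in (0, 1], default
#'   1), `lag` (hours, default 0).
#' @param noise_sd Multiplicative Gaussian noise SD (fraction, >= 0).
#' @param ramp_frac Fraction of the rising half-photoperiod spent ramping
#'   before the plateau (default 0.5).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `diel_scenario`.
#' @export
diel_scenario <- function(parameters, noise_sd = 0, ramp_frac = 0.5,
                          seed = NULL) {
  .assert(is.list(parameters) && length(parameters) > 0 &&
            !is.null(names(parameters)) && all(nzchar(names(parameters))),
          "parameters must be a named list of trajectory specs")
  parameters <- lapply(parameters, function(sp) {
    sp <- utils::modifyList(list(peak_mult = 1, depression = 1, lag = 0), sp)
    .assert(!is.null(sp$baseline) && .is_num(sp$baseline) && sp$baseline > 0,
            "each trajectory needs a positive baseline")
    .assert(.is_num(sp$peak_mult) && sp$peak_mult > 0, "peak_mult must be > 0")
    .assert(.is_num(sp$depression) && sp$depression > 0 && sp$depression <= 1,
            "depression factor must lie in (0, 1]")
    .assert(.is_num(sp$lag), "lag must be a single number (hours)")
    sp
  })
  .assert(.is_num(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  .assert(.is_num(ramp_frac) && ramp_frac > 0 && ramp_frac <= 1,
          "ramp_frac must lie in (0, 1]")
  structure(list(parameters = parameters, noise_sd = noise_sd,
                 ramp_frac = ramp_frac, seed = seed),
            class = "diel_scenario")
}

## Dimensionless diel shape for one parameter spec at hours-since-onset u.
.diel_shape <- function(u, pp, sp, ramp_frac) {
  t_peak <- pp / 2
  t_m <- ramp_frac * t_peak
  morning <- function(v) {
    ifelse(v < t_m, 1 + (sp$peak_mult - 1) * v / t_m, sp$peak_mult)
  }
  u <- u - sp$lag
  out <- rep(1, length(u))
  rising <- u >= 0 & u < t_peak
  falling <- u >= t_peak & u < pp
  out[rising] <- morning(u[rising])
  out[falling] <- sp$depression * morning(pp - u[falling])
  out
}

#' Simulate a diel time series of photosynthetic parameters
#'
#' Evaluates each trajectory of a [diel_scenario()] on a regular time grid
#' over one 24 h cycle of the given schedule, attaching the irradiance at
#' each timestamp. In the noiseless limit the configured asymmetries are
#' recovered exactly by [midday_depression()] (returns the depression
#' factor) and [hysteresis_index()] (returns one minus the depression
#' factor) for lag-free scenarios.
#'
#' @param scenario A [diel_scenario()].
#' @param schedule An [make_irradiance_schedule()]; half-sine mode is the
#'   intended use.
#' @param dt Sampling step, hours (default 0.25).
#' @return data.frame of class `diel_series` with columns `time`
#'   (hours since light onset), `parameter`, `value`, `irradiance`,
#'   carrying the scenario as the `truth` attribute.
#' @export
simulate_diel_experiment <- function(scenario, schedule, dt = 0.25) {
  stopifnot(inherits(scenario, "diel_scenario"),
            inherits(schedule, "irradiance_schedule"))
  .assert(.is_num(dt) && dt > 0 && dt <= 6, "dt must lie in (0, 6] hours")
  tt <- seq(0, schedule$day_length - dt, by = dt)
  ee <- irradiance_at(schedule, tt)
  pp <- schedule$photoperiod
  pieces <- lapply(names(scenario$parameters), function(nm) {
    sp <- scenario$parameters[[nm]]
    v <- sp$baseline * .diel_shape(tt, pp, sp, scenario$ramp_frac)
    data.frame(time = tt, parameter = nm, value = v, irradiance = ee)
  })
  out <- do.call(rbind, pieces)
  if (scenario$noise_sd > 0) {
    mult <- .with_seed_opt(
      scenario$seed,
      1 + stats::rnorm(nrow(out), 0, scenario$noise_sd))
    out$value <- out$value * mult
  }
  class(out) <- c("diel_series", "data.frame")
  attr(out, "truth") <- scenario
  out
}

#' Simulate semi-continuous growth with periodic dilutions
#'
#' Exponential growth at rate `mu` sampled daily; whenever the
#' concentration exceeds the upper threshold it is reset to the lower
#' threshold (a dilution with fresh medium) and the census is flagged.
#'
#' @param c0 Starting concentration, cells mL^-1 (> 0).
#' @param mu Specific growth rate, day^-1.
#' @param days Number of days to simulate (>= 1).
#' @param dilution_thresholds Length-2 numeric `(lower, upper)` working
#'   band, or `NULL` for no dilutions.
#' @param dt Census interval, days (default 1).
#' @return data.frame with columns `t`, `c`, `dilution_flag`.
#' @export
simulate_growth <- function(c0, mu, days, dilution_thresholds = c(1e6, 2e6),
                            dt = 1) {
  .assert(.is_num(c0) && c0 > 0, "c0 must be > 0")
  .assert(.is_num(mu), "mu must be a single number")
  .assert(.is_num(days) && days >= 1, "days must be >= 1")
  if (!is.null(dilution_thresholds)) {
    .assert(is.numeric(dilution_thresholds) &&
              length(dilution_thresholds) == 2 &&
              dilution_thresholds[1] > 0 &&
              dilution_thresholds[1] < dilution_thresholds[2],
            "dilution thresholds must be an ordered positive pair")
  }
  tt <- seq(0, days, by = dt)
  cc <- numeric(length(tt))
  flag <- logical(length(tt))
  cc[1] <- c0
  for (i in seq_along(tt)[-1]) {
    cur <- cc[i - 1] * exp(mu * dt)
    if (!is.null(dilution_thresholds) && cur > dilution_thresholds[2]) {
      cur <- dilution_thresholds[1]
      flag[i] <- TRUE
    }
    cc[i] <- cur
  }
  data.frame(t = tt, c = cc, dilution_flag = flag)
}
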