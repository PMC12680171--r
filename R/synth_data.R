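#' Configuration for the synthetic two-structure recording
#'
#' Describes a simulated recording from two interconnected structures ("A",
#' "B"): log-normal background rates, a shared slow rate modulation, planted
#' assemblies (member co-activations within a brief timescale at a fixed
#' incidence, with partial member recruitment), and downstream reader units
#' that respond to those co-activations. Defaults encode the study
#' conditions the pipeline targets: 30 units per structure, 30-min epochs,
#' ~1 Hz median background rate, 15-ms assembly timescale, ~1.5 Hz
#' activation incidence, and collective readers discharging ~20 ms after
#' activations.
#'
#' @param n_units_a,n_units_b units per structure; A-units get ids
#'   `1..n_units_a`, B-units follow.
#' @param duration_s epoch duration in seconds.
#' @param rate_meanlog,rate_sdlog log-normal parameters of per-unit
#'   background rates (Hz).
#' @param mod_amplitude,mod_freq_hz shared sinusoidal rate modulation
#'   (amplitude in `[0, 1)`, frequency in Hz); mimics the slow global
#'   fluctuations of sleep shared across structures.
#' @param assemblies list of assemblies; each a list with `members` (A-unit
#'   ids), `timescale_ms`, `incidence_hz`, `p_recruit` (per-member
#'   recruitment probability), created by [synth_assembly()].
#' @param readers list of readers; each a list with `unit` (B-unit id),
#'   `assembly` (index into `assemblies`), `delay_mean_ms`, `delay_sd_ms`,
#'   `mode` ("collective", "independent" or "coincidence"), and for
#'   collective readers the sigmoid recruitment dependence (`midpoint` on
#'   the active fraction, `steepness`, `p_max`); for the other modes `p_max`
#'   is the per-trigger response probability. Created by [synth_reader()].
#' @param plasticity named numeric vector of per-reader multipliers applied
#'   to `p_max` in the "post" epoch of [generate_pre_post()] (names = reader
#'   indices); `NULL` for none.
#' @param seed integer RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_units_a = 30, n_units_b = 30, duration_s = 1800,
                         rate_meanlog = log(1), rate_sdlog = 0.5,
                         mod_amplitude = 0.3, mod_freq_hz = 0.8,
                         assemblies = NULL, readers = NULL,
                         plasticity = NULL, seed = 1L) {
  if (is.null(assemblies)) {
    assemblies <- lapply(0:4, function(k)
      synth_assembly(members = (5 * k + 1):(5 * k + 5)))
  }
  if (is.null(readers)) {
    readers <- lapply(seq_along(assemblies), function(k)
      synth_reader(unit = n_units_a + k, assembly = k))
  }
  stopifnot(mod_amplitude >= 0, mod_amplitude < 1)
  for (a in assemblies) {
    stopifnot(all(a$members >= 1 & a$members <= n_units_a),
              a$p_recruit >= 0, a$p_recruit <= 1)
  }
  for (r in readers) {
    if (r$unit <= n_units_a || r$unit > n_units_a + n_units_b)
      stop("reader units must belong to structure B")
    if (any(vapply(assemblies, function(a) r$unit %in% a$members, logical(1))))
      stop("unit assigned both member and reader roles")
  }
  structure(list(n_units_a = n_units_a, n_units_b = n_units_b,
                 duration_s = duration_s, rate_meanlog = rate_meanlog,
                 rate_sdlog = rate_sdlog, mod_amplitude = mod_amplitude,
                 mod_freq_hz = mod_freq_hz, assemblies = assemblies,
                 readers = readers, plasticity = plasticity,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @rdname synth_config
#' @param members,timescale_ms,incidence_hz,p_recruit,jitter see
#'   `assemblies` above; `jitter` defaults to uniform within the timescale.
#' @export
synth_assembly <- function(members, timescale_ms = 15, incidence_hz = 1.5,
                           p_recruit = 0.75) {
  list(members = as.integer(members), timescale_ms = timescale_ms,
       incidence_hz = incidence_hz, p_recruit = p_recruit)
}

#' @rdname synth_config
#' @param unit,assembly,delay_mean_ms,delay_sd_ms,midpoint,steepness,p_max,mode
#'   see `readers` above.
#' @export
synth_reader <- function(unit, assembly, delay_mean_ms = 20, delay_sd_ms = 3,
                         midpoint = 0.4, steepness = 10, p_max = 0.6,
                         mode = c("collective", "independent", "coincidence")) {
  mode <- match.arg(mode)
  stopifnot(p_max >= 0, p_max <= 1, delay_mean_ms > 0)
  list(unit = as.integer(unit), assembly = as.integer(assembly),
       delay_mean_ms = delay_mean_ms, delay_sd_ms = delay_sd_ms,
       midpoint = midpoint, steepness = steepness, p_max = p_max, mode = mode)
}

# inhomogeneous Poisson by thinning; rate(t) = r * (1 + amp * sin(2*pi*f*t))
.sim_poisson_mod <- function(rate, t0, t1, amp, freq) {
  if (rate <= 0) return(numeric(0))
  rmax <- rate * (1 + amp)
  n <- stats::rpois(1, rmax * (t1 - t0))
  if (!n) return(numeric(0))
  t <- sort(stats::runif(n, t0, t1))
  keep <- stats::runif(n) < (1 + amp * sin(2 * pi * freq * t)) / (1 + amp)
  t[keep]
}

# one epoch of the generative model; returns spike df + truth pieces
.sim_epoch <- function(config, t0, t1, rates, p_max_mult = NULL) {
  amp <- config$mod_amplitude; freq <- config$mod_freq_hz
  n_tot <- config$n_units_a + config$n_units_b
  sp_unit <- list(); sp_time <- list()
  for (u in seq_len(n_tot)) {
    t <- .sim_poisson_mod(rates[u], t0, t1, amp, freq)
    sp_unit[[u]] <- rep(u, length(t)); sp_time[[u]] <- t
  }
  events <- vector("list", length(config$assemblies))
  for (k in seq_along(config$assemblies)) {
    a <- config$assemblies[[k]]
    ts <- a$timescale_ms / 1000
    n_ev <- stats::rpois(1, a$incidence_hz * (t1 - t0))
    ev_t <- sort(stats::runif(n_ev, t0 + ts, t1 - ts - 0.1))
    recr <- vector("list", length(ev_t))
    for (j in seq_along(ev_t)) {
      r <- which(stats::runif(length(a$members)) < a$p_recruit)
      while (!length(r)) r <- which(stats::runif(length(a$members)) < a$p_recruit)
      recr[[j]] <- a$members[r]
      jit <- stats::runif(length(r), -ts / 2, ts / 2)
      sp_unit[[length(sp_unit) + 1]] <- a$members[r]
      sp_time[[length(sp_time) + 1]] <- ev_t[j] + jit
    }
    events[[k]] <- list(times = ev_t, recruited = recr)
  }
  for (ri in seq_along(config$readers)) {
    r <- config$readers[[ri]]
    a <- config$assemblies[[r$assembly]]
    p_max <- r$p_max * if (is.null(p_max_mult)) 1 else p_max_mult[ri]
    if (p_max > 1) { warning("response probability clipped to 1"); p_max <- 1 }
    ts <- a$timescale_ms / 1000
    rt <- numeric(0)
    if (r$mode == "collective") {
      ev <- events[[r$assembly]]
      for (j in seq_along(ev$times)) {
        frac <- length(ev$recruited[[j]]) / length(a$members)
        p <- p_max * stats::plogis(r$steepness * (frac - r$midpoint))
        if (stats::runif(1) < p)
          rt <- c(rt, ev$times[j] + stats::rnorm(1, r$delay_mean_ms, r$delay_sd_ms) / 1000)
      }
    } else if (r$mode == "independent") {
      all_u <- unlist(sp_unit); all_t <- unlist(sp_time)
      msp <- sort(all_t[all_u %in% a$members])
      fire <- msp[stats::runif(length(msp)) < p_max]
      if (length(fire))
        rt <- fire + stats::rnorm(length(fire), r$delay_mean_ms, r$delay_sd_ms) / 1000
    } else { # coincidence: consecutive spikes from two distinct members within ts
      all_u <- unlist(sp_unit); all_t <- unlist(sp_time)
      sel <- all_u %in% a$members
      mu <- all_u[sel]; mt <- all_t[sel]
      o <- order(mt); mu <- mu[o]; mt <- mt[o]
      if (length(mt) > 1) {
        hit <- which(diff(mt) <= ts & mu[-1] != mu[-length(mu)])
        hit <- hit[stats::runif(length(hit)) < p_max]
        if (length(hit))
          rt <- mt[hit + 1] + stats::rnorm(length(hit), r$delay_mean_ms, r$delay_sd_ms) / 1000
      }
    }
    rt <- rt[rt >= t0 & rt < t1]
    sp_unit[[length(sp_unit) + 1]] <- rep(r$unit, length(rt))
    sp_time[[length(sp_time) + 1]] <- rt
  }
  list(unit = unlist(sp_unit), time = unlist(sp_time), events = events)
}

.unit_table <- function(config) {
  data.frame(unit = seq_len(config$n_units_a + config$n_units_b),
             structure = c(rep("A", config$n_units_a), rep("B", config$n_units_b)))
}

#' Generate one synthetic session
#'
#' Background spikes follow an inhomogeneous Poisson process (per-unit
#' log-normal rate times a shared sinusoidal modulation). At each planted
#' assembly activation, each member is recruited with probability
#' `p_recruit` (at least one member per event) and emits one spike jittered
#' uniformly within the assembly timescale around the event time. Reader
#' spikes are added on top of the reader's background train: "collective"
#' readers fire once per activation with a sigmoid probability in the
#' recruited fraction, at event time + Normal(delay); "independent" readers
#' fire after every member spike with probability `p_max`; "coincidence"
#' readers fire after consecutive spikes of two distinct members within the
#' timescale. Identical seeds give identical output.
#'
#' @param config a [synth_config()].
#' @param session_id,animal_id labels stamped on the output.
#' @return list with `spikes` (a [spike_data()]), `epochs` (an
#'   [interval_set()] with one epoch `[0, duration_s)`), and `truth` (ground
#'   truth manifest: per-assembly event times and recruited member sets,
#'   planted member sets, reader couplings).
#' @export
generate_session <- function(config, session_id = "s1", animal_id = "a1") {
  stopifnot(inherits(config, "synth_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  n_tot <- config$n_units_a + config$n_units_b
  rates <- stats::rlnorm(n_tot, config$rate_meanlog, config$rate_sdlog)
  ep <- .sim_epoch(config, 0, config$duration_s, rates)
  ut <- .unit_table(config)
  sd <- spike_data(ep$unit, ep$time, stats::setNames(ut$structure, ut$unit),
                   session_id = session_id, animal_id = animal_id)
  truth <- list(
    assemblies = lapply(config$assemblies, function(a)
      list(members = a$members, timescale_ms = a$timescale_ms,
           incidence_hz = a$incidence_hz)),
    events = ep$events,
    readers = config$readers,
    rates = rates,
    epoch_labels = "pre")
  list(spikes = sd, epochs = interval_set(0, config$duration_s), truth = truth)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a nested cohort of sessions
#'
#' Animals get a random rate offset (on the log scale) shared by all their
#' sessions, inducing the nested correlation structure the hierarchical
#' bootstrap must respect. Session seeds are derived deterministically from
#' the config seed and the (animal, session) index.
#'
#' @param config a [synth_config()]; its `seed` anchors the cohort.
#' @param n_animals,n_sessions cohort shape (default 4 animals x 5 sessions,
#'   the natural scale for this kind of study).
#' @param animal_sd standard deviation of the per-animal log-rate offset.
#' @return list of sessions (each as in [generate_session()]), with
#'   `animal`/`session` labels set.
#' @export
generate_cohort <- function(config, n_animals = 4, n_sessions = 5, animal_sd = 0.2) {
  stopifnot(n_animals >= 1, n_sessions >= 1)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  offsets <- stats::rnorm(n_animals, 0, animal_sd)
  out <- list()
  for (a in seq_len(n_animals)) for (s in seq_len(n_sessions)) {
    cfg <- config
    cfg$rate_meanlog <- config$rate_meanlog + offsets[a]
    cfg$seed <- (config$seed + 7919L * a + 104729L * s) %% .Machine$integer.max
    out[[length(out) + 1]] <- generate_session(cfg, session_id = paste0("s", s),
                                               animal_id = paste0("a", a))
  }
  out
}

#' Generate matched pre/post epochs with planted coupling changes
#'
#' Runs the identical generative process in two consecutive epochs, except
#' that in the "post" epoch each reader's response probability is scaled by
#' its plasticity multiplier (`config$plasticity`, default 1). Multipliers
#' pushing the probability above 1 are clipped with a warning.
#'
#' @param config a [synth_config()].
#' @param gap_s silent gap between the two epochs (seconds).
#' @return list with `spikes`, `epochs` (two intervals: pre then post), and
#'   `truth` (with `events_pre`, `events_post`, `epoch_labels`).
#' @export
generate_pre_post <- function(config, gap_s = 60) {
  stopifnot(inherits(config, "synth_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  n_tot <- config$n_units_a + config$n_units_b
  rates <- stats::rlnorm(n_tot, config$rate_meanlog, config$rate_sdlog)
  mult <- rep(1, length(config$readers))
  if (!is.null(config$plasticity)) {
    ix <- as.integer(names(config$plasticity))
    mult[ix] <- as.numeric(config$plasticity)
  }
  dur <- config$duration_s
  pre <- .sim_epoch(config, 0, dur, rates)
  post <- .sim_epoch(config, dur + gap_s, 2 * dur + gap_s, rates, p_max_mult = mult)
  ut <- .unit_table(config)
  sd <- spike_data(c(pre$unit, post$unit), c(pre$time, post$time),
                   stats::setNames(ut$structure, ut$unit))
  epochs <- interval_set(c(0, dur + gap_s), c(dur, 2 * dur + gap_s))
  truth <- list(
    assemblies = lapply(config$assemblies, function(a)
      list(members = a$members, timescale_ms = a$timescale_ms,
           incidence_hz = a$incidence_hz)),
    events_pre = pre$events, events_post = post$events,
    readers = config$readers, multipliers = mult, rates = rates,
    epoch_labels = c("pre", "post"))
  list(spikes = sd, epochs = epochs, truth = truth)
}
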