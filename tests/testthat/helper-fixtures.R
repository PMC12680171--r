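# Shared fixtures, built once per test run and memoized.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small single-assembly session: 20 units (10 A + 10 B), one 4-member
# assembly with a collective reader, 10 minutes
small_session <- function() fixture("small_session", function() {
  cfg <- synth_config(seed = 101, n_units_a = 10, n_units_b = 10,
                      duration_s = 600,
                      assemblies = list(synth_assembly(1:4)),
                      readers = list(synth_reader(11, 1)))
  ses <- generate_session(cfg)
  ses$Z <- bin_and_zscore(ses$spikes, ses$epochs)
  ses$assemblies <- filter_mixed_sign(detect_assemblies(ses$Z))$kept
  ia <- which(vapply(ses$assemblies, function(a)
    length(intersect(a$members, 1:4)) >= 3, logical(1)))[1]
  ses$planted <- ses$assemblies[[ia]]
  ses$series <- extract_activation_events(
    activation_strength(ses$spikes, ses$planted, ses$epochs), ses$spikes)
  ses
})

# pure Poisson spike_data (no assemblies), n units at `rate` Hz
poisson_spikes <- function(n_units, duration_s, rate = 2, seed = 1) {
  set.seed(seed)
  u <- integer(0); t <- numeric(0)
  for (i in seq_len(n_units)) {
    ti <- sort(runif(rpois(1, rate * duration_s), 0, duration_s))
    u <- c(u, rep(i, length(ti))); t <- c(t, ti)
  }
  spike_data(u, t, stats::setNames(rep("A", n_units), seq_len(n_units)))
}

# hand-made assembly_model
make_assembly <- function(weights, units = seq_along(weights), timescale = 15) {
  w <- weights / sqrt(sum(weights^2))
  if (w[which.max(abs(w))] < 0) w <- -w
  names(w) <- units
  ot <- otsu_members(w)
  members <- as.integer(ot$members)
  sgn <- sign(w[as.character(members)])
  structure(list(weights = w, members = members,
                 otsu_threshold = ot$threshold,
                 effectiveness = ot$effectiveness, timescale_ms = timescale,
                 sign_valid = all(sgn > 0) || all(sgn < 0), id = 1L),
            class = "assembly_model")
}
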