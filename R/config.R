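#' Build a model configuration
#'
#' Assembles the full parameter set of a simulation run. Every argument has a
#' default; the defaults are the study conditions under which the model's
#' landscape-scale behaviour is characterised. A run is fully specified by a
#' configuration plus its `seed`.
#'
#' @param grid_width,grid_height Patch counts of the rectangular landscape.
#'   The 33 x 33 default (1089 parcels) with a mean parcel of 35.5 ha puts
#'   roughly 38,700 ha of woodland on the landscape.
#' @param n_foresters Number of professional foresters on the landscape.
#' @param n_peer_leaders Number of conservation-trained peer leaders.
#' @param forester_visits_range Integer interval `c(lo, hi)`; each forester's
#'   landowner visits per year is drawn once, at initialization, uniformly
#'   from this interval. Private licensed foresters work with 50-100 clients
#'   annually, hence the default. Values anywhere in 10-500 are permitted.
#' @param peer_visits_range As above for peer leaders (default 1-5 referrals
#'   per year).
#' @param opinion_type Valence of the opinion landowners spread among
#'   themselves: `"positive"`, `"negative"`, or `"neutral"`.
#' @param n_ticks Run length in years.
#' @param burn_in Initial ticks excluded from harvest summaries, discounting
#'   the initial pulse of mature-forest harvesting.
#' @param trust_lock_high,trust_lock_low Thresholds for permanent trust
#'   conversion: trust above `trust_lock_high` (below `trust_lock_low`) for
#'   `trust_lock_window` consecutive ticks locks the channel at 1 (at 0).
#' @param trust_lock_window Consecutive-tick window for locking.
#' @param forester_trust_up_max,forester_trust_down_max Upper bounds of the
#'   uniform trust increments a forester visit applies (gain is drawn from
#'   U(0, 0.75), loss from U(0, 0.5): trust is won in larger steps than it is
#'   lost).
#' @param peer_trust_delta_max,peer_forester_boost_max,opinion_delta_max
#'   Upper bounds of the uniform increments used by peer-leader visits and
#'   community opinion spread (all default 1).
#' @param landowner_death_age Age at which a parcel passes to a new owner.
#' @param mature_age_softwood,mature_age_hardwood Stand age (years since
#'   harvest) at which a softwood / hardwood parcel is mature and ready.
#' @param precommercial_age Stand age from which pre-commercial thinning is
#'   possible.
#' @param area_unit_scale Multiplier applied to parcel area inside the
#'   harvest-predisposition equation (the printed coefficient 0.001 is per
#'   stored area unit; set this if areas should enter on another unit).
#' @param opinion_influence_mode `"trust_gated"` (an opinion lands with
#'   probability equal to the recipient's mean trust across the two channels)
#'   or `"always"`.
#' @param classify_by_owner If `FALSE` (default) a cut executed on a mature
#'   stand is counted sustainable regardless of the owner's disposition; if
#'   `TRUE` the owner's sustainability value decides the class.
#' @param turnover_redraws_all If `TRUE`, parcel turnover at death redraws all
#'   owner demographics; by default only the age is redrawn.
#' @param demographics Named list of initialization-distribution parameters;
#'   see [default_demographics()].
#' @param seed Integer seed; the single source of randomness for a run.
#'
#' @return A validated list of class `pwo_config`.
#' @seealso [run_model()], [init_landscape()], [read_config()]
#' @export
pwo_config <- function(grid_width = 33L,
                       grid_height = 33L,
                       n_foresters = 20L,
                       n_peer_leaders = 2L,
                       forester_visits_range = c(50L, 100L),
                       peer_visits_range = c(1L, 5L),
                       opinion_type = c("neutral", "positive", "negative"),
                       n_ticks = 80L,
                       burn_in = 10L,
                       trust_lock_high = 0.7,
                       trust_lock_low = 0.3,
                       trust_lock_window = 5L,
                       forester_trust_up_max = 0.75,
                       forester_trust_down_max = 0.5,
                       peer_trust_delta_max = 1.0,
                       peer_forester_boost_max = 1.0,
                       opinion_delta_max = 1.0,
                       landowner_death_age = 100,
                       mature_age_softwood = 40,
                       mature_age_hardwood = 60,
                       precommercial_age = 15,
                       area_unit_scale = 1.0,
                       opinion_influence_mode = c("trust_gated", "always"),
                       classify_by_owner = FALSE,
                       turnover_redraws_all = FALSE,
                       demographics = default_demographics(),
                       seed = 42L) {
  opinion_type <- match.arg(opinion_type)
  opinion_influence_mode <- match.arg(opinion_influence_mode)
  cfg <- list(
    grid_width = as.integer(grid_width),
    grid_height = as.integer(grid_height),
    n_foresters = as.integer(n_foresters),
    n_peer_leaders = as.integer(n_peer_leaders),
    forester_visits_range = as.integer(forester_visits_range),
    peer_visits_range = as.integer(peer_visits_range),
    opinion_type = opinion_type,
    n_ticks = as.integer(n_ticks),
    burn_in = as.integer(burn_in),
    trust_lock_high = trust_lock_high,
    trust_lock_low = trust_lock_low,
    trust_lock_window = as.integer(trust_lock_window),
    forester_trust_up_max = forester_trust_up_max,
    forester_trust_down_max = forester_trust_down_max,
    peer_trust_delta_max = peer_trust_delta_max,
    peer_forester_boost_max = peer_forester_boost_max,
    opinion_delta_max = opinion_delta_max,
    landowner_death_age = landowner_death_age,
    mature_age_softwood = mature_age_softwood,
    mature_age_hardwood = mature_age_hardwood,
    precommercial_age = precommercial_age,
    area_unit_scale = area_unit_scale,
    opinion_influence_mode = opinion_influence_mode,
    classify_by_owner = isTRUE(classify_by_owner),
    turnover_redraws_all = isTRUE(turnover_redraws_all),
    demographics = demographics,
    seed = as.integer(seed)
  )
  class(cfg) <- "pwo_config"
  validate_config(cfg)
}

#' Default initialization-distribution parameters for landowner demographics
#'
#' Moments of a mail survey of woodland owners: the harvesting ownership
#' objective `inct` is Poisson on 0-5 with (truncated) mean 2.66; owner age is
#' Normal(56.96, 12.68); years the land has been in the family is
#' Poisson(31.46); the residency class `live` (1 resident, 2 seasonal,
#' 3 absentee, 4 other) has mean 2.04, realised here as the categorical
#' probabilities `live_probs`; parcel size has mean 35.50 ha with sd 85.49 ha,
#' realised as a moment-matched log-normal (the sd being 2.4x the mean demands
#' a heavy right tail) floored at 0.4 ha.
#'
#' @return Named list of distribution parameters consumed by
#'   [draw_landowners()].
#' @export
default_demographics <- function() {
  list(
    inct_mean = 2.66, inct_max = 5L,
    age_mean = 56.96, age_sd = 12.68, age_min = 18,
    lngfam_mean = 31.46,
    live_probs = c(0.38, 0.30, 0.22, 0.10),
    ha_mean = 35.50, ha_sd = 85.49, ha_floor = 0.4,
    forest_age_max = 60L
  )
}

#' Validate a model configuration
#'
#' Checks range and ordering invariants (probabilities in \[0,1\], interval
#' ends ordered, burn-in shorter than the run, lock thresholds ordered) and
#' that the truncated-Poisson target for `inct` is attainable.
#'
#' @param cfg A `pwo_config` list.
#' @return The configuration, invisibly unchanged, if valid; otherwise an
#'   error of class `pwo_config_error`.
#' @export
validate_config <- function(cfg) {
  fail <- function(msg) stop(errorCondition(msg, class = c("pwo_config_error", "error")))
  pos_int <- function(x) length(x) == 1 && is.finite(x) && x >= 1
  if (!pos_int(cfg$grid_width) || !pos_int(cfg$grid_height)) {
    fail("grid_width and grid_height must be positive integers")
  }
  if (cfg$n_foresters < 0 || cfg$n_peer_leaders < 0) {
    fail("agent counts must be non-negative")
  }
  for (nm in c("forester_visits_range", "peer_visits_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || any(r < 1) || r[1] > r[2]) {
      fail(sprintf("%s must be an integer interval [lo, hi] with 1 <= lo <= hi", nm))
    }
  }
  if (cfg$n_ticks < 0) fail("n_ticks must be non-negative")
  if (cfg$burn_in < 0 || (cfg$n_ticks > 0 && cfg$burn_in >= cfg$n_ticks)) {
    fail("burn_in must be non-negative and smaller than n_ticks")
  }
  probs <- c(cfg$trust_lock_high, cfg$trust_lock_low)
  if (any(probs < 0 | probs > 1)) fail("trust-lock thresholds must be probabilities in [0,1]")
  if (cfg$trust_lock_low >= cfg$trust_lock_high) {
    fail("trust_lock_low must be strictly below trust_lock_high")
  }
  if (cfg$trust_lock_window < 1) fail("trust_lock_window must be a positive number of ticks")
  deltas <- c(cfg$forester_trust_up_max, cfg$forester_trust_down_max,
              cfg$peer_trust_delta_max, cfg$peer_forester_boost_max,
              cfg$opinion_delta_max)
  if (any(deltas < 0)) fail("trust increment bounds must be non-negative")
  if (cfg$landowner_death_age <= cfg$demographics$age_min) {
    fail("landowner_death_age must exceed the minimum drawn age")
  }
  if (cfg$precommercial_age > min(cfg$mature_age_softwood, cfg$mature_age_hardwood)) {
    fail("precommercial_age must not exceed the maturity thresholds")
  }
  d <- cfg$demographics
  if (abs(sum(d$live_probs) - 1) > 1e-8 || any(d$live_probs < 0)) {
    fail("live_probs must be a probability vector over the four residency classes")
  }
  if (d$inct_mean <= 0 || d$inct_mean >= d$inct_max) {
    fail("inct_mean must lie strictly between 0 and inct_max for the truncated Poisson")
  }
  invisible(cfg)
}

#' Calibrate a right-truncated Poisson rate to a target mean
#'
#' Finds the rate `lambda` such that a Poisson variable conditioned on being
#' at most `upper` has mean `target_mean`. Survey-derived scores reported as
#' "Poisson with mean m on 0..k" need this: sampling Poisson(m) and clipping
#' would bias the mean downward.
#'
#' @param target_mean Desired mean of the truncated variable.
#' @param upper Truncation point (inclusive); `Inf` returns `target_mean`
#'   itself.
#' @param tol Tolerance on the achieved mean.
#' @return The calibrated rate (a single number).
#' @export
#' @examples
#' calibrate_truncated_poisson(2.66, 5)
calibrate_truncated_poisson <- function(target_mean, upper, tol = 1e-9) {
  if (target_mean <= 0 || target_mean >= upper) {
    stop(errorCondition(
      "target_mean must lie strictly between 0 and upper",
      class = c("pwo_config_error", "error")
    ))
  }
  if (is.infinite(upper)) return(target_mean)
  trunc_mean <- function(lambda) {
    k <- 0:upper
    p <- stats::dpois(k, lambda)
    sum(k * p) / sum(p)
  }
  # truncated mean is increasing in lambda, from 0 toward upper
  hi <- target_mean + 1
  while (trunc_mean(hi) < target_mean) hi <- hi * 2
  stats::uniroot(function(l) trunc_mean(l) - target_mean,
                 lower = 1e-12, upper = hi, tol = tol)$root
}

# keys accepted in a config file, in pwo_config() argument order
config_file_keys <- function() {
  c("grid_width", "grid_height", "n_foresters", "n_peer_leaders",
    "forester_visits_range", "peer_visits_range", "opinion_type",
    "n_ticks", "burn_in", "trust_lock_high", "trust_lock_low",
    "trust_lock_window", "forester_trust_up_max", "forester_trust_down_max",
    "peer_trust_delta_max", "peer_forester_boost_max", "opinion_delta_max",
    "landowner_death_age", "mature_age_softwood", "mature_age_hardwood",
    "precommercial_age", "area_unit_scale", "opinion_influence_mode",
    "classify_by_owner", "turnover_redraws_all", "seed",
    names(default_demographics()))
}

#' Read a model configuration from a flat key/value file
#'
#' The file is YAML with one key per configuration field (demographic
#' parameters appear as top-level keys, e.g. `age_mean`). Omitted keys take
#' the package defaults; unknown keys are rejected rather than ignored so a
#' typo cannot silently run the default.
#'
#' @param path Path to the file.
#' @param seed Optional seed overriding the file's `seed` key.
#' @return A validated `pwo_config`.
#' @export
read_config <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("config file not found: ", path),
                        class = c("pwo_config_error", "error")))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_file_keys())
  if (length(unknown)) {
    stop(errorCondition(
      paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
      class = c("pwo_config_error", "error")
    ))
  }
  demo <- default_demographics()
  demo_keys <- intersect(names(raw), names(demo))
  demo[demo_keys] <- raw[demo_keys]
  args <- raw[setdiff(names(raw), demo_keys)]
  args$demographics <- demo
  if (!is.null(seed)) args$seed <- seed
  do.call(pwo_config, args)
}

#' Write the resolved run manifest
#'
#' Records the full configuration, seed, and package version next to a run's
#' outputs as flat key/value text so any output file can be traced back to the
#' exact conditions that produced it.
#'
#' @param cfg A `pwo_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, path) {
  flat <- cfg[setdiff(names(cfg), "demographics")]
  flat <- c(flat, cfg$demographics,
            list(pwosim_version = as.character(utils::packageVersion("pwosim"))))
  lines <- vapply(names(flat), function(k) {
    paste0(k, ": ", paste(format(flat[[k]], digits = 15), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
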