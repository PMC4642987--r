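#' Stand readiness from forest age and type
#'
#' Deterministically classifies a stand as not ready (0), ready for
#' pre-commercial thinning (1), or mature and ready (2). Softwood matures
#' faster than hardwood (defaults 40 vs 60 years since last harvest);
#' thinning becomes possible at `precommercial_age` (default 15).
#'
#' @param forest_age Years since the stand was last harvested (vectorised).
#' @param forest_type 0 for hardwood-dominated, 1 for softwood-dominated
#'   (vectorised, recycled against `forest_age`).
#' @param cfg A `pwo_config` supplying the thresholds.
#' @return Integer vector of readiness codes in `{0, 1, 2}`.
#' @export
harvestability_from_age <- function(forest_age, forest_type, cfg) {
  mature_at <- ifelse(forest_type == 1L, cfg$mature_age_softwood, cfg$mature_age_hardwood)
  out <- integer(length(forest_age))
  out[forest_age >= cfg$precommercial_age] <- 1L
  out[forest_age >= mature_at] <- 2L
  out
}

#' Draw landowner-parcel agents from the survey-derived distributions
#'
#' Draws `n` independent owners/parcels: harvest objective `inct` from a
#' Poisson right-truncated to 0..5 with its rate calibrated so the truncated
#' mean equals the survey mean; owner age from a clamped normal; family
#' tenure from a Poisson; residency class from the categorical convention in
#' [default_demographics()]; parcel area from a moment-matched log-normal;
#' stand age uniform on 0..60 with a fair hardwood/softwood split; initial
#' sustainability disposition a fair coin; both trust channels (and the
#' stored-but-unused psychological distance) uniform on (0,1).
#'
#' Draws consume the current R random stream, one field at a time in column
#' order, so a fixed seed reproduces the table exactly.
#'
#' @param n Number of agents to draw.
#' @param cfg A `pwo_config`.
#' @return A data.frame with one row per agent and all initialization fields.
#' @export
draw_landowners <- function(n, cfg) {
  d <- cfg$demographics
  lambda <- calibrate_truncated_poisson(d$inct_mean, d$inct_max)
  k <- 0:d$inct_max
  inct_p <- stats::dpois(k, lambda)
  data.frame(
    inct = sample(k, n, replace = TRUE, prob = inct_p),
    age = draw_owner_age(n, cfg),
    lngfam = stats::rpois(n, d$lngfam_mean),
    live = sample.int(4L, n, replace = TRUE, prob = d$live_probs),
    ha = draw_parcel_area(n, d),
    forest_age = sample(0:d$forest_age_max, n, replace = TRUE),
    forest_type = stats::rbinom(n, 1L, 0.5),
    sustainability = stats::rbinom(n, 1L, 0.5),
    forester_trust = stats::runif(n),
    peer_trust = stats::runif(n),
    psychdist = stats::runif(n)
  )
}

draw_owner_age <- function(n, cfg) {
  d <- cfg$demographics
  pmin(pmax(stats::rnorm(n, d$age_mean, d$age_sd), d$age_min),
       cfg$landowner_death_age - 1)
}

draw_parcel_area <- function(n, d) {
  # log-normal with first two moments matched to (ha_mean, ha_sd)
  s2 <- log(1 + (d$ha_sd / d$ha_mean)^2)
  mu <- log(d$ha_mean) - s2 / 2
  pmax(stats::rlnorm(n, meanlog = mu, sdlog = sqrt(s2)), d$ha_floor)
}

# Moore (8-cell) neighbourhood as an n x 8 index matrix (NA-padded at edges),
# patches numbered row-major.
moore_neighbours <- function(width, height) {
  n <- width * height
  row <- (seq_len(n) - 1L) %/% width + 1L
  col <- (seq_len(n) - 1L) %% width + 1L
  offs <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  nb <- matrix(NA_integer_, n, 8L)
  for (j in seq_len(8L)) {
    r <- row + offs[j, "dr"]
    c <- col + offs[j, "dc"]
    ok <- r >= 1L & r <= height & c >= 1L & c <= width
    nb[ok, j] <- (r[ok] - 1L) * width + c[ok]
  }
  # left-compact each row so neighbour k of patch i is nb[i, k], k <= deg[i]
  deg <- rowSums(!is.na(nb))
  comp <- t(vapply(seq_len(n), function(i) {
    v <- nb[i, !is.na(nb[i, ])]
    length(v) <- 8L
    v
  }, integer(8L)))
  list(idx = comp, deg = deg)
}

#' Initialize a landscape
#'
#' Draws the full grid of landowner parcels plus the influencer roster. Each
#' forester's (peer leader's) visits-per-year is drawn once, uniformly from
#' the configured range, and is fixed for the run. The same configuration and
#' seed always reproduce the identical landscape.
#'
#' @param cfg A `pwo_config`. The caller is responsible for seeding (see
#'   [run_model()], which seeds from `cfg$seed`).
#' @return A list of class `pwo_landscape`: per-patch state vectors in
#'   row-major patch order, the influencer visit rosters, and the
#'   precomputed adjacency used by local opinion sharing.
#' @export
init_landscape <- function(cfg) {
  validate_config(cfg)
  n <- cfg$grid_width * cfg$grid_height
  own <- draw_landowners(n, cfg)
  forester_visits <- if (cfg$n_foresters > 0) {
    sample(cfg$forester_visits_range[1]:cfg$forester_visits_range[2],
           cfg$n_foresters, replace = TRUE)
  } else integer(0)
  peer_visits <- if (cfg$n_peer_leaders > 0) {
    sample(cfg$peer_visits_range[1]:cfg$peer_visits_range[2],
           cfg$n_peer_leaders, replace = TRUE)
  } else integer(0)
  nb <- moore_neighbours(cfg$grid_width, cfg$grid_height)
  ls <- list(
    n = n,
    width = cfg$grid_width,
    height = cfg$grid_height,
    row = (seq_len(n) - 1L) %/% cfg$grid_width,
    col = (seq_len(n) - 1L) %% cfg$grid_width,
    inct = own$inct,
    age = own$age,
    lngfam = own$lngfam,
    live = own$live,
    ha = own$ha,
    forest_age = own$forest_age,
    forest_type = own$forest_type,
    harvestability = harvestability_from_age(own$forest_age, own$forest_type, cfg),
    sustainability = own$sustainability,
    forester_trust = own$forester_trust,
    peer_trust = own$peer_trust,
    psychdist = own$psychdist,
    # lock state: 0 unlocked, 1 locked high, -1 locked low
    f_lock = integer(n),
    p_lock = integer(n),
    consec_high_f = integer(n),
    consec_low_f = integer(n),
    consec_high_p = integer(n),
    consec_low_p = integer(n),
    harvest_decision = logical(n),
    patch_harvested = logical(n),
    # 0 none, 1 sustainable, 2 unsustainable
    harvest_class = integer(n),
    forester_visits = forester_visits,
    peer_visits = peer_visits,
    nb_idx = nb$idx,
    nb_deg = nb$deg
  )
  class(ls) <- "pwo_landscape"
  ls
}

#' @export
print.pwo_landscape <- function(x, ...) {
  cat(sprintf("<pwo_landscape> %d x %d grid (%d parcels, %.0f ha), %d foresters, %d peer leaders\n",
              x$height, x$width, x$n, sum(x$ha),
              length(x$forester_visits), length(x$peer_visits)))
  invisible(x)
}
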