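#' Linear predictor of the harvest predisposition
#'
#' Affine score from the harvest-intention logistic regression fitted to a
#' landowner survey; coefficients are taken as given:
#' `H = -3.065 + 0.001 A - 0.30 L + 0.282 I + 0.03 AG + 0.01 F`.
#'
#' @param A Parcel area (ha, after any unit scaling).
#' @param L Residency class (1 resident ... 4 other).
#' @param I Timber-harvesting ownership objective score (0-5).
#' @param AG Owner age in years.
#' @param F_ Years the land has been in the family.
#' @return The linear predictor (vectorised).
#' @export
linear_predictor <- function(A, L, I, AG, F_) {
  -3.065 + 0.001 * A - 0.30 * L + 0.282 * I + 0.03 * AG + 0.01 * F_
}

#' Reset per-tick state and advance ages
#'
#' First step of every tick: clears last year's harvest flags and intent,
#' ages owners by one year (an owner reaching the death age passes the parcel
#' on, redrawing the owner's age -- or the full demographic profile if
#' `turnover_redraws_all` is set), grows every stand by one year, and
#' recomputes stand readiness.
#'
#' @param ls A `pwo_landscape`.
#' @param cfg A `pwo_config`.
#' @return The updated landscape.
#' @export
reset_and_age <- function(ls, cfg) {
  ls$patch_harvested[] <- FALSE
  ls$harvest_class[] <- 0L
  ls$harvest_decision[] <- FALSE
  ls$age <- ls$age + 1
  dead <- which(ls$age >= cfg$landowner_death_age)
  if (length(dead)) {
    if (cfg$turnover_redraws_all) {
      new <- draw_landowners(length(dead), cfg)
      for (f in c("inct", "age", "lngfam", "live", "psychdist")) {
        ls[[f]][dead] <- new[[f]]
      }
    } else {
      ls$age[dead] <- draw_owner_age(length(dead), cfg)
    }
  }
  ls$forest_age <- ls$forest_age + 1L
  ls$harvestability <- harvestability_from_age(ls$forest_age, ls$forest_type, cfg)
  ls
}

#' Pre-interaction harvest decision
#'
#' Converts the linear predictor to a probability through the logistic link,
#' then applies the model's asymmetric draw: a uniform number on (0.5, 1) is
#' compared against the probability, so an owner forms harvest intent with
#' probability `max(0, 2p - 1)` -- only owners whose predisposition exceeds
#' one half can decide to harvest before any interaction.
#'
#' @inheritParams reset_and_age
#' @return The landscape with `harvest_decision` set.
#' @export
pre_interaction_decision <- function(ls, cfg) {
  H <- linear_predictor(ls$ha * cfg$area_unit_scale, ls$live, ls$inct,
                        ls$age, ls$lngfam)
  p <- stats::plogis(H)
  u <- stats::runif(ls$n, 0.5, 1)
  ls$harvest_decision <- u < p
  ls
}

#' One trust-experience update
#'
#' The visit's experience is positive with probability equal to the current
#' trust itself: if `u_gate < trust` the channel gains `u_inc * up_max`,
#' otherwise it loses `u_inc * down_max`. Exposed separately so the drift of
#' the rule (zero expected change at `trust = down_max / (up_max + down_max)`
#' before clamping) can be examined directly.
#'
#' @param trust Current trust value(s).
#' @param u_gate,u_inc Uniform(0,1) draws (vectorised with `trust`).
#' @param up_max,down_max Upper bounds of the uniform gain and loss.
#' @param clamp Clamp the result into \[0,1\] (the model always does).
#' @return Updated trust value(s).
#' @export
trust_experience <- function(trust, u_gate, u_inc, up_max, down_max, clamp = TRUE) {
  out <- ifelse(u_gate < trust, trust + u_inc * up_max, trust - u_inc * down_max)
  if (clamp) out <- pmin(1, pmax(0, out))
  out
}

# k-th occurrence index of each value in `x`, in original order. Visits that
# hit the same patch repeatedly within a tick are applied in arrival order by
# sweeping occurrence "rounds"; within a round all targets are distinct so the
# update is vectorised yet identical to strictly sequential application
# (every random draw is made per visit, up front, in visit order).
occurrence_index <- function(x) {
  o <- order(x, method = "radix")
  occ <- integer(length(x))
  occ[o] <- sequence(rle(x[o])$lengths)
  occ
}

#' Forester visits
#'
#' Applies a batch of forester visits (one element of `targets` per visit, in
#' visit order). Each visit runs three trust-gated sub-steps on the visited
#' owner: (a) with probability equal to the owner's forester trust, the
#' sustainability value is set to 1; (b) if the stand is mature, with the same
#' gate the harvest intent is set; (c) the visit experience moves forester
#' trust up by U(0, 0.75) or down by U(0, 0.5) via [trust_experience()].
#' Locked trust channels keep their value but still gate (a) and (b).
#'
#' @param ls A `pwo_landscape`.
#' @param targets Integer patch indices visited, in order.
#' @param cfg A `pwo_config`.
#' @return The updated landscape.
#' @export
forester_interaction <- function(ls, targets, cfg) {
  m <- length(targets)
  if (m == 0) return(ls)
  u1 <- stats::runif(m)
  u2 <- stats::runif(m)
  u3 <- stats::runif(m)
  uinc <- stats::runif(m)
  occ <- occurrence_index(targets)
  for (r in seq_len(max(occ))) {
    sel <- which(occ == r)
    t <- targets[sel]
    ft <- ls$forester_trust[t]
    ls$sustainability[t[u1[sel] < ft]] <- 1L
    hit <- ls$harvestability[t] == 2L & u2[sel] < ft
    ls$harvest_decision[t[hit]] <- TRUE
    unlocked <- ls$f_lock[t] == 0L
    newt <- trust_experience(ft, u3[sel], uinc[sel],
                             cfg$forester_trust_up_max,
                             cfg$forester_trust_down_max)
    ls$forester_trust[t[unlocked]] <- newt[unlocked]
  }
  ls
}

#' Peer-leader visits
#'
#' Applies a batch of peer-leader visits (one element of `targets` per visit,
#' in visit order). Each visit runs three sub-steps gated by the owner's
#' peer-leader trust: (a) the sustainability value is set to 1; (b) peer
#' trust itself moves up or down by U(0, 1) via [trust_experience()]; (c)
#' because peer leaders speak well of foresters, forester trust is boosted by
#' U(0, 1) -- it never decreases through this channel. Peer leaders never
#' touch the harvest decision. Locked channels keep their value.
#'
#' @inheritParams forester_interaction
#' @return The updated landscape.
#' @export
peer_leader_interaction <- function(ls, targets, cfg) {
  m <- length(targets)
  if (m == 0) return(ls)
  u1 <- stats::runif(m)
  u2 <- stats::runif(m)
  u3 <- stats::runif(m)
  inc1 <- stats::runif(m)
  inc2 <- stats::runif(m)
  occ <- occurrence_index(targets)
  for (r in seq_len(max(occ))) {
    sel <- which(occ == r)
    t <- targets[sel]
    pt <- ls$peer_trust[t]
    ls$sustainability[t[u1[sel] < pt]] <- 1L
    unlocked_p <- ls$p_lock[t] == 0L
    newp <- trust_experience(pt, u2[sel], inc1[sel],
                             cfg$peer_trust_delta_max, cfg$peer_trust_delta_max)
    ls$peer_trust[t[unlocked_p]] <- newp[unlocked_p]
    pt_now <- ls$peer_trust[t]
    boost <- u3[sel] < pt_now & ls$f_lock[t] == 0L
    tb <- t[boost]
    ls$forester_trust[tb] <- pmin(1, ls$forester_trust[tb] +
                                    inc2[sel][boost] * cfg$peer_forester_boost_max)
  }
  ls
}

#' Community opinion spread
#'
#' Rumor-mill style information sharing: every owner, in row-major order,
#' flips a fair coin and shares an opinion either with a uniformly random
#' *other* owner anywhere on the landscape or with a uniformly random
#' Moore-adjacent neighbour (never both). Under the default `trust_gated`
#' mode the opinion lands with probability equal to the recipient's mean
#' trust across the two channels; a landed positive (negative) opinion raises
#' (lowers) both of the recipient's trusts by U(0, 1), clamped; a neutral
#' opinion changes nothing. Harvest decisions are never touched; locked
#' channels keep their value. A single-patch landscape has no valid target
#' and is returned unchanged.
#'
#' @inheritParams reset_and_age
#' @return The updated landscape.
#' @export
community_opinion_step <- function(ls, cfg) {
  n <- ls$n
  if (n < 2) return(ls)
  ucoin <- stats::runif(n)
  utar <- stats::runif(n)
  ugate <- stats::runif(n)
  udelta <- stats::runif(n)
  if (cfg$opinion_type == "neutral") return(ls)
  self <- seq_len(n)
  # global target: uniform over the n-1 other owners
  g <- as.integer(floor(utar * (n - 1))) + 1L
  g[g >= self] <- g[g >= self] + 1L
  # local target: uniform over the Moore neighbours
  k <- pmin(as.integer(floor(utar * ls$nb_deg)) + 1L, ls$nb_deg)
  l <- ls$nb_idx[cbind(self, k)]
  targets <- ifelse(ucoin < 0.5, g, l)
  sign <- if (cfg$opinion_type == "positive") 1 else -1
  occ <- occurrence_index(targets)
  for (r in seq_len(max(occ))) {
    sel <- which(occ == r)
    t <- targets[sel]
    landed <- if (cfg$opinion_influence_mode == "always") {
      rep(TRUE, length(sel))
    } else {
      ugate[sel] < (ls$forester_trust[t] + ls$peer_trust[t]) / 2
    }
    delta <- sign * udelta[sel] * cfg$opinion_delta_max
    upd_f <- landed & ls$f_lock[t] == 0L
    tf <- t[upd_f]
    ls$forester_trust[tf] <- pmin(1, pmax(0, ls$forester_trust[tf] + delta[upd_f]))
    upd_p <- landed & ls$p_lock[t] == 0L
    tp <- t[upd_p]
    ls$peer_trust[tp] <- pmin(1, pmax(0, ls$peer_trust[tp] + delta[upd_p]))
  }
  ls
}

#' Final harvest decision
#'
#' Resolves each owner's harvest intent against stand readiness and the
#' owner's sustainability disposition. A sustainable-inclined owner (value 1)
#' cuts only a mature stand; an unsustainable-inclined owner (value 0) also
#' cuts a pre-commercial stand, risking conversion to an undesirable species
#' mix. Nobody cuts a stand that is not ready. By default the cut is classed
#' sustainable when it was executed on a mature stand (a property of the
#' stand state); with `classify_by_owner` the owner's disposition decides.
#' A harvested parcel's stand age resets to 0.
#'
#' @inheritParams reset_and_age
#' @return The updated landscape with `patch_harvested`, `harvest_class`,
#'   `forest_age`, and `harvestability` resolved for the tick.
#' @export
final_harvest_decision <- function(ls, cfg) {
  sust <- ls$sustainability == 1L
  h <- ls$harvestability
  cut <- ls$harvest_decision & ((sust & h == 2L) | (!sust & h >= 1L))
  sustainable_cut <- if (cfg$classify_by_owner) sust[cut] else h[cut] == 2L
  ls$harvest_class[cut] <- ifelse(sustainable_cut, 1L, 2L)
  ls$patch_harvested[cut] <- TRUE
  ls$forest_age[cut] <- 0L
  ls$harvestability[cut] <- 0L
  ls
}

#' Permanent trust conversion
#'
#' End-of-tick learning rule: a trust channel that has stayed above
#' `trust_lock_high` (below `trust_lock_low`) for `trust_lock_window`
#' consecutive ticks is permanently set to 1 (to 0). Once locked, no
#' interaction can move the channel again -- trust or distrust has hardened
#' from attitude into belief.
#'
#' @inheritParams reset_and_age
#' @return The updated landscape.
#' @export
update_trust_lock <- function(ls, cfg) {
  lock_channel <- function(trust, lock, hi, lo) {
    unl <- lock == 0L
    hi[unl] <- ifelse(trust[unl] > cfg$trust_lock_high, hi[unl] + 1L, 0L)
    lo[unl] <- ifelse(trust[unl] < cfg$trust_lock_low, lo[unl] + 1L, 0L)
    to_hi <- unl & hi >= cfg$trust_lock_window
    to_lo <- unl & lo >= cfg$trust_lock_window
    lock[to_hi] <- 1L
    trust[to_hi] <- 1
    lock[to_lo] <- -1L
    trust[to_lo] <- 0
    list(trust = trust, lock = lock, hi = hi, lo = lo)
  }
  f <- lock_channel(ls$forester_trust, ls$f_lock, ls$consec_high_f, ls$consec_low_f)
  ls$forester_trust <- f$trust
  ls$f_lock <- f$lock
  ls$consec_high_f <- f$hi
  ls$consec_low_f <- f$lo
  p <- lock_channel(ls$peer_trust, ls$p_lock, ls$consec_high_p, ls$consec_low_p)
  ls$peer_trust <- p$trust
  ls$p_lock <- p$lock
  ls$consec_high_p <- p$hi
  ls$consec_low_p <- p$lo
  ls
}
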