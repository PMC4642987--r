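test_that("the harvest-predisposition predictor reproduces hand-computed values", {
  expect_equal(linear_predictor(0, 0, 0, 0, 0), -3.065)
  expect_equal(linear_predictor(35.5, 2, 3, 57, 31), -0.7635)
  expect_equal(linear_predictor(1000, 1, 5, 70, 100), 2.145)
})

test_that("pre-interaction decision rate equals clamp(2p - 1, 0, 1)", {
  # analytic oracle: u ~ U(0.5, 1), P(u < p) = max(0, min(1, 2p - 1))
  cfg <- pwo_config()
  n <- 40000
  for (p in c(0.3, 0.5, 0.6, 0.75, 0.9, 1 - 1e-12)) {
    ls <- predictor_landscape(n, qlogis(p))
    set.seed(round(1000 * p))
    ls <- pre_interaction_decision(ls, cfg)
    expected <- max(0, min(1, 2 * p - 1))
    tol <- 3 * sqrt(max(expected * (1 - expected), 1e-4) / n)
    expect_lt(abs(mean(ls$harvest_decision) - expected), tol)
  }
})

test_that("trust-experience drift matches the closed form and vanishes at 0.4", {
  # closed form (before clamping): E[delta] = t * up_max/2 - (1 - t) * down_max/2
  n <- 200000
  for (t in c(0.2, 0.4, 0.7)) {
    set.seed(round(100 * t))
    new <- trust_experience(rep(t, n), runif(n), runif(n), 0.75, 0.5,
                            clamp = FALSE)
    drift <- mean(new) - t
    closed <- t * 0.375 - (1 - t) * 0.25
    expect_lt(abs(drift - closed), 3 * 0.4 / sqrt(n))
  }
  # zero crossing: 0.375 t = 0.25 (1 - t)  =>  t = 0.4
  expect_equal(0.25 / (0.375 + 0.25), 0.4)
})

test_that("forester visits respect trust extremes and locks", {
  cfg <- mini_cfg()

  zero <- fixed_landscape(cfg, forester_trust = 0, sustainability = 0L,
                          harvest_decision = FALSE, f_lock = 0L)
  set.seed(5)
  out <- forester_interaction(zero, seq_len(zero$n), cfg)
  expect_identical(out$sustainability, zero$sustainability)
  expect_identical(out$harvest_decision, zero$harvest_decision)
  expect_true(all(out$forester_trust == 0))

  locked <- fixed_landscape(cfg, forester_trust = 1, f_lock = 1L,
                            sustainability = 0L, harvestability = 2L,
                            harvest_decision = FALSE)
  set.seed(6)
  out <- forester_interaction(locked, seq_len(locked$n), cfg)
  expect_true(all(out$forester_trust == 1))     # locked high never moves
  expect_true(all(out$sustainability == 1L))    # full trust always persuades
  expect_true(all(out$harvest_decision))        # mature stands get intent

  # intent is never created on an immature stand
  young <- fixed_landscape(cfg, forester_trust = 1, harvestability = 1L,
                           harvest_decision = FALSE)
  set.seed(7)
  out <- forester_interaction(young, seq_len(young$n), cfg)
  expect_false(any(out$harvest_decision))
})

test_that("peer leaders persuade but never create intent or erode forester trust", {
  cfg <- mini_cfg()

  zero <- fixed_landscape(cfg, peer_trust = 0, sustainability = 0L,
                          forester_trust = 0.5)
  set.seed(8)
  out <- peer_leader_interaction(zero, seq_len(zero$n), cfg)
  expect_identical(out$sustainability, zero$sustainability)
  expect_identical(out$peer_trust, zero$peer_trust)
  expect_identical(out$forester_trust, zero$forester_trust)

  full <- fixed_landscape(cfg, peer_trust = 1, p_lock = 1L,
                          forester_trust = 0.5, harvest_decision = FALSE)
  set.seed(9)
  out <- full
  for (i in 1:10) out <- peer_leader_interaction(out, seq_len(out$n), cfg)
  expect_true(all(out$forester_trust >= 0.5))   # boost-only channel
  expect_gt(mean(out$forester_trust), 0.5)
  expect_false(any(out$harvest_decision))
})

test_that("opinion spread is valence-faithful and leaves single patches alone", {
  cfg <- mini_cfg()
  ls <- fixed_landscape(cfg)

  neutral <- ls
  set.seed(10)
  out <- community_opinion_step(neutral, cfg)
  expect_identical(out$forester_trust, ls$forester_trust)
  expect_identical(out$peer_trust, ls$peer_trust)

  pos_cfg <- mini_cfg(opinion_type = "positive")
  set.seed(11)
  out <- community_opinion_step(ls, pos_cfg)
  expect_gte(mean(out$forester_trust), mean(ls$forester_trust))
  expect_gte(mean(out$peer_trust), mean(ls$peer_trust))
  expect_false(any(out$harvest_decision != ls$harvest_decision))

  neg_cfg <- mini_cfg(opinion_type = "negative")
  set.seed(12)
  out <- community_opinion_step(ls, neg_cfg)
  expect_lte(mean(out$forester_trust), mean(ls$forester_trust))

  one <- fixed_landscape(pwo_config(grid_width = 1, grid_height = 1,
                                    n_ticks = 2, burn_in = 0, seed = 1))
  set.seed(13)
  expect_identical(community_opinion_step(one, pos_cfg)$forester_trust,
                   one$forester_trust)
})

test_that("the final harvest decision follows the readiness x disposition rules", {
  cfg <- mini_cfg()
  cases <- expand.grid(decision = c(FALSE, TRUE), sustainability = 0:1,
                       harvestability = 0:2)
  # expected class: 0 none, 1 sustainable, 2 unsustainable
  expected <- with(cases, ifelse(!decision, 0L,
                          ifelse(sustainability == 1L,
                                 ifelse(harvestability == 2L, 1L, 0L),
                                 ifelse(harvestability == 2L, 1L,
                                 ifelse(harvestability == 1L, 2L, 0L)))))
  for (i in seq_len(nrow(cases))) {
    ls <- fixed_landscape(cfg,
                          harvest_decision = cases$decision[i],
                          sustainability = cases$sustainability[i],
                          harvestability = as.integer(cases$harvestability[i]),
                          forest_age = 50L)
    out <- final_harvest_decision(ls, cfg)
    expect_true(all(out$harvest_class == expected[i]),
                info = paste(cases[i, ], collapse = "/"))
    if (expected[i] > 0L) {
      expect_true(all(out$patch_harvested))
      expect_true(all(out$forest_age == 0L))
      expect_true(all(out$harvestability == 0L))
    } else {
      expect_false(any(out$patch_harvested))
    }
  }

  # owner-based classification: a cut by an unsustainable owner counts
  # unsustainable even on a mature stand
  own_cfg <- mini_cfg(classify_by_owner = TRUE)
  ls <- fixed_landscape(own_cfg, harvest_decision = TRUE, sustainability = 0L,
                        harvestability = 2L)
  expect_true(all(final_harvest_decision(ls, own_cfg)$harvest_class == 2L))
})

test_that("sustained high or low trust converts permanently", {
  cfg <- mini_cfg()
  run_history <- function(history, channel = "forester_trust",
                          lock = "f_lock") {
    ls <- fixed_landscape(cfg)
    for (v in history) {
      ls[[channel]][ls[[lock]] == 0L] <- v
      ls <- update_trust_lock(ls, cfg)
    }
    ls
  }
  high <- run_history(c(0.8, 0.75, 0.9, 0.71, 0.72))
  expect_true(all(high$f_lock == 1L))
  expect_true(all(high$forester_trust == 1))

  broken <- run_history(c(0.8, 0.8, 0.8, 0.8, 0.6))
  expect_true(all(broken$f_lock == 0L))

  low <- run_history(c(0.2, 0.1, 0.25, 0.29, 0.05))
  expect_true(all(low$f_lock == -1L))
  expect_true(all(low$forester_trust == 0))

  # exactly at a threshold does not count toward a lock
  edge <- run_history(rep(0.7, 10))
  expect_true(all(edge$f_lock == 0L))
})

test_that("locked channels absorb: no interaction sequence moves them", {
  cfg <- mini_cfg(opinion_type = "positive")
  ls <- fixed_landscape(cfg, forester_trust = 1, f_lock = 1L,
                        peer_trust = 0, p_lock = -1L)
  set.seed(21)
  for (i in 1:25) {
    ls <- forester_interaction(ls, sample.int(ls$n, 30, replace = TRUE), cfg)
    ls <- peer_leader_interaction(ls, sample.int(ls$n, 10, replace = TRUE), cfg)
    ls <- community_opinion_step(ls, cfg)
    ls <- update_trust_lock(ls, cfg)
    expect_true(all(ls$forester_trust == 1))
    expect_true(all(ls$peer_trust == 0))
  }
})

test_that("trusts stay in [0,1] under arbitrary interaction sequences", {
  for (seed in 1:5) {
    cfg <- mini_cfg(opinion_type = sample(c("positive", "negative", "neutral"), 1))
    set.seed(seed)
    ls <- init_landscape(cfg)
    for (i in 1:15) {
      ls <- forester_interaction(ls, sample.int(ls$n, 40, replace = TRUE), cfg)
      ls <- peer_leader_interaction(ls, sample.int(ls$n, 15, replace = TRUE), cfg)
      ls <- community_opinion_step(ls, cfg)
      ls <- update_trust_lock(ls, cfg)
      expect_all_trusts_valid(ls)
    }
  }
})

test_that("positive opinion climates end with at least as much trust as negative", {
  # paired across seeds on a small landscape
  final_trust <- function(op, seed) {
    cfg <- pwo_config(grid_width = 8, grid_height = 8, n_foresters = 3,
                      n_peer_leaders = 1, n_ticks = 25, burn_in = 5,
                      opinion_type = op, seed = seed)
    rec <- run_model(cfg)
    mean(attr(rec, "final_landscape")$forester_trust)
  }
  seeds <- 1:30
  pos <- vapply(seeds, function(s) final_trust("positive", s), numeric(1))
  neg <- vapply(seeds, function(s) final_trust("negative", s), numeric(1))
  expect_gt(mean(pos - neg), 0)
  expect_gt(mean(pos >= neg), 0.9)
})
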