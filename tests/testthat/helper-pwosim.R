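# Small configurations and hand-built landscapes used across the suite.

mini_cfg <- function(...) {
  args <- list(grid_width = 6L, grid_height = 6L, n_foresters = 2L,
               n_peer_leaders = 1L, n_ticks = 8L, burn_in = 2L, seed = 101L)
  over <- list(...)
  args[names(over)] <- over
  do.call(pwo_config, args)
}

# A deterministic landscape whose state fields can be overridden directly;
# draws its skeleton from init_landscape under a local seed.
fixed_landscape <- function(cfg = mini_cfg(), seed = 1L, ...) {
  withr::with_seed(seed, {
    ls <- init_landscape(cfg)
  })
  over <- list(...)
  for (nm in names(over)) {
    stopifnot(nm %in% names(ls))
    ls[[nm]] <- rep_len(over[[nm]], length(ls[[nm]]))
  }
  ls
}

# Minimal stand-in landscape for operations that only touch demographic
# fields (pre-interaction decision): n identical owners with predictor H.
predictor_landscape <- function(n, H) {
  list(n = n, ha = rep(0, n), live = rep(0L, n), inct = rep(0L, n),
       age = rep((H + 3.065) / 0.03, n), lngfam = rep(0L, n))
}

expect_all_trusts_valid <- function(ls) {
  expect_true(all(ls$forester_trust >= 0 & ls$forester_trust <= 1))
  expect_true(all(ls$peer_trust >= 0 & ls$peer_trust <= 1))
  expect_true(all(ls$forester_trust[ls$f_lock == 1L] == 1))
  expect_true(all(ls$forester_trust[ls$f_lock == -1L] == 0))
  expect_true(all(ls$peer_trust[ls$p_lock == 1L] == 1))
  expect_true(all(ls$peer_trust[ls$p_lock == -1L] == 0))
}
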