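#' Advance the model by one year
#'
#' Executes the seven-step annual schedule in fixed order: (1) reset and
#' aging, (2) pre-interaction harvest decision, (3) every forester performs
#' its visits (roster order; each visit targets a uniformly random parcel,
#' with replacement), (4) every peer leader likewise, (5) community opinion
#' spread, (6) final harvest decision followed by the permanent-trust check,
#' (7) landscape summaries recorded. Patches are processed in row-major
#' order throughout, so a run is reproducible draw for draw.
#'
#' @param ls A `pwo_landscape`.
#' @param cfg A `pwo_config`.
#' @param tick Tick number stamped into the record.
#' @return `list(landscape = <updated landscape>, record = <one-row
#'   data.frame>)`; see [tick_record()] for the record columns.
#' @export
step_model <- function(ls, cfg, tick = 1L) {
  ls <- reset_and_age(ls, cfg)
  ls <- pre_interaction_decision(ls, cfg)
  if (length(ls$forester_visits)) {
    targets <- unlist(lapply(ls$forester_visits, function(v) {
      sample.int(ls$n, v, replace = TRUE)
    }), use.names = FALSE)
    ls <- forester_interaction(ls, targets, cfg)
  }
  if (length(ls$peer_visits)) {
    targets <- unlist(lapply(ls$peer_visits, function(v) {
      sample.int(ls$n, v, replace = TRUE)
    }), use.names = FALSE)
    ls <- peer_leader_interaction(ls, targets, cfg)
  }
  ls <- community_opinion_step(ls, cfg)
  ls <- final_harvest_decision(ls, cfg)
  ls <- update_trust_lock(ls, cfg)
  list(landscape = ls, record = tick_record(ls, tick))
}

#' Run the model
#'
#' Seeds the random stream from `cfg$seed`, initializes the landscape, and
#' advances it `cfg$n_ticks` years, collecting one summary record per tick.
#' Pure apart from the records it returns: persisting output is the job of
#' [write_timeseries()] / [cmd_run()].
#'
#' @param cfg A `pwo_config`.
#' @return A data.frame with one row per tick (see [tick_record()]); the
#'   final landscape state is attached as attribute `"final_landscape"`.
#' @export
#' @examples
#' cfg <- pwo_config(grid_width = 8, grid_height = 8, n_ticks = 5, burn_in = 1,
#'                   n_foresters = 2, seed = 1)
#' run_model(cfg)
run_model <- function(cfg) {
  validate_config(cfg)
  set.seed(cfg$seed)
  ls <- init_landscape(cfg)
  records <- vector("list", cfg$n_ticks)
  for (tk in seq_len(cfg$n_ticks)) {
    out <- step_model(ls, cfg, tick = tk)
    ls <- out$landscape
    records[[tk]] <- out$record
  }
  res <- if (cfg$n_ticks > 0) {
    do.call(rbind, records)
  } else {
    empty_records()
  }
  attr(res, "final_landscape") <- ls
  res
}
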