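timeseries_columns <- function() {
  c("tick", "pct_harvested", "pct_sustainable", "pct_unsustainable",
    "pct_high_forester_trust", "pct_high_peer_trust",
    "mean_age", "mean_sustainability")
}

empty_records <- function() {
  cols <- timeseries_columns()
  df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  df
}

#' Share of landowners with high trust
#'
#' Trust is classified high when strictly above the threshold (default 0.5);
#' a landowner sitting exactly at the threshold counts as low.
#'
#' @param ls A `pwo_landscape`.
#' @param channel `"forester"` or `"peer"`.
#' @param threshold Classification cut point.
#' @return Percentage of landowners (0-100).
#' @export
pct_high_trust <- function(ls, channel = c("forester", "peer"), threshold = 0.5) {
  channel <- match.arg(channel)
  trust <- if (channel == "forester") ls$forester_trust else ls$peer_trust
  100 * mean(trust > threshold)
}

#' Per-tick landscape summary
#'
#' One row of the run's time series: the percentage of parcels harvested this
#' tick, split exactly into its sustainable and unsustainable parts; the
#' percentage of landowners with high (> 0.5) trust in foresters and in peer
#' leaders; and the landscape means of owner age and sustainability.
#'
#' @param ls A `pwo_landscape` at the end of a tick.
#' @param tick The tick number.
#' @return A one-row data.frame with the columns listed above.
#' @export
tick_record <- function(ls, tick) {
  data.frame(
    tick = as.numeric(tick),
    pct_harvested = 100 * mean(ls$patch_harvested),
    pct_sustainable = 100 * mean(ls$harvest_class == 1L),
    pct_unsustainable = 100 * mean(ls$harvest_class == 2L),
    pct_high_forester_trust = pct_high_trust(ls, "forester"),
    pct_high_peer_trust = pct_high_trust(ls, "peer"),
    mean_age = mean(ls$age),
    mean_sustainability = mean(ls$sustainability)
  )
}

#' Summarize a run over its post-burn-in window
#'
#' Drops the first `burn_in` ticks (the initial pulse of mature-forest
#' harvesting is not representative of the trend) and reports mean, min, max,
#' and sd (n-1 denominator) of every time-series metric over the retained
#' ticks, plus each metric's final-tick value.
#'
#' @param records A run's records, as returned by [run_model()].
#' @param burn_in Number of leading ticks to drop.
#' @return A one-row data.frame with columns `<metric>_mean`, `_min`, `_max`,
#'   `_sd`, and `final_<metric>` for each metric.
#' @export
summarize_run <- function(records, burn_in = 0L) {
  if (burn_in < 0 || burn_in >= nrow(records)) {
    stop(errorCondition(
      "burn_in must leave at least one tick to summarize",
      class = c("pwo_metrics_error", "error")
    ))
  }
  kept <- records[(burn_in + 1L):nrow(records), , drop = FALSE]
  metrics <- setdiff(timeseries_columns(), "tick")
  out <- list()
  for (m in metrics) {
    v <- kept[[m]]
    out[[paste0(m, "_mean")]] <- mean(v)
    out[[paste0(m, "_min")]] <- min(v)
    out[[paste0(m, "_max")]] <- max(v)
    out[[paste0(m, "_sd")]] <- stats::sd(v)
    out[[paste0("final_", m)]] <- v[length(v)]
  }
  as.data.frame(out)
}

#' Write / read a run's time series as CSV
#'
#' The file carries the canonical header
#' `tick,pct_harvested,pct_sustainable,pct_unsustainable,pct_high_forester_trust,pct_high_peer_trust,mean_age,mean_sustainability`.
#' Reading is header-driven (column order in the file does not matter) and a
#' non-numeric cell is reported with its line number. A write/read round
#' trip reproduces the records to full double precision.
#'
#' @param records Records data.frame from [run_model()].
#' @param path File path.
#' @return `write_timeseries()` returns `path` invisibly; `read_timeseries()`
#'   returns the records data.frame in canonical column order.
#' @export
write_timeseries <- function(records, path) {
  utils::write.csv(records[timeseries_columns()], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("time-series file not found: ", path),
                        class = c("pwo_parse_error", "error")))
  }
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  missing <- setdiff(timeseries_columns(), names(df))
  if (length(missing)) {
    stop(errorCondition(
      paste0("missing column(s) in ", path, ": ", paste(missing, collapse = ", ")),
      class = c("pwo_parse_error", "error")
    ))
  }
  df <- df[timeseries_columns()]
  for (cl in names(df)) {
    num <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(num) & !is.na(df[[cl]]))
    if (length(bad)) {
      stop(errorCondition(
        sprintf("malformed value '%s' in column '%s' at line %d of %s",
                df[[cl]][bad[1]], cl, bad[1] + 1L, path),
        class = c("pwo_parse_error", "error")
      ))
    }
    df[[cl]] <- num
  }
  df
}
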