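sweep_variables <- function() {
  c("forester_visits", "peer_visits", "n_foresters", "n_peer_leaders",
    "opinion_type")
}

apply_sweep_level <- function(cfg, variable, level) {
  switch(variable,
    forester_visits = {
      cfg$forester_visits_range <- rep(as.integer(level), 2L)
    },
    peer_visits = {
      cfg$peer_visits_range <- rep(as.integer(level), 2L)
    },
    n_foresters = {
      cfg$n_foresters <- as.integer(level)
    },
    n_peer_leaders = {
      cfg$n_peer_leaders <- as.integer(level)
    },
    opinion_type = {
      cfg$opinion_type <- match.arg(as.character(level),
                                    c("positive", "negative", "neutral"))
    },
    stop(errorCondition(
      paste0("unknown sweep variable: ", variable, " (expected one of ",
             paste(sweep_variables(), collapse = ", "), ")"),
      class = c("pwo_config_error", "error")
    ))
  )
  validate_config(cfg)
}

#' One-variable parameter sweep with replicates
#'
#' Runs the model `reps` times at every level of one swept variable, holding
#' everything else at `base_config`. Visit-count levels pin the respective
#' visits range to a single value; the other variables set counts or the
#' opinion type directly. Every run gets its own seed, drawn (distinctly)
#' from a stream seeded by `master_seed`, so the whole table is reproducible
#' and replicates share no random state.
#'
#' @param variable One of `"forester_visits"`, `"peer_visits"`,
#'   `"n_foresters"`, `"n_peer_leaders"`, `"opinion_type"`.
#' @param levels Vector of levels to sweep.
#' @param reps Replicate runs per level.
#' @param base_config A `pwo_config` providing all non-swept parameters.
#' @param master_seed Integer seed for the seed-derivation stream.
#' @return A data.frame of class `pwo_sweep`: one row per (level, replicate)
#'   with its seed and the run summary columns of [summarize_run()].
#' @export
run_sweep <- function(variable, levels, reps, base_config = pwo_config(),
                      master_seed = 1L) {
  variable <- as.character(variable)
  if (!variable %in% sweep_variables()) {
    apply_sweep_level(base_config, variable, levels[1])  # raises config error
  }
  if (reps < 1) {
    stop(errorCondition("reps must be at least 1",
                        class = c("pwo_config_error", "error")))
  }
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, length(levels) * reps)
  rows <- vector("list", length(levels) * reps)
  i <- 0L
  for (lv in levels) {
    cfg <- apply_sweep_level(base_config, variable, lv)
    for (rep in seq_len(reps)) {
      i <- i + 1L
      cfg$seed <- seeds[i]
      records <- run_model(cfg)
      rows[[i]] <- cbind(
        data.frame(variable = variable, level = as.character(lv),
                   replicate = rep, seed = seeds[i]),
        summarize_run(records, cfg$burn_in)
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pwo_sweep", class(out))
  out
}

#' Pooled descriptive statistics of a sweep metric
#'
#' Pools all rows of the sweep (every level and replicate together, the
#' convention of a one-row-per-variable summary table) and reports min, max,
#' mean, and sd (n-1 denominator).
#'
#' @param sweep_table A `pwo_sweep` table.
#' @param metric Name of a summary column, e.g.
#'   `"final_pct_high_forester_trust"`.
#' @return Named numeric vector `c(min, max, mean, sd)`.
#' @export
aggregate_sweep <- function(sweep_table, metric) {
  if (!metric %in% names(sweep_table)) {
    stop(errorCondition(paste0("unknown metric: ", metric),
                        class = c("pwo_config_error", "error")))
  }
  v <- sweep_table[[metric]]
  c(min = min(v), max = max(v), mean = mean(v), sd = stats::sd(v))
}

#' One-way ANOVA of a sweep metric across levels
#'
#' Classical fixed-effects one-way analysis of variance of the chosen metric
#' with sweep level as the grouping factor: `F = MS_between / MS_within` on
#' `(k - 1, N - k)` degrees of freedom. If every group has zero internal
#' variance while group means differ, `F` is reported as infinite with
#' `p = 0`.
#'
#' @inheritParams aggregate_sweep
#' @return A list with elements `F`, `p`, `df_between`, `df_within`.
#' @export
anova_one_way <- function(sweep_table, metric) {
  if (!metric %in% names(sweep_table)) {
    stop(errorCondition(paste0("unknown metric: ", metric),
                        class = c("pwo_config_error", "error")))
  }
  y <- sweep_table[[metric]]
  g <- factor(sweep_table$level)
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stop(errorCondition("need at least 2 levels with at least 2 replicates each",
                        class = c("pwo_config_error", "error")))
  }
  k <- nlevels(g)
  df_b <- k - 1L
  df_w <- length(y) - k
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  if (ssw == 0) {
    means <- tapply(y, g, mean)
    if (max(means) - min(means) == 0) {
      return(list(F = 0, p = 1, df_between = df_b, df_within = df_w))
    }
    return(list(F = Inf, p = 0, df_between = df_b, df_within = df_w))
  }
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df_between = df_b, df_within = df_w)
}

#' Relative factor influence by permutation importance
#'
#' Ranks the swept factors of a multi-factor table by how much shuffling each
#' factor's column degrades a random-forest fit of the response (increase in
#' mean squared error, negatives truncated to zero), normalized to sum to
#' 100%. This is a transparent stand-in for a boosted-regression-tree
#' influence analysis.
#'
#' @param table A data.frame holding the factor columns and the response.
#' @param response Name of the response column.
#' @param factors Character vector of factor column names (>= 2).
#' @param n_perm Permutations averaged per factor.
#' @param seed Seed for the fit and the permutations.
#' @return Named numeric vector of percentages summing to 100.
#' @export
variable_importance <- function(table, response, factors, n_perm = 20L,
                                seed = 1L) {
  if (length(factors) < 2) {
    stop(errorCondition("need at least two factors to compare",
                        class = c("pwo_config_error", "error")))
  }
  if (!requireNamespace("randomForest", quietly = TRUE)) {
    stop("variable_importance requires the randomForest package")
  }
  set.seed(as.integer(seed))
  dat <- table[c(factors, response)]
  for (f in factors) {
    if (is.character(dat[[f]])) dat[[f]] <- factor(dat[[f]])
  }
  fit <- randomForest::randomForest(
    stats::reformulate(factors, response), data = dat, ntree = 300
  )
  y <- dat[[response]]
  base_mse <- mean((stats::predict(fit, dat) - y)^2)
  raw <- vapply(factors, function(f) {
    mean(vapply(seq_len(n_perm), function(i) {
      perm <- dat
      perm[[f]] <- sample(perm[[f]])
      mean((stats::predict(fit, perm) - y)^2) - base_mse
    }, numeric(1)))
  }, numeric(1))
  raw <- pmax(raw, 0)
  if (sum(raw) == 0) raw <- rep(1, length(raw))
  100 * raw / sum(raw)
}
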