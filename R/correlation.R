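#' Pearson correlation between two percentile vectors
#'
#' The two-step temporal-persistence test: rank patients within each period,
#' then correlate the rank percentiles. Because only ranks enter, the
#' statistic is invariant to any strictly monotone transform of raw PMPM.
#'
#' @param pctl_a,pctl_b Equal-length percentile vectors over the common
#'   population.
#' @return Pearson product-moment correlation coefficient.
#' @export
pearson_on_percentiles <- function(pctl_a, pctl_b) {
  stopifnot(length(pctl_a) == length(pctl_b))
  if (length(pctl_a) < 3L) {
    stop("need at least 3 patients", call. = FALSE)
  }
  if (stats::sd(pctl_a) == 0 || stats::sd(pctl_b) == 0) {
    stop("zero variance in a percentile vector", call. = FALSE)
  }
  stats::cor(pctl_a, pctl_b)
}

# percentile vectors for a (period_a, period_b) pair over the common
# eligible population, ranks recomputed within that common population
common_percentiles <- function(pd, period_a, period_b) {
  rec <- pd$records
  a <- rec[rec$period_index == period_a & rec$eligible, ]
  b <- rec[rec$period_index == period_b & rec$eligible, ]
  ids <- intersect(a$patient_id, b$patient_id)
  list(
    ids = ids,
    pctl_a = rank_percentile(a$pmpm[match(ids, a$patient_id)]),
    pctl_b = rank_percentile(b$pmpm[match(ids, b$patient_id)])
  )
}

#' Lagged rank-percentile correlation table
#'
#' For each requested lag, correlates the PMPM rank percentiles of every
#' available period pair `(p, p + lag)` over patients eligible in both
#' periods, and reports the average correlation across pairs.
#'
#' @param pd A `period_data` with objectives computed.
#' @param lags Integer vector of lags in periods.
#' @return data.frame with columns period_length, lag, pearson_r,
#'   n_patients (average common-population size), n_pairs.
#' @export
lagged_correlation_table <- function(pd, lags = 1:3) {
  n_per <- pd$grid$n_periods
  out <- list()
  for (lag in lags) {
    if (n_per < lag + 1L) {
      warning(sprintf("not enough periods for lag %d; omitted", lag))
      next
    }
    rs <- c()
    ns <- c()
    for (p in seq_len(n_per - lag)) {
      cp <- common_percentiles(pd, p, p + lag)
      if (length(cp$ids) < 3L) next
      rs <- c(rs, pearson_on_percentiles(cp$pctl_a, cp$pctl_b))
      ns <- c(ns, length(cp$ids))
    }
    if (length(rs)) {
      out[[length(out) + 1L]] <- data.frame(
        period_length = pd$grid$length_months, lag = as.integer(lag),
        pearson_r = mean(rs), n_patients = mean(ns), n_pairs = length(rs)
      )
    }
  }
  do.call(rbind, out) %||% data.frame(
    period_length = integer(0), lag = integer(0), pearson_r = numeric(0),
    n_patients = numeric(0), n_pairs = integer(0)
  )
}

#' Top-decile persistence between two periods
#'
#' Identifies the baseline top decile (percentile >= 0.9 in the earlier
#' period, computed within the common eligible population) and reports the
#' share still in the top decile later, plus the mean and sd of their
#' follow-up percentiles (in percent).
#'
#' @param pd A `period_data` with objectives computed.
#' @param period_a,period_b Baseline and follow-up period indices.
#' @return data.frame with period_length, lag, retention_pct,
#'   mean_followup_pctl, sd_followup_pctl, n_top.
#' @export
top_decile_persistence <- function(pd, period_a, period_b) {
  cp <- common_percentiles(pd, period_a, period_b)
  top <- cp$pctl_a >= 0.9
  if (!any(top)) stop("empty top decile", call. = FALSE)
  follow <- cp$pctl_b[top]
  data.frame(
    period_length = pd$grid$length_months,
    lag = period_b - period_a,
    retention_pct = 100 * mean(follow >= 0.9),
    mean_followup_pctl = 100 * mean(follow),
    sd_followup_pctl = 100 * stats::sd(follow),
    n_top = sum(top)
  )
}

#' Persistence table across lags
#'
#' [top_decile_persistence()] averaged over all period pairs per lag,
#' mirroring the layout of retention / follow-up percentile tables.
#'
#' @param pd A `period_data` with objectives computed.
#' @param lags Integer vector of lags in periods.
#' @return data.frame, one row per available lag.
#' @export
persistence_table <- function(pd, lags = 1:3) {
  n_per <- pd$grid$n_periods
  out <- list()
  for (lag in lags) {
    if (n_per < lag + 1L) next
    rows <- lapply(seq_len(n_per - lag), function(p) {
      top_decile_persistence(pd, p, p + lag)
    })
    rows <- do.call(rbind, rows)
    out[[length(out) + 1L]] <- data.frame(
      period_length = pd$grid$length_months, lag = lag,
      retention_pct = mean(rows$retention_pct),
      mean_followup_pctl = mean(rows$mean_followup_pctl),
      sd_followup_pctl = mean(rows$sd_followup_pctl),
      n_pairs = nrow(rows)
    )
  }
  do.call(rbind, out)
}
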