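#' Tile the study window into equal periods
#'
#' Periods are half-open month ranges, 0-based; only whole periods that fit
#' inside the window are kept.
#'
#' @param n_months Total study months.
#' @param length_months Period length: 1, 3, 6 or 12 months.
#' @return Object of class `period_grid`: list with `length_months`,
#'   `n_periods`, and a data.frame `periods` (period_index, start_month,
#'   end_month — half open).
#' @export
period_grid <- function(n_months, length_months) {
  stopifnot(length_months %in% c(1L, 3L, 6L, 12L))
  n_periods <- n_months %/% length_months
  if (n_periods < 1L) stop("window shorter than one period", call. = FALSE)
  periods <- data.frame(
    period_index = seq_len(n_periods),
    start_month = (seq_len(n_periods) - 1L) * length_months,
    end_month = seq_len(n_periods) * length_months
  )
  structure(
    list(length_months = as.integer(length_months),
         n_periods = n_periods, periods = periods),
    class = "period_grid"
  )
}

#' Enrollment filter for one period
#'
#' A patient is eligible for a period when enrolled strictly more than
#' two-thirds of its months (e.g. at least 9 of 12, at least 3 of 3).
#'
#' @param enrollment Enrollment table (patient_id, month_index, enrolled).
#' @param grid A [period_grid()].
#' @param period_index Which period.
#' @return Character vector of eligible patient ids.
#' @export
filter_enrollment <- function(enrollment, grid, period_index) {
  per <- grid$periods[grid$periods$period_index == period_index, ]
  if (nrow(per) != 1L) stop("unknown period index", call. = FALSE)
  months <- seq.int(per$start_month, per$end_month - 1L)
  enr <- data.table::as.data.table(enrollment)
  sub <- enr[enr$month_index %in% months & enr$enrolled == 1L, ]
  tab <- sub[, list(months_enrolled = .N), by = "patient_id"]
  tab$patient_id[tab$months_enrolled > (2 / 3) * grid$length_months]
}

#' Aggregate claims into patient-period records
#'
#' For every patient and period: months enrolled, total expenditure (sum of
#' paid amounts), and grouped event-count blocks (283 diagnosis, 231
#' procedure, 893 drug groups). Ineligible patients are flagged, not
#' dropped. [compute_objectives()] then fills PMPM and its transforms.
#'
#' @param claims,enrollment,demographics Tables in the generator schema.
#' @param grid A [period_grid()].
#' @param maps A `code_group_maps`.
#' @return Object of class `period_data`: list with `records` (data.table:
#'   patient_id, period_index, months_enrolled, total_expenditure, pmpm,
#'   log_pmpm, pctl_pmpm, eligible), `counts` (list per period of sparse
#'   n_patients x 1407 matrices), `patient_ids`, `demographics`, `grid`.
#' @export
aggregate_period <- function(claims, enrollment, demographics, grid, maps) {
  claims <- data.table::as.data.table(claims)
  enrollment <- data.table::as.data.table(enrollment)
  demographics <- data.table::as.data.table(demographics)
  patient_ids <- sort(unique(enrollment$patient_id))
  if (nrow(claims) && !all(claims$patient_id %in% patient_ids)) {
    stop("claims reference patients missing from enrollment", call. = FALSE)
  }
  n <- length(patient_ids)
  L <- grid$length_months

  month_to_period <- function(mo) (mo %/% L) + 1L

  enr <- enrollment[enrollment$enrolled == 1L, ]
  enr$period_index <- month_to_period(enr$month_index)
  enr <- enr[enr$period_index <= grid$n_periods, ]
  enr_tab <- enr[, list(months_enrolled = .N),
                 by = c("patient_id", "period_index")]

  cl <- claims
  if (nrow(cl)) {
    cl$period_index <- month_to_period(cl$month_index)
    cl <- cl[cl$period_index <= grid$n_periods, ]
    cost_tab <- cl[, list(total_expenditure = sum(paid_amount)),
                   by = c("patient_id", "period_index")]
  } else {
    cost_tab <- data.table::data.table(
      patient_id = character(0), period_index = integer(0),
      total_expenditure = numeric(0)
    )
  }

  records <- data.table::CJ(patient_id = patient_ids,
                            period_index = seq_len(grid$n_periods))
  records <- merge(records, enr_tab,
                   by = c("patient_id", "period_index"), all.x = TRUE)
  records <- merge(records, cost_tab,
                   by = c("patient_id", "period_index"), all.x = TRUE)
  records$months_enrolled[is.na(records$months_enrolled)] <- 0L
  records$total_expenditure[is.na(records$total_expenditure)] <- 0
  records$eligible <- records$months_enrolled > (2 / 3) * L
  records$pmpm <- NA_real_
  records$log_pmpm <- NA_real_
  records$pctl_pmpm <- NA_real_

  counts <- lapply(seq_len(grid$n_periods), function(p) {
    per <- grid$periods[p, ]
    grouped_count_matrix(
      claims, maps,
      months = seq.int(per$start_month, per$end_month - 1L),
      patient_ids = patient_ids
    )
  })

  structure(
    list(records = records, counts = counts, patient_ids = patient_ids,
         demographics = demographics, grid = grid),
    class = "period_data"
  )
}

#' Fill the three prediction objectives
#'
#' For records with at least one enrolled month:
#' `pmpm = total_expenditure / months_enrolled`,
#' `log_pmpm = log10(pmpm + 1)`, and `pctl_pmpm` the average-rank percentile
#' of PMPM within the period's *eligible* population (ascending: the top
#' spender has percentile 1; high-cost high-need patients are
#' `pctl_pmpm >= 0.9`). Percentiles are computed within each period
#' independently, so no cross-period information is shared.
#'
#' @param pd A `period_data`.
#' @return The `period_data` with objective columns filled.
#' @export
compute_objectives <- function(pd) {
  rec <- pd$records
  has_months <- rec$months_enrolled > 0L
  rec$pmpm[has_months] <-
    rec$total_expenditure[has_months] / rec$months_enrolled[has_months]
  rec$log_pmpm <- log10(rec$pmpm + 1)
  rec$pctl_pmpm <- NA_real_
  for (p in seq_len(pd$grid$n_periods)) {
    sel <- which(rec$period_index == p & rec$eligible)
    if (length(sel)) {
      rec$pctl_pmpm[sel] <- rank_percentile(rec$pmpm[sel])
    }
  }
  pd$records <- rec
  pd
}

# demographics block: age, sex one-hot (2), race one-hot (6), disabled
demographics_block <- function(demographics, patient_ids) {
  d <- demographics[match(patient_ids, demographics$patient_id), ]
  races <- c("White", "Black", "Hispanic", "AmIndianAlaskan", "Asian",
             "UnknownOther")
  X <- cbind(
    age = d$age,
    sex_F = as.numeric(d$sex == "F"),
    sex_M = as.numeric(d$sex == "M"),
    vapply(races, function(r) as.numeric(d$race == r),
           numeric(length(patient_ids))),
    disabled = as.numeric(d$disabled)
  )
  colnames(X) <- c("age", "sex_F", "sex_M", paste0("race_", races),
                   "disabled")
  X
}

#' Assemble a multi-period design matrix
#'
#' Rows are patients eligible in every referenced period (the `n_prior`
#' predictor periods and the forecast period). Under `feature_flags =
#' "full"` each prior period contributes K = 1 + 283 + 231 + 893 = 1408
#' columns (the prior objective value, then the three grouped-count
#' blocks), followed by L = 10 demographics columns. Under
#' `"prior_objective_only"` each prior period contributes a single column
#' (the prior objective) and demographics are omitted. The target is the
#' chosen objective in the forecast period; no column is derived from the
#' forecast period.
#'
#' @param pd A `period_data` with objectives computed.
#' @param n_prior Number of prior periods (>= 1).
#' @param forecast_period Index of the period whose objective is predicted.
#' @param feature_flags `"full"` or `"prior_objective_only"`.
#' @param objective `"pmpm"`, `"log_pmpm"` or `"pctl_pmpm"`.
#' @return Object of class `claims_design`: list with sparse matrix `x`,
#'   target `y`, `patient_id`, `col_names`, and a `layout` describing the
#'   block structure (n_prior, K, L, temporal column index per period,
#'   static column index, periods_used, forecast_period, objective).
#' @export
assemble_design <- function(pd, n_prior, forecast_period,
                            feature_flags = c("full", "prior_objective_only"),
                            objective = c("pmpm", "log_pmpm", "pctl_pmpm")) {
  feature_flags <- match.arg(feature_flags)
  objective <- match.arg(objective)
  stopifnot(n_prior >= 1)
  prior_periods <- seq.int(forecast_period - n_prior, forecast_period - 1L)
  if (prior_periods[1] < 1L || forecast_period > pd$grid$n_periods) {
    stop("referenced periods fall outside the period grid", call. = FALSE)
  }

  rec <- pd$records
  elig_in <- function(p) rec$patient_id[rec$period_index == p & rec$eligible]
  keep <- Reduce(intersect, lapply(c(prior_periods, forecast_period), elig_in))
  keep <- intersect(pd$patient_ids, keep)  # master order
  if (length(keep) == 0L) {
    stop("no patients eligible in all referenced periods", call. = FALSE)
  }
  ridx <- match(keep, pd$patient_ids)

  obj_of <- function(p) {
    sub <- rec[rec$period_index == p, ]
    sub[[objective]][match(keep, sub$patient_id)]
  }
  y <- obj_of(forecast_period)

  group_names <- c(
    sprintf("dx_%03d", seq_len(CODE_GROUP_SIZES[["dx"]])),
    sprintf("proc_%03d", seq_len(CODE_GROUP_SIZES[["proc"]])),
    sprintf("drug_%03d", seq_len(CODE_GROUP_SIZES[["drug"]]))
  )

  xs <- list()
  col_names <- character(0)
  temporal_cols <- list()
  for (i in seq_along(prior_periods)) {
    p <- prior_periods[i]
    off <- length(col_names)
    if (feature_flags == "prior_objective_only") {
      xs[[length(xs) + 1L]] <- Matrix::Matrix(obj_of(p), ncol = 1,
                                              sparse = TRUE)
      col_names <- c(col_names, sprintf("prior%d_%s", i, objective))
      temporal_cols[[i]] <- off + 1L
    } else {
      blk <- cbind(
        Matrix::Matrix(obj_of(p), ncol = 1, sparse = TRUE),
        pd$counts[[p]][ridx, , drop = FALSE]
      )
      xs[[length(xs) + 1L]] <- blk
      col_names <- c(col_names,
                     sprintf("prior%d_%s", i, objective),
                     sprintf("prior%d_%s", i, group_names))
      temporal_cols[[i]] <- off + seq_len(ncol(blk))
    }
  }
  static_cols <- integer(0)
  if (feature_flags == "full") {
    demo <- demographics_block(pd$demographics, keep)
    xs[[length(xs) + 1L]] <- Matrix::Matrix(demo, sparse = TRUE)
    static_cols <- length(col_names) + seq_len(ncol(demo))
    col_names <- c(col_names, colnames(demo))
  }
  x <- do.call(cbind, xs)
  colnames(x) <- col_names

  structure(
    list(
      x = x, y = y, patient_id = keep, col_names = col_names,
      layout = list(
        n_prior = as.integer(n_prior),
        K = if (feature_flags == "full") 1L + sum(CODE_GROUP_SIZES) else 1L,
        L = length(static_cols),
        temporal_cols = temporal_cols,
        static_cols = static_cols,
        periods_used = prior_periods,
        forecast_period = as.integer(forecast_period),
        objective = objective,
        feature_flags = feature_flags
      )
    ),
    class = "claims_design"
  )
}

#' @export
print.claims_design <- function(x, ...) {
  cat(sprintf(
    "<claims_design> %d patients x %d columns (%d prior periods, K=%d, L=%d), objective %s, forecast period %d\n",
    nrow(x$x), ncol(x$x), x$layout$n_prior, x$layout$K, x$layout$L,
    x$layout$objective, x$layout$forecast_period
  ))
  invisible(x)
}

# reshape a full design into the sequential layout used by the RNN:
# list of T sparse n x K matrices (oldest first) plus the static block
design_sequences <- function(design) {
  stopifnot(design$layout$feature_flags %in% c("full", "prior_objective_only"))
  x_t <- lapply(design$layout$temporal_cols, function(cols) {
    design$x[, cols, drop = FALSE]
  })
  x_s <- if (length(design$layout$static_cols)) {
    as.matrix(design$x[, design$layout$static_cols, drop = FALSE])
  } else {
    matrix(0, nrow(design$x), 0)
  }
  list(x_temporal = x_t, x_static = x_s)
}

#' Select a chronic-condition cohort
#'
#' A patient belongs to the cohort when any diagnosis count in the cohort's
#' group ids is positive in any observed period.
#'
#' @param pd A `period_data`.
#' @param dx_group_ids Integer vector of diagnosis group ids (1..283).
#' @return Character vector of patient ids.
#' @export
select_cohort <- function(pd, dx_group_ids) {
  stopifnot(length(dx_group_ids) >= 1)
  if (any(dx_group_ids < 1L | dx_group_ids > CODE_GROUP_SIZES[["dx"]])) {
    stop("unknown diagnosis group id", call. = FALSE)
  }
  hit <- rep(FALSE, length(pd$patient_ids))
  for (p in seq_along(pd$counts)) {
    sub <- pd$counts[[p]][, dx_group_ids, drop = FALSE]
    hit <- hit | (Matrix::rowSums(sub) > 0)
  }
  pd$patient_ids[hit]
}
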