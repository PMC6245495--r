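#' Chronic-condition cohort definitions
#'
#' Diagnosis-group sets used to flag chronic subcohorts, following the
#' CCS-category convention: diabetes (categories 49 and 50), COPD (127),
#' asthma (128) and hypertension (98 and 99).
#'
#' @return Named list of integer vectors of diagnosis group ids.
#' @export
default_cohorts <- function() {
  list(
    diabetes = c(49L, 50L),
    copd = 127L,
    asthma = 128L,
    hypertension = c(98L, 99L)
  )
}

#' Configuration for the synthetic claims generator
#'
#' Bundles and validates every knob of [simulate_population()]. Monthly
#' expenditures follow a zero-inflated lognormal whose log-mean tracks a
#' stationary patient-level AR(1) severity state `h`; coded events arrive as
#' Poisson streams whose rates rise with severity. The defaults describe a
#' Medicaid-like adult panel: a few hundred dollars per member per month,
#' heavy right tail, roughly a third of enrolled months with no spending,
#' and strong month-to-month persistence.
#'
#' @param n_patients Number of patients (>= 0).
#' @param n_months Number of study months.
#' @param seed Integer seed; identical configurations reproduce the panel
#'   bit for bit.
#' @param rho Lag-1 autocorrelation of the latent severity state, in [0, 1).
#' @param sigma Stationary standard deviation of the latent state.
#' @param mu_sd Standard deviation of the patient-level severity mean
#'   `mu_i`; 0 gives an exchangeable population with purely AR(1) dynamics.
#' @param zero_prob Probability an enrolled patient-month has zero
#'   expenditure (independent of severity).
#' @param cost_scale Log-mean of the positive monthly expenditure at
#'   `h = 0` (log-dollars).
#' @param cost_sdlog Extra lognormal noise sd on top of the latent state.
#' @param event_rate Mean coded events per enrolled month per code system at
#'   `h = 0`; realized rates scale with `exp(h / 2)`.
#' @param enroll_gap_prob Probability any given month is unenrolled.
#' @param cohort_prevalences Named numeric vector, cohort name ->
#'   prevalence; names must appear in `cohort_groups`.
#' @param cohort_groups Named list mapping cohort names to diagnosis group
#'   ids (default [default_cohorts()]). Cohort marker groups are emitted
#'   only by members, so generator flags are exactly recoverable from
#'   claims.
#' @param cohort_mu_shift Additive shift of `mu_i` for cohort members
#'   (applied once per membership).
#' @param cohort_emit_prob Per enrolled month probability that a member
#'   emits one diagnosis event in a cohort marker group (the first enrolled
#'   month always emits one).
#' @param regime `"latent_ar"` (default) or `"planted_linear"`, in which the
#'   second half of the window carries an exactly linear signal in the first
#'   half's grouped counts — used for parameter-recovery experiments.
#' @param planted_coefficients Coefficient vector over the
#'   283 + 231 + 893 = 1407 grouped-count columns (see
#'   [planted_coefficients()]); required when `regime = "planted_linear"`.
#' @param planted_intercept Baseline PMPM (USD/month) of the planted linear
#'   response.
#' @param planted_noise_ratio Noise sd as a fraction of the planted signal
#'   sd.
#' @param n_dx_codes,n_proc_codes,n_drug_codes Raw-code vocabulary sizes
#'   passed to [build_code_group_maps()].
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_patients,
                             n_months,
                             seed = 1L,
                             rho = 0.7,
                             sigma = 1,
                             mu_sd = 0,
                             zero_prob = 0.35,
                             cost_scale = 5.5,
                             cost_sdlog = 0.7,
                             event_rate = 0.5,
                             enroll_gap_prob = 0.05,
                             cohort_prevalences = numeric(0),
                             cohort_groups = default_cohorts(),
                             cohort_mu_shift = 0.6,
                             cohort_emit_prob = 0.6,
                             regime = c("latent_ar", "planted_linear"),
                             planted_coefficients = NULL,
                             planted_intercept = 600,
                             planted_noise_ratio = 0.5,
                             n_dx_codes = 3000L,
                             n_proc_codes = 2000L,
                             n_drug_codes = 9000L) {
  regime <- match.arg(regime)
  stopifnot(
    n_patients >= 0, n_months >= 1,
    rho >= 0, rho < 1,
    sigma >= 0, mu_sd >= 0,
    zero_prob >= 0, zero_prob <= 1,
    event_rate >= 0,
    enroll_gap_prob >= 0, enroll_gap_prob <= 1,
    cost_sdlog >= 0,
    planted_noise_ratio >= 0
  )
  if (length(cohort_prevalences)) {
    stopifnot(
      !is.null(names(cohort_prevalences)),
      all(names(cohort_prevalences) %in% names(cohort_groups)),
      all(cohort_prevalences >= 0), all(cohort_prevalences <= 1)
    )
  }
  if (regime == "planted_linear") {
    if (is.null(planted_coefficients)) {
      stop("planted_linear regime requires planted_coefficients", call. = FALSE)
    }
    k_total <- sum(CODE_GROUP_SIZES)
    if (length(planted_coefficients) != k_total) {
      stop(sprintf(
        "planted_coefficients must have length %d (got %d)",
        k_total, length(planted_coefficients)
      ), call. = FALSE)
    }
    if (n_months %% 2L != 0L) {
      stop("planted_linear regime needs an even n_months", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Planted coefficient vector for recovery experiments
#'
#' A sparse coefficient vector over the 1407 grouped-count columns
#' (283 diagnosis, then 231 procedure, then 893 drug groups). Active
#' coefficients are placed on distinct diagnosis groups with magnitudes
#' drawn uniformly from `magnitude` and random signs.
#'
#' @param n_active Number of nonzero coefficients.
#' @param magnitude Range of absolute coefficient values (USD/month per
#'   event count).
#' @param seed Integer seed.
#' @return Numeric vector of length 1407.
#' @export
planted_coefficients <- function(n_active = 20L, magnitude = c(60, 160),
                                 seed = 1L) {
  stopifnot(n_active >= 1, n_active <= CODE_GROUP_SIZES[["dx"]])
  with_seed(seed, {
    beta <- numeric(sum(CODE_GROUP_SIZES))
    idx <- sample.int(CODE_GROUP_SIZES[["dx"]], n_active)
    beta[idx] <- stats::runif(n_active, magnitude[1], magnitude[2]) *
      sample(c(-1, 1), n_active, replace = TRUE, prob = c(0.3, 0.7))
    beta
  })
}

#' Simulate a longitudinal claims panel
#'
#' Generates enrollment spans, demographics, coded claim events with paid
#' amounts, and the latent ground truth that produced them. Per patient the
#' severity state follows a stationary AR(1),
#' `h_m = mu_i + rho * (h_{m-1} - mu_i) + eps_m`, with stationary variance
#' `sigma^2`. An enrolled month has zero expenditure with probability
#' `zero_prob`, otherwise the expenditure is lognormal with log-mean
#' `cost_scale + h_m`. Event counts per code system are Poisson with rate
#' `event_rate * exp(h_m / 2)`; event codes are drawn uniformly within
#' uniformly chosen groups, and a month's expenditure is split evenly over
#' that month's events (a positive-cost month with no events emits one
#' carrier diagnosis event so claim totals conserve expenditures exactly).
#' Cohort members get an elevated severity mean and emit events in reserved
#' cohort marker groups. In the `planted_linear` regime the second half of
#' the window has PMPM equal to a stated linear function of the first half's
#' grouped counts plus Gaussian noise.
#'
#' @param config A [generator_config()].
#' @param maps Optional [build_code_group_maps()] result; built from the
#'   config's vocabulary sizes and seed when omitted.
#' @return An object of class `claims_panel`: list with `claims`,
#'   `enrollment`, `demographics` (data.tables), `ground_truth` (list with
#'   `latent_states`, `rho_used`, `cohort_flags`, `monthly_cost`, and in the
#'   planted regime `planted`), `maps`, and `config`.
#' @export
simulate_population <- function(config, maps = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(maps)) {
    maps <- build_code_group_maps(
      config$n_dx_codes, config$n_proc_codes, config$n_drug_codes,
      seed = child_seed(config$seed, "maps")
    )
  }
  n <- as.integer(config$n_patients)
  m <- as.integer(config$n_months)
  patient_id <- if (n > 0) sprintf("P%06d", seq_len(n)) else character(0)

  if (n == 0L) {
    empty_claims <- data.table::data.table(
      patient_id = character(0), month_index = integer(0),
      code_system = character(0), raw_code = character(0),
      paid_amount = numeric(0)
    )
    return(structure(list(
      claims = empty_claims,
      enrollment = data.table::data.table(
        patient_id = character(0), month_index = integer(0),
        enrolled = integer(0)
      ),
      demographics = data.table::data.table(
        patient_id = character(0), age = integer(0), sex = character(0),
        race = character(0), disabled = integer(0)
      ),
      ground_truth = list(
        latent_states = matrix(numeric(0), 0, m), rho_used = config$rho,
        planted_coefficients = NULL,
        cohort_flags = data.table::data.table(patient_id = character(0)),
        monthly_cost = matrix(numeric(0), 0, m)
      ),
      maps = maps, config = config
    ), class = "claims_panel"))
  }

  with_seed(config$seed, {
    ## --- cohort membership and latent means ------------------------------
    cohorts <- names(config$cohort_prevalences)
    member <- matrix(FALSE, n, length(cohorts),
                     dimnames = list(NULL, cohorts))
    for (cn in cohorts) {
      member[, cn] <- stats::runif(n) < config$cohort_prevalences[[cn]]
    }
    mu <- stats::rnorm(n, 0, config$mu_sd)
    if (length(cohorts)) {
      mu <- mu + member %*% rep(config$cohort_mu_shift, length(cohorts))
      mu <- as.numeric(mu)
    }

    ## --- latent AR(1) severity, stationary variance sigma^2 --------------
    rho <- config$rho
    h <- matrix(0, n, m)
    h[, 1] <- mu + stats::rnorm(n, 0, config$sigma)
    if (m > 1) {
      innov_sd <- config$sigma * sqrt(1 - rho^2)
      for (j in 2:m) {
        h[, j] <- mu + rho * (h[, j - 1] - mu) + stats::rnorm(n, 0, innov_sd)
      }
    }

    ## --- enrollment and monthly expenditures -----------------------------
    enrolled <- matrix(
      stats::rbinom(n * m, 1L, 1 - config$enroll_gap_prob), n, m
    )
    zero <- matrix(stats::rbinom(n * m, 1L, config$zero_prob), n, m)
    cost <- matrix(
      stats::rlnorm(n * m, config$cost_scale + as.numeric(h),
                    config$cost_sdlog),
      n, m
    )
    cost[zero == 1L] <- 0
    cost <- cost * enrolled

    planted_truth <- NULL

    ## --- coded events -----------------------------------------------------
    reserved_dx <- if (length(cohorts)) {
      sort(unique(unlist(config$cohort_groups[cohorts])))
    } else integer(0)
    free_dx <- setdiff(seq_len(CODE_GROUP_SIZES[["dx"]]), reserved_dx)

    lam <- config$event_rate * exp(as.numeric(h) / 2)
    sys_names <- c("dx", "proc", "drug")
    map_names <- c(dx = "dx_map", proc = "proc_map", drug = "drug_map")
    counts <- lapply(sys_names, function(s) {
      k <- matrix(stats::rpois(n * m, lam), n, m) * enrolled
      k
    })
    names(counts) <- sys_names

    # cohort marker emissions (dx only): Bernoulli per enrolled month, with
    # a forced emission in the first enrolled month of every member
    marker <- vector("list", length(cohorts))
    names(marker) <- cohorts
    for (cn in cohorts) {
      e <- matrix(
        stats::rbinom(n * m, 1L, config$cohort_emit_prob), n, m
      ) * enrolled
      e[!member[, cn], ] <- 0L
      first_enr <- apply(enrolled == 1L, 1L, function(z) {
        w <- which(z)
        if (length(w)) w[1] else NA_integer_
      })
      force_rows <- which(member[, cn] & !is.na(first_enr))
      if (length(force_rows)) {
        e[cbind(force_rows, first_enr[force_rows])] <- 1L
      }
      marker[[cn]] <- e
    }

    # a positive-cost month with no events carries one dx event
    total_events <- Reduce(`+`, counts)
    for (cn in cohorts) total_events <- total_events + marker[[cn]]
    need_carrier <- (cost > 0) & (total_events == 0L)
    counts$dx <- counts$dx + need_carrier
    total_events <- total_events + need_carrier

    ## --- expand events into a claims table --------------------------------
    paid_unit <- ifelse(total_events > 0L, cost / pmax(total_events, 1L), 0)

    event_block <- function(k, system, allowed_groups) {
      tot <- sum(k)
      if (tot == 0L) return(NULL)
      idx <- which(k > 0L, arr.ind = TRUE)
      reps <- k[k > 0L]
      pat <- rep.int(idx[, 1], reps)
      mon <- rep.int(idx[, 2], reps)
      grp <- allowed_groups[
        sample.int(length(allowed_groups), tot, replace = TRUE)
      ]
      list(pat = pat, mon = mon, grp = grp, system = system)
    }

    blocks <- list(
      event_block(counts$dx, "dx", free_dx),
      event_block(counts$proc, "proc",
                  seq_len(CODE_GROUP_SIZES[["proc"]])),
      event_block(counts$drug, "drug",
                  seq_len(CODE_GROUP_SIZES[["drug"]]))
    )
    for (cn in cohorts) {
      grp_ids <- config$cohort_groups[[cn]]
      k <- marker[[cn]]
      if (sum(k) > 0L) {
        b <- event_block(k, "dx", grp_ids)
        blocks <- c(blocks, list(b))
      }
    }
    blocks <- Filter(Negate(is.null), blocks)

    claims <- if (length(blocks)) {
      parts <- lapply(blocks, function(b) {
        gi <- group_code_index(maps[[map_names[[b$system]]]],
                               CODE_GROUP_SIZES[[b$system]])
        pick <- floor(stats::runif(length(b$grp)) * gi$sizes[b$grp]) + 1L
        raw <- gi$codes[gi$starts[b$grp] + pick - 1L]
        data.table::data.table(
          patient_id = patient_id[b$pat],
          month_index = b$mon - 1L,
          code_system = b$system,
          raw_code = raw,
          paid_amount = paid_unit[cbind(b$pat, b$mon)]
        )
      })
      data.table::rbindlist(parts)
    } else {
      data.table::data.table(
        patient_id = character(0), month_index = integer(0),
        code_system = character(0), raw_code = character(0),
        paid_amount = numeric(0)
      )
    }

    ## --- planted_linear regime: overwrite second-half expenditures --------
    if (config$regime == "planted_linear") {
      p <- m %/% 2L
      beta <- config$planted_coefficients
      X <- grouped_count_matrix(claims, maps, months = 0:(p - 1L),
                                patient_ids = patient_id)
      signal <- as.numeric(X %*% beta)
      signal_sd <- stats::sd(signal)
      noise_sd <- config$planted_noise_ratio * signal_sd
      noise <- stats::rnorm(n, 0, noise_sd)
      pmpm2 <- pmax(config$planted_intercept + signal + noise, 0)
      # constant monthly spend in the forecast half: PMPM is invariant to
      # partial enrollment
      late <- (p + 1L):m
      cost[, late] <- matrix(pmpm2, n, length(late)) * enrolled[, late]
      # rewrite paid amounts for the late months
      total_events_late <- total_events[, late, drop = FALSE]
      need2 <- (cost[, late, drop = FALSE] > 0) & (total_events_late == 0L)
      if (any(need2)) {
        idx <- which(need2, arr.ind = TRUE)
        gi <- group_code_index(maps$dx_map, CODE_GROUP_SIZES[["dx"]])
        grp <- free_dx[sample.int(length(free_dx), nrow(idx), replace = TRUE)]
        pick <- floor(stats::runif(nrow(idx)) * gi$sizes[grp]) + 1L
        claims <- data.table::rbindlist(list(claims, data.table::data.table(
          patient_id = patient_id[idx[, 1]],
          month_index = late[idx[, 2]] - 1L,
          code_system = "dx",
          raw_code = gi$codes[gi$starts[grp] + pick - 1L],
          paid_amount = 0
        )))
        for (r in seq_len(nrow(idx))) {
          total_events[idx[r, 1], late[idx[r, 2]]] <-
            total_events[idx[r, 1], late[idx[r, 2]]] + 1L
        }
      }
      paid_unit <- ifelse(total_events > 0L, cost / pmax(total_events, 1L), 0)
      late0 <- late - 1L
      sel <- claims$month_index %in% late0
      claims$paid_amount[sel] <- paid_unit[cbind(
        match(claims$patient_id[sel], patient_id),
        claims$month_index[sel] + 1L
      )]
      planted_truth <- list(
        coefficients = beta, intercept = config$planted_intercept,
        signal = signal, noise = noise, signal_sd = signal_sd,
        noise_sd = noise_sd, period_months = p
      )
    }

    ## --- demographics -----------------------------------------------------
    demographics <- data.table::data.table(
      patient_id = patient_id,
      age = sample(18:65, n, replace = TRUE),
      sex = sample(c("F", "M"), n, replace = TRUE),
      race = sample(
        c("White", "Black", "Hispanic", "AmIndianAlaskan", "Asian",
          "UnknownOther"),
        n, replace = TRUE,
        prob = c(0.35, 0.20, 0.30, 0.03, 0.04, 0.08)
      ),
      disabled = stats::rbinom(n, 1L, 0.15)
    )

    enrollment <- data.table::data.table(
      patient_id = rep(patient_id, each = m),
      month_index = rep(0:(m - 1L), times = n),
      enrolled = as.integer(t(enrolled))
    )

    cohort_flags <- data.table::data.table(patient_id = patient_id)
    for (cn in cohorts) cohort_flags[[cn]] <- member[, cn]

    data.table::setorder(claims, patient_id, month_index, code_system,
                         raw_code)

    structure(list(
      claims = claims,
      enrollment = enrollment,
      demographics = demographics,
      ground_truth = list(
        latent_states = h,
        rho_used = rho,
        planted_coefficients = if (is.null(planted_truth)) NULL else
          planted_truth$coefficients,
        planted = planted_truth,
        cohort_flags = cohort_flags,
        monthly_cost = cost,
        enrolled = enrolled,
        mu = mu
      ),
      maps = maps,
      config = config
    ), class = "claims_panel")
  })
}

#' @export
print.claims_panel <- function(x, ...) {
  cat(sprintf(
    "<claims_panel> %d patients x %d months, %d claim events\n",
    x$config$n_patients, x$config$n_months, nrow(x$claims)
  ))
  invisible(x)
}

# n_patients x 1407 grouped-count matrix over the given months (sparse).
grouped_count_matrix <- function(claims, maps, months, patient_ids) {
  k_sizes <- CODE_GROUP_SIZES
  offsets <- c(dx = 0L, proc = k_sizes[["dx"]],
               drug = k_sizes[["dx"]] + k_sizes[["proc"]])
  sel <- claims$month_index %in% months
  out <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(length(patient_ids), sum(k_sizes))
  )
  if (!any(sel)) return(out)
  cc <- claims[sel, ]
  map_of <- c(dx = "dx_map", proc = "proc_map", drug = "drug_map")
  grp <- integer(nrow(cc))
  for (s in names(map_of)) {
    rows <- cc$code_system == s
    if (any(rows)) {
      grp[rows] <- maps[[map_of[[s]]]][cc$raw_code[rows]] + offsets[[s]]
    }
  }
  i <- match(cc$patient_id, patient_ids)
  Matrix::sparseMatrix(i = i, j = grp, x = 1,
                       dims = c(length(patient_ids), sum(k_sizes)))
}

#' Write a claims panel to delimited text files
#'
#' Emits `claims.csv`, `enrollment.csv`, `demographics.csv` and
#' `code_groups.csv` (code_system, raw_code, group_id) under `dir`.
#'
#' @param panel A `claims_panel`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_claims_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "claims_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(panel$claims, file.path(dir, "claims.csv"))
  data.table::fwrite(panel$enrollment, file.path(dir, "enrollment.csv"))
  data.table::fwrite(panel$demographics, file.path(dir, "demographics.csv"))
  map_dt <- data.table::rbindlist(lapply(
    c(dx = "dx_map", proc = "proc_map", drug = "drug_map"),
    function(mn) data.table::data.table(
      code_system = sub("_map$", "", mn),
      raw_code = names(panel$maps[[mn]]),
      group_id = as.integer(panel$maps[[mn]])
    )
  ))
  data.table::fwrite(map_dt, file.path(dir, "code_groups.csv"))
  invisible(dir)
}

#' Read a claims panel written by [write_claims_panel()]
#'
#' Also accepts user-supplied files in the same schema.
#'
#' @param dir Directory containing the four CSV files.
#' @return List with `claims`, `enrollment`, `demographics`, `maps`.
#' @export
read_claims_panel <- function(dir) {
  claims <- data.table::fread(file.path(dir, "claims.csv"))
  enrollment <- data.table::fread(file.path(dir, "enrollment.csv"))
  demographics <- data.table::fread(file.path(dir, "demographics.csv"))
  map_dt <- data.table::fread(file.path(dir, "code_groups.csv"))
  maps <- lapply(split(map_dt, map_dt$code_system), function(d) {
    v <- d$group_id
    names(v) <- d$raw_code
    v
  })
  maps <- structure(
    list(dx_map = maps$dx, proc_map = maps$proc, drug_map = maps$drug),
    class = "code_group_maps"
  )
  list(claims = claims, enrollment = enrollment,
       demographics = demographics, maps = maps)
}
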