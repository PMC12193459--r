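# Seeded synthetic ICU cohort generator. Emulates the structure of a
# MIMIC-style hemorrhagic-stroke extract: long-format chart/lab/prescription
# events with tiered missingness, per-patient demographics, and a known
# ground-truth volume process N(M_j(t), Sigma_j(t)) from which expansion
# labels are realized. Nothing here is real patient data.

#' Default clinical feature roster
#'
#' 28 features: 6 demographic/admission variables (one-hot-able), 8 hourly
#' vitals, 10 labs including the coagulation markers PT and INR, and 4
#' medication flags. `lower`/`upper` are hard physiologic plausibility
#' bounds used by the outlier step; `missing_rate` is the per-cell
#' probability that an hourly value goes unrecorded, chosen so that the
#' three imputation tiers (< 5%, 5-20%, > 20%) are all exercised.
#'
#' @return data.frame with columns `name`, `kind` (continuous, categorical
#'   or binary), `table` (emulated source table), `lower`, `upper`,
#'   `missing_rate`.
#' @export
feature_roster <- function() {
  rbind(
    data.frame(name = c("gender", "admission_type", "insurance",
                        "marital_status", "language"),
               kind = "categorical", table = "demographics",
               lower = NA, upper = NA, missing_rate = 0),
    data.frame(name = "anchor_age", kind = "continuous", table = "demographics",
               lower = 0, upper = 120, missing_rate = 0),
    data.frame(name = c("heart_rate", "sbp", "dbp", "map", "resp_rate",
                        "spo2", "temperature", "gcs"),
               kind = "continuous", table = "chartevents",
               lower = c(20, 40, 20, 30, 4, 50, 32, 3),
               upper = c(220, 300, 200, 250, 60, 100, 42, 15),
               missing_rate = c(0.02, 0.03, 0.03, 0.04, 0.03, 0.02, 0.04, 0.04)),
    data.frame(name = c("pt", "inr", "aptt", "platelets", "wbc",
                        "hemoglobin", "glucose", "sodium", "creatinine",
                        "fibrinogen"),
               kind = "continuous", table = "labevents",
               lower = c(8, 0.5, 15, 5, 0.5, 3, 30, 110, 0.2, 50),
               upper = c(60, 12, 150, 1000, 60, 22, 700, 175, 15, 1000),
               missing_rate = c(0.10, 0.10, 0.25, 0.08, 0.08, 0.08, 0.12,
                                0.08, 0.12, 0.30)),
    data.frame(name = c("antihypertensive", "anticoagulant_reversal",
                        "mannitol", "sedative"),
               kind = "binary", table = "prescriptions",
               lower = NA, upper = NA, missing_rate = 0)
  )
}

#' Synthetic cohort specification
#'
#' Defaults mirror the emulated study population: 947 patients, 28 clinical
#' features, 72 h of hourly sampling, and an expansion prevalence of 0.32
#' within a 24 h prediction window.
#'
#' @param n_patients number of subjects.
#' @param duration record length in hours.
#' @param sampling sampling interval in hours.
#' @param expansion_rate target prevalence of hematoma expansion in (0, 1);
#'   the generator calibrates the baseline growth intercept so the mean
#'   analytic crossing probability equals this rate.
#' @param horizon labeling/prediction window in hours.
#' @param mean_effects named effects (ml of 24 h growth per SD) of the two
#'   signal features on the growth rate: `sbp` and `inr`.
#' @param trend_tau time constant (hours) of the saturating growth trend
#'   `1 - exp(-t/tau)`.
#' @param var_intercept log of the baseline process variance (ml^2).
#' @param var_age_coef log-linear effect of standardized age on the
#'   variance (0 gives a feature-independent variance).
#' @param var_time_ramp relative linear growth of the variance across the
#'   record (0 gives a time-constant variance).
#' @param growth_intercept optional fixed baseline growth intercept (ml per
#'   24 h); `NULL` (default) calibrates it to hit `expansion_rate`.
#' @param missingness_plan optional named per-feature missing rates
#'   overriding the roster.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 947L, duration = 72, sampling = 1,
                        expansion_rate = 0.32, horizon = 24,
                        mean_effects = c(sbp = 4, inr = 5), trend_tau = 12,
                        var_intercept = log(4), var_age_coef = 0.3,
                        var_time_ramp = 0.5, growth_intercept = NULL,
                        missingness_plan = NULL, seed = 7L) {
  stopifnot(n_patients >= 1, duration > 0, sampling > 0,
            expansion_rate > 0, expansion_rate < 1, horizon <= duration,
            trend_tau > 0, var_time_ramp >= 0)
  roster <- feature_roster()
  if (!is.null(missingness_plan)) {
    if (is.null(names(missingness_plan)) ||
        !all(names(missingness_plan) %in% roster$name) ||
        any(missingness_plan < 0) || any(missingness_plan >= 1)) {
      stop("`missingness_plan` must be named rates in [0, 1) for roster features",
           call. = FALSE)
    }
    roster$missing_rate[match(names(missingness_plan), roster$name)] <- missingness_plan
  }
  structure(list(n_patients = as.integer(n_patients), duration = duration,
                 sampling = sampling, expansion_rate = expansion_rate,
                 horizon = horizon, mean_effects = mean_effects,
                 trend_tau = trend_tau, var_intercept = var_intercept,
                 var_age_coef = var_age_coef, var_time_ramp = var_time_ramp,
                 growth_intercept = growth_intercept,
                 roster = roster, n_features = nrow(roster),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Fixed reference scales used to standardize the signal features inside the
# generator (kept constant so the truth does not depend on cohort size).
.ref_scales <- list(sbp = c(150, 20), inr = c(1.25, 0.35), age = c(66, 12))

ar1_series <- function(n, base, amp, phase, rho, sd_innov, t) {
  e <- stats::rnorm(n, sd = sd_innov)
  x <- numeric(n)
  x[1] <- e[1] / sqrt(1 - rho^2)
  for (i in 2:n) x[i] <- rho * x[i - 1] + e[i]
  base + amp * sin(2 * pi * (t + phase) / 24) + x
}

#' Simulate a synthetic hemorrhagic-stroke cohort
#'
#' Draws demographics, circadian-drifting vitals, slowly drifting labs and
#' medication exposure per patient; constructs the true volume process with
#' mean `M_j(t) = v0 + s_j (1 - exp(-t/tau))` — the growth rate `s_j` linear
#' in standardized baseline systolic blood pressure and INR — and log-linear
#' variance `Sigma_j(t)`; calibrates the growth intercept so the mean
#' analytic crossing probability within the labeling window equals
#' `expansion_rate`; realizes volumes `V(t_i) ~ N(M_j, Sigma_j)` and labels
#' expansion by whether any realized volume in the window reaches the
#' clinical threshold. Fully reproducible under `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `mskt_cohort`: list with `events` (long table:
#'   subject_id, hadm_id, charttime, table, item, value), `demographics`,
#'   `truth` (times, per-patient M, S and realized V matrices, v0,
#'   threshold, label, growth rate, calibrated intercept) and `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  t <- seq(0, spec$duration - spec$sampling, by = spec$sampling)
  T_ <- length(t)
  roster <- spec$roster

  with_seed(spec$seed, {
    demographics <- data.frame(
      subject_id = 10000L + seq_len(n),
      hadm_id = 20000000L + seq_len(n),
      gender = sample(c("M", "F"), n, TRUE, prob = c(0.55, 0.45)),
      anchor_age = round(pmin(pmax(stats::rnorm(n, 66, 12), 18), 95)),
      admission_type = sample(c("EMERGENCY", "URGENT", "ELECTIVE"), n, TRUE,
                              prob = c(0.7, 0.2, 0.1)),
      insurance = sample(c("Medicare", "Medicaid", "Other"), n, TRUE,
                         prob = c(0.5, 0.15, 0.35)),
      marital_status = sample(c("MARRIED", "SINGLE", "WIDOWED"), n, TRUE,
                              prob = c(0.5, 0.3, 0.2)),
      language = sample(c("ENGLISH", "OTHER"), n, TRUE, prob = c(0.85, 0.15)),
      admittime = as.POSIXct("2150-01-01 00:00:00", tz = "UTC") +
        round(stats::runif(n, 0, 3650)) * 86400
    )

    lab_base <- list(pt = c(14, 2), inr = NA, aptt = c(32, 6),
                     platelets = c(230, 60), wbc = NA, hemoglobin = c(13, 1.8),
                     glucose = c(140, 40), sodium = c(139, 4), creatinine = NA,
                     fibrinogen = c(350, 80))
    vital_base <- list(heart_rate = c(82, 12, 3), sbp = c(150, 20, 5),
                       dbp = c(85, 12, 3), resp_rate = c(18, 3, 1),
                       spo2 = c(97, 1.5, 0.3), temperature = c(36.8, 0.4, 0.3),
                       gcs = c(12, 2, 0))

    v0 <- pmin(pmax(stats::rlnorm(n, log(14), 0.6), 1), 90)
    series <- vector("list", n)
    sbp_base <- numeric(n)
    inr_base <- numeric(n)
    for (j in seq_len(n)) {
      m <- matrix(NA_real_, T_, nrow(roster), dimnames = list(NULL, roster$name))
      m[, "anchor_age"] <- demographics$anchor_age[j]
      bases <- list()
      for (v in names(vital_base)) {
        p <- vital_base[[v]]
        bases[[v]] <- stats::rnorm(1, p[1], p[2])
        m[, v] <- ar1_series(T_, bases[[v]], p[3], stats::runif(1, 0, 24),
                             0.8, p[2] / 6, t)
      }
      m[, "spo2"] <- pmin(m[, "spo2"], 100)
      m[, "gcs"] <- round(pmin(pmax(m[, "gcs"], 3), 15))
      m[, "map"] <- m[, "dbp"] + (m[, "sbp"] - m[, "dbp"]) / 3 +
        stats::rnorm(T_, sd = 2)
      for (v in names(lab_base)) {
        p <- lab_base[[v]]
        base <- switch(v,
          inr = stats::rlnorm(1, log(1.25), 0.25),
          wbc = stats::rlnorm(1, log(9), 0.3),
          creatinine = stats::rlnorm(1, log(1.0), 0.35),
          stats::rnorm(1, p[1], p[2]))
        drift <- stats::rnorm(1, 0, 0.02) * t
        noise_sd <- max(abs(base) * 0.04, 1e-3)
        m[, v] <- base * (1 + drift / max(abs(base), 1)) +
          stats::rnorm(T_, sd = noise_sd)
      }
      for (v in c("antihypertensive", "anticoagulant_reversal", "mannitol",
                  "sedative")) {
        pr <- switch(v,
          antihypertensive = 0.6,
          anticoagulant_reversal = stats::plogis(-1.5 + 2 * (m[1, "inr"] - 1.25)),
          mannitol = 0.3,
          sedative = 0.5)
        on <- stats::rbinom(1, 1, pr)
        m[, v] <- if (on) as.numeric(t >= stats::runif(1, 0, 12)) else 0
      }
      sbp_base[j] <- bases$sbp
      inr_base[j] <- m[1, "inr"]
      series[[j]] <- m
    }

    z_sbp <- (sbp_base - .ref_scales$sbp[1]) / .ref_scales$sbp[2]
    z_inr <- (inr_base - .ref_scales$inr[1]) / .ref_scales$inr[2]
    z_age <- (demographics$anchor_age - .ref_scales$age[1]) / .ref_scales$age[2]

    trend <- 1 - exp(-t / spec$trend_tau)
    Svar <- exp(spec$var_intercept + spec$var_age_coef * z_age) %o%
      (1 + spec$var_time_ramp * t / spec$duration)
    thr <- vapply(v0, function(v) expansion_threshold(v)$c, numeric(1))
    slope_part <- spec$mean_effects[["sbp"]] * z_sbp +
      spec$mean_effects[["inr"]] * z_inr
    in_window <- which(t < spec$horizon)

    mean_cross <- function(a0) {
      s <- a0 + slope_part
      M <- v0 + s %o% trend
      beta <- stats::pnorm(thr, M[, in_window, drop = FALSE],
                           sqrt(Svar[, in_window, drop = FALSE]),
                           lower.tail = FALSE)
      mean(1 - apply(1 - beta, 1L, prod))
    }
    if (is.null(spec$growth_intercept)) {
      lo <- -60; hi <- 150
      if (mean_cross(lo) > spec$expansion_rate || mean_cross(hi) < spec$expansion_rate) {
        stop("`expansion_rate` is not achievable under the configured effect sizes",
             call. = FALSE)
      }
      a0 <- stats::uniroot(function(a) mean_cross(a) - spec$expansion_rate,
                           c(lo, hi), tol = 1e-6)$root
    } else {
      a0 <- spec$growth_intercept
    }
    s_j <- a0 + slope_part
    M <- v0 + s_j %o% trend
    V <- M + matrix(stats::rnorm(n * T_), n, T_) * sqrt(Svar)
    label <- as.integer(apply(V[, in_window, drop = FALSE] >=
                                matrix(thr, n, length(in_window)), 1L, any))

    # Long-format events with per-cell missingness on the measured features.
    ev <- vector("list", n)
    cont <- roster$name[roster$kind == "continuous" & roster$table != "demographics"]
    bin <- roster$name[roster$kind == "binary"]
    for (j in seq_len(n)) {
      m <- series[[j]]
      rows <- list()
      for (v in cont) {
        keep <- stats::runif(T_) >= roster$missing_rate[roster$name == v]
        if (any(keep)) {
          rows[[v]] <- data.frame(
            table = roster$table[roster$name == v], item = v,
            time_h = t[keep], value = m[keep, v])
        }
      }
      for (v in bin) {
        on <- which(m[, v] == 1)
        if (length(on)) {
          rows[[v]] <- data.frame(table = "prescriptions", item = v,
                                  time_h = t[on], value = 1)
        }
      }
      e <- do.call(rbind, rows)
      if (!is.null(e)) {
        e$subject_id <- demographics$subject_id[j]
        e$hadm_id <- demographics$hadm_id[j]
        ev[[j]] <- e
      }
    }
    events <- do.call(rbind, ev)
    events$charttime <- demographics$admittime[match(events$subject_id,
                                                     demographics$subject_id)] +
      events$time_h * 3600
    rownames(events) <- NULL
    events <- events[, c("subject_id", "hadm_id", "charttime", "time_h",
                         "table", "item", "value")]

    structure(list(
      events = events,
      demographics = demographics,
      truth = list(times = t, M = M, S = Svar, V = V, v0 = v0,
                   threshold = thr, label = label, growth = s_j,
                   intercept = a0, horizon = spec$horizon),
      spec = spec
    ), class = "mskt_cohort")
  })
}

#' @export
print.mskt_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d events, %d h at %g h sampling\n",
              nrow(x$demographics), nrow(x$events), x$spec$duration,
              x$spec$sampling))
  cat(sprintf("  expansion prevalence %.3f (target %.2f), seed %d\n",
              mean(x$truth$label), x$spec$expansion_rate, x$spec$seed))
  invisible(x)
}

#' Inject measurement noise into a cohort
#'
#' Adds independent Gaussian perturbations to the continuous measured
#' features in the event table; ground truth, labels and demographics are
#' untouched. Used for the noise-robustness (RNH) evaluation.
#'
#' @param cohort an `mskt_cohort`.
#' @param noise_sd non-negative scalar, or named per-feature vector of
#'   noise SDs on the measurement scale.
#' @param seed integer seed.
#' @return the perturbed cohort.
#' @export
inject_noise <- function(cohort, noise_sd, seed = 1L) {
  stopifnot(inherits(cohort, "mskt_cohort"), all(noise_sd >= 0))
  roster <- cohort$spec$roster
  cont <- roster$name[roster$kind == "continuous" & roster$table != "demographics"]
  ev <- cohort$events
  with_seed(seed, {
    for (v in cont) {
      sdv <- if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
        noise_sd
      } else {
        unname(noise_sd[v])
      }
      if (is.na(sdv) || sdv == 0) next
      i <- which(ev$item == v)
      ev$value[i] <- ev$value[i] + stats::rnorm(length(i), sd = sdv)
    }
  })
  cohort$events <- ev
  cohort
}

#' Subject-level train/validation/test split
#'
#' Randomly partitions subjects (never rows) into three disjoint sets with
#' sizes `round(n * fractions)` for validation and test and the remainder in
#' training.
#'
#' @param x an `mskt_cohort`, or a vector of subject identifiers, or a
#'   single count n.
#' @param fractions length-3 vector summing to 1 (train, validation, test).
#' @param seed integer seed.
#' @return list with `train`, `validation`, `test` subject-id vectors.
#' @export
split_cohort <- function(x, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (inherits(x, "mskt_cohort")) {
    ids <- x$demographics$subject_id
  } else if (length(x) == 1L && is.numeric(x)) {
    ids <- seq_len(x)
  } else {
    ids <- x
  }
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L) {
    stop("`fractions` must be three values summing to 1", call. = FALSE)
  }
  n <- length(ids)
  n_val <- round(n * fractions[2L])
  n_test <- round(n * fractions[3L])
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1L) {
    stop("cohort too small for three non-empty splits", call. = FALSE)
  }
  perm <- with_seed(seed, sample(ids))
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}
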