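# Leakage-safe clinical preprocessing: hourly resampling, one-hot encoding,
# hard physiologic-range removal, winsorized outlier handling, and tiered
# missing-value imputation. All reference statistics (levels, percentiles,
# SDs, medians, modes, KNN donors) are computed on the training split only
# and frozen for validation/test transforms.

#' Hourly resampling of long-format events
#'
#' Aggregates timestamped events onto a 0-based half-open hourly grid
#' \[h, h+1): continuous features keep the last observation per bin,
#' medication features become presence flags (1 when any event falls in the
#' bin, 0 otherwise); bins without an event are missing (NA) for continuous
#' features.
#'
#' @param events long table with columns `subject_id`, `time_h` (hours since
#'   admission), `item`, `value`.
#' @param duration record length in hours.
#' @param roster feature roster (see [feature_roster()]); determines which
#'   items are continuous vs binary.
#' @param subjects subject ids to resample (default: all in `events`).
#' @param sampling bin width in hours (default 1).
#' @return named list of T x d matrices (one per subject, d = measured
#'   features in roster order), with per-feature missing rates as the
#'   `"missing_rate"` attribute.
#' @export
resample_hourly <- function(events, duration, roster = feature_roster(),
                            subjects = NULL, sampling = 1) {
  stopifnot(duration > 0)
  if (is.null(subjects)) subjects <- sort(unique(events$subject_id))
  measured <- roster[roster$table != "demographics", ]
  T_ <- as.integer(ceiling(duration / sampling))
  out <- vector("list", length(subjects))
  names(out) <- as.character(subjects)
  for (si in seq_along(subjects)) {
    e <- events[events$subject_id == subjects[si] & events$time_h < duration, ]
    if (nrow(e) == 0L) {
      stop(sprintf("subject %s has no events", subjects[si]), call. = FALSE)
    }
    m <- matrix(NA_real_, T_, nrow(measured),
                dimnames = list(NULL, measured$name))
    m[, measured$name[measured$kind == "binary"]] <- 0
    e <- e[order(e$time_h), ]
    bin <- floor(e$time_h / sampling) + 1L
    for (f in seq_len(nrow(measured))) {
      v <- measured$name[f]
      i <- which(e$item == v)
      if (!length(i)) next
      if (measured$kind[f] == "binary") {
        m[unique(bin[i]), v] <- 1
      } else {
        # events are time-ordered, so the last index per bin wins
        m[bin[i], v] <- e$value[i]
      }
    }
    out[[si]] <- m
  }
  mr <- colMeans(do.call(rbind, lapply(out, is.na)))
  attr(out, "missing_rate") <- mr
  out
}

#' One-hot encode categorical variables
#'
#' Each categorical column is replaced by one indicator column per level;
#' for a non-missing source value exactly one indicator per row is 1. A
#' missing source value yields missing indicators (routed to imputation).
#'
#' @param data data.frame holding the categorical columns.
#' @param columns names of the categorical columns.
#' @param levels optional named list of level sets (frozen from training);
#'   by default levels observed in `data`.
#' @param drop_first drop the first level's indicator per variable.
#' @param unseen `"error"` (default) to fail on a level absent from
#'   `levels`, or `"other"` to route it to an explicit `_other` column.
#' @return list with `matrix` (numeric indicator matrix) and `levels`.
#' @export
one_hot_encode <- function(data, columns, levels = NULL, drop_first = FALSE,
                           unseen = c("error", "other")) {
  unseen <- match.arg(unseen)
  if (is.null(levels)) {
    levels <- lapply(columns, function(cl) sort(unique(stats::na.omit(data[[cl]]))))
    names(levels) <- columns
  }
  blocks <- lapply(columns, function(cl) {
    x <- as.character(data[[cl]])
    lv <- levels[[cl]]
    bad <- !is.na(x) & !(x %in% lv)
    if (any(bad)) {
      if (unseen == "error") {
        stop(sprintf("unseen category '%s' in `%s`", x[bad][1L], cl), call. = FALSE)
      }
      x[bad] <- "_other_"
      lv <- c(lv, "_other_")
    }
    keep <- if (drop_first) lv[-1L] else lv
    b <- matrix(NA_real_, length(x), length(keep),
                dimnames = list(NULL, paste0(cl, "_", keep)))
    ok <- !is.na(x)
    for (k in seq_along(keep)) b[ok, k] <- as.numeric(x[ok] == keep[k])
    b
  })
  list(matrix = do.call(cbind, blocks), levels = levels)
}

# Assemble the raw per-subject design matrix: replicated demographic
# columns (one-hot categoricals + age) followed by the resampled measured
# features. Categorical NAs may remain NA in the one-hot block.
assemble_raw <- function(cohort, subjects, levels = NULL, duration = NULL,
                         sampling = NULL) {
  roster <- cohort$spec$roster
  duration <- duration %||% cohort$spec$duration
  sampling <- sampling %||% cohort$spec$sampling
  cat_cols <- roster$name[roster$kind == "categorical"]
  dem <- cohort$demographics[match(subjects, cohort$demographics$subject_id), ]
  oh <- one_hot_encode(dem, cat_cols, levels = levels)
  meas <- resample_hourly(cohort$events, duration, roster, subjects, sampling)
  T_ <- nrow(meas[[1L]])
  mats <- lapply(seq_along(subjects), function(i) {
    const <- c(oh$matrix[i, ], anchor_age = dem$anchor_age[i])
    cbind(matrix(const, T_, length(const), byrow = TRUE,
                 dimnames = list(NULL, names(const))),
          meas[[i]])
  })
  names(mats) <- as.character(subjects)
  list(matrices = mats, levels = oh$levels)
}

#' Winsorized outlier handling
#'
#' Two-stage rule on continuous columns: values outside the hard
#' physiologic range are removed (set missing, pre-imputation); remaining
#' values further than 3 SDs from the reference mean are pulled to the
#' reference 2.5th / 97.5th percentile on their side. Reference statistics
#' come from the training split.
#'
#' @param m numeric matrix with named columns.
#' @param ranges data.frame with `name`, `lower`, `upper` hard bounds.
#' @param stats named list per feature with `mean`, `sd`, `q025`, `q975`
#'   (training-split values); features with (near-)zero SD are skipped.
#' @return list with `matrix`, and counts `n_removed`, `n_winsorized` per
#'   feature.
#' @export
clean_outliers <- function(m, ranges, stats) {
  nrem <- integer(0)
  nwin <- integer(0)
  for (v in names(stats)) {
    x <- m[, v]
    r <- ranges[ranges$name == v, ]
    out_range <- !is.na(x) & (x < r$lower | x > r$upper)
    x[out_range] <- NA
    st <- stats[[v]]
    w <- 0L
    if (!is.null(st) && is.finite(st$sd) && st$sd > 1e-12) {
      hi <- !is.na(x) & (x > st$mean + 3 * st$sd)
      lo <- !is.na(x) & (x < st$mean - 3 * st$sd)
      x[hi] <- st$q975
      x[lo] <- st$q025
      w <- sum(hi) + sum(lo)
    }
    m[, v] <- x
    nrem[v] <- sum(out_range)
    nwin[v] <- w
  }
  list(matrix = m, n_removed = nrem, n_winsorized = nwin)
}

#' Tiered missing-value imputation
#'
#' Applies the frozen tier decisions of a fitted pipeline to one raw
#' matrix: features with training missing rate < 5% get median (continuous)
#' or mode (indicator) imputation; 5-20% get K-nearest-neighbour imputation
#' over patients (donor = mean of the K nearest training patients' values);
#' > 20% are dropped unless whitelisted (whitelisted features fall back to
#' the median).
#'
#' @param m raw matrix (post outlier handling) with NA gaps.
#' @param pipeline a fitted [fit_pipeline()] object.
#' @param subject_id optional id, used to exclude the patient itself from
#'   its donor pool.
#' @return completed matrix restricted to the kept columns; no NAs remain.
#' @export
tiered_impute <- function(m, pipeline, subject_id = NULL) {
  p <- pipeline
  out <- m[, p$kept, drop = FALSE]
  for (v in p$kept) {
    miss <- is.na(out[, v])
    if (!any(miss)) next
    tier <- p$tiers[[v]]
    if (tier == "median" || tier == "whitelist_median") {
      out[miss, v] <- p$medians[[v]]
    } else if (tier == "mode") {
      out[miss, v] <- p$modes[[v]]
    } else if (tier == "knn") {
      out[miss, v] <- knn_donor_value(out, v, p, subject_id)
    }
  }
  if (anyNA(out)) stop("imputation left missing values", call. = FALSE)
  out
}

knn_donor_value <- function(m, feature, pipeline, subject_id = NULL) {
  ref <- pipeline$knn$reference   # train patients x reference features (standardized)
  donors <- pipeline$knn$donor_values[[feature]]  # train patient mean values, NA if unobserved
  prof <- colMeans(m[, pipeline$knn$features, drop = FALSE], na.rm = TRUE)
  prof <- (prof - pipeline$knn$center) / pipeline$knn$scale
  d2 <- colSums((t(ref) - prof)^2)
  if (!is.null(subject_id)) {
    d2[rownames(ref) == as.character(subject_id)] <- Inf
  }
  d2[is.na(donors)] <- Inf
  k <- min(pipeline$knn$k, sum(is.finite(d2)))
  if (k < 1L) return(pipeline$medians[[feature]])
  mean(donors[order(d2)[seq_len(k)]])
}

#' Fit the preprocessing pipeline on the training split
#'
#' Computes and freezes every reference statistic of the cleaning pipeline
#' from the training subjects: categorical levels, hard-range and
#' winsorization statistics (mean, SD, 2.5/97.5 percentiles, after range
#' removal), per-feature missing rates and imputation tiers, medians and
#' modes, the KNN donor pool, and post-imputation standardization
#' statistics. Missing rates are computed after hard-range removal, since
#' removal itself creates missingness.
#'
#' @param cohort an `mskt_cohort`.
#' @param train_ids training subject ids (statistics use only these).
#' @param whitelist clinically important features retained (with median
#'   fallback) even above 20% missingness; empty by default.
#' @param k_neighbors K for the KNN tier (default 5).
#' @return object of class `mskt_pipeline`; its `audit` element logs the
#'   tier, action and counts per feature.
#' @export
fit_pipeline <- function(cohort, train_ids, whitelist = character(),
                         k_neighbors = 5L) {
  stopifnot(inherits(cohort, "mskt_cohort"))
  roster <- cohort$spec$roster
  raw <- assemble_raw(cohort, train_ids)
  mats <- raw$matrices
  cols <- colnames(mats[[1L]])
  cont <- c("anchor_age", roster$name[roster$kind == "continuous" &
                                        roster$table != "demographics"])
  ranges <- roster[roster$name %in% cont, c("name", "lower", "upper")]

  # Hard-range removal on the training split, then winsorization statistics.
  stacked <- do.call(rbind, mats)
  for (v in cont) {
    r <- ranges[ranges$name == v, ]
    x <- stacked[, v]
    x[!is.na(x) & (x < r$lower | x > r$upper)] <- NA
    stacked[, v] <- x
  }
  wstats <- lapply(cont, function(v) {
    x <- stacked[, v]
    list(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
         q025 = stats::quantile(x, 0.025, na.rm = TRUE, names = FALSE),
         q975 = stats::quantile(x, 0.975, na.rm = TRUE, names = FALSE))
  })
  names(wstats) <- cont

  miss_rate <- colMeans(is.na(stacked))
  tiers <- vapply(cols, function(v) {
    if (miss_rate[v] > 0.20) {
      if (v %in% whitelist) "whitelist_median" else "drop"
    } else if (miss_rate[v] >= 0.05) {
      "knn"
    } else if (v %in% cont) {
      "median"
    } else {
      "mode"
    }
  }, character(1))
  kept <- cols[tiers != "drop"]

  medians <- lapply(cols, function(v) stats::median(stacked[, v], na.rm = TRUE))
  names(medians) <- cols
  modes <- lapply(cols, function(v) {
    x <- stacked[, v]
    ux <- unique(stats::na.omit(x))
    ux[which.max(tabulate(match(x, ux)))]
  })
  names(modes) <- cols

  # KNN donor pool: patient profiles over the complete (< 5% tier)
  # continuous features, median-completed and standardized.
  knn_ref_features <- cols[tiers == "median"]
  knn_features <- cols[tiers == "knn"]
  profiles <- t(vapply(seq_along(mats), function(i) {
    m <- clean_matrix(mats[[i]], ranges, wstats, cont)$matrix
    pr <- colMeans(m[, knn_ref_features, drop = FALSE], na.rm = TRUE)
    miss <- !is.finite(pr)
    pr[miss] <- unlist(medians[knn_ref_features])[miss]
    pr
  }, numeric(length(knn_ref_features))))
  rownames(profiles) <- as.character(train_ids)
  center <- colMeans(profiles)
  scl <- pmax(apply(profiles, 2L, stats::sd), 1e-8)
  donor_values <- lapply(knn_features, function(v) {
    vapply(seq_along(mats), function(i) {
      m <- clean_matrix(mats[[i]], ranges, wstats, cont)$matrix
      x <- m[, v]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
  })
  names(donor_values) <- knn_features

  pipeline <- structure(list(
    roster = roster, levels = raw$levels, columns = cols, kept = kept,
    cont = cont, ranges = ranges, wstats = wstats,
    missing_rate = miss_rate, tiers = as.list(tiers),
    medians = medians, modes = modes,
    knn = list(k = as.integer(k_neighbors), features = knn_ref_features,
               reference = sweep(sweep(profiles, 2L, center), 2L, scl, "/"),
               center = center, scale = scl, donor_values = donor_values),
    duration = cohort$spec$duration, sampling = cohort$spec$sampling,
    train_ids = train_ids, whitelist = whitelist
  ), class = "mskt_pipeline")

  # Post-imputation standardization statistics on the completed train set.
  completed <- lapply(seq_along(mats), function(i) {
    pipeline_transform(pipeline, mats[[i]], subject_id = train_ids[i])
  })
  allc <- do.call(rbind, completed)
  std_cols <- intersect(cont, kept)
  pipeline$std <- list(columns = std_cols,
                       center = colMeans(allc[, std_cols, drop = FALSE]),
                       scale = pmax(apply(allc[, std_cols, drop = FALSE], 2L,
                                          stats::sd), 1e-8))
  pipeline$audit <- data.frame(
    feature = cols, missing_rate = unname(miss_rate[cols]),
    tier = unname(unlist(pipeline$tiers[cols])),
    action = ifelse(cols %in% kept, "kept", "dropped"))
  pipeline
}

clean_matrix <- function(m, ranges, wstats, cont) {
  clean_outliers(m, ranges, wstats[intersect(cont, colnames(m))])
}

#' Apply a fitted pipeline to one raw matrix
#'
#' Hard-range removal, winsorization against the frozen training
#' statistics, and tiered imputation; returns the completed matrix on the
#' kept columns. The transform is idempotent.
#'
#' @param pipeline a fitted [fit_pipeline()].
#' @param m raw matrix with the pipeline's raw columns.
#' @param subject_id optional id for donor-pool self-exclusion.
#' @return completed numeric matrix.
#' @export
pipeline_transform <- function(pipeline, m, subject_id = NULL) {
  cl <- clean_matrix(m, pipeline$ranges, pipeline$wstats, pipeline$cont)
  tiered_impute(cl$matrix, pipeline, subject_id)
}

#' Apply a fitted pipeline to cohort subjects
#'
#' @param pipeline a fitted [fit_pipeline()].
#' @param cohort an `mskt_cohort`.
#' @param subjects subject ids (default: all).
#' @return named list of completed T x d matrices.
#' @export
apply_pipeline <- function(pipeline, cohort, subjects = NULL) {
  if (is.null(subjects)) subjects <- cohort$demographics$subject_id
  raw <- assemble_raw(cohort, subjects, levels = pipeline$levels,
                      duration = pipeline$duration, sampling = pipeline$sampling)
  out <- lapply(seq_along(subjects), function(i) {
    pipeline_transform(pipeline, raw$matrices[[i]], subject_id = subjects[i])
  })
  names(out) <- as.character(subjects)
  out
}

#' @export
print.mskt_pipeline <- function(x, ...) {
  cat(sprintf("Preprocessing pipeline fitted on %d subjects\n", length(x$train_ids)))
  cat(sprintf("  %d raw columns -> %d kept (%d dropped at > 20%% missing)\n",
              length(x$columns), length(x$kept), sum(unlist(x$tiers) == "drop")))
  tab <- table(unlist(x$tiers))
  cat("  tiers:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fitted pipeline to JSON
#'
#' @param pipeline a fitted [fit_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_json <- function(pipeline, path) {
  jsonlite::write_json(list(
    columns = pipeline$columns, kept = pipeline$kept,
    missing_rate = as.list(pipeline$missing_rate), tiers = pipeline$tiers,
    medians = pipeline$medians, modes = pipeline$modes,
    wstats = pipeline$wstats,
    std = list(columns = pipeline$std$columns,
               center = as.list(pipeline$std$center),
               scale = as.list(pipeline$std$scale)),
    whitelist = pipeline$whitelist, k_neighbors = pipeline$knn$k
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build model-ready data from a cohort and a fitted pipeline
#'
#' Applies the pipeline, z-scores the continuous columns with the frozen
#' training statistics, appends the (standardized) baseline hematoma volume
#' as an input feature, and attaches the realized volume trajectories as the
#' likelihood targets.
#'
#' @param cohort an `mskt_cohort`.
#' @param pipeline a fitted [fit_pipeline()].
#' @param subjects subject ids (default: all).
#' @param include_baseline append the baseline volume as a feature column.
#' @return an [mskt_data()] object.
#' @export
as_mskt_data <- function(cohort, pipeline, subjects = NULL,
                         include_baseline = TRUE) {
  if (is.null(subjects)) subjects <- cohort$demographics$subject_id
  mats <- apply_pipeline(pipeline, cohort, subjects)
  std <- pipeline$std
  idx <- match(subjects, cohort$demographics$subject_id)
  v0 <- cohort$truth$v0[idx]
  tr_idx <- match(pipeline$train_ids, cohort$demographics$subject_id)
  v0_center <- mean(cohort$truth$v0[tr_idx])
  v0_scale <- max(stats::sd(cohort$truth$v0[tr_idx]), 1e-8)
  feats <- lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    m[, std$columns] <- std_apply(m[, std$columns, drop = FALSE],
                                  std$center, std$scale)
    if (include_baseline) {
      m <- cbind(m, baseline_volume = (v0[i] - v0_center) / v0_scale)
    }
    m
  })
  mskt_data(feats,
            volumes = cohort$truth$V[idx, , drop = FALSE],
            v0 = v0,
            times = cohort$truth$times,
            labels = cohort$truth$label[idx],
            subject_ids = subjects)
}
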