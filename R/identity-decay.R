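#' Calibrate a linear identity-decay rate
#'
#' Anchors a constant rate of percent-identity loss to an assumed age for
#' the most recent common ancestor of the calibrating lineages. If two
#' paralogous proteins have each lost `anchor_divergence_pct` percent
#' identity since a split dated to `mrca_age_ma`, the implied chronometer
#' runs at `mrca_age_ma / anchor_divergence_pct` Ma per 1% identity loss.
#' The classic anchoring for the Photosystem I subunits is 30% divergence
#' since a cyanobacterial MRCA at the Great Oxidation Event (2400 Ma),
#' giving 80 Ma per percent.
#'
#' @param mrca_age_ma Assumed age of the calibrating ancestor, Ma (> 0).
#' @param anchor_divergence_pct Percent identity lost since that ancestor
#'   (> 0); see [anchor_divergence()].
#' @return A `decay_rate` object with fields `ma_per_pct`, `mrca_age_ma`
#'   and `anchor_divergence_pct`.
#' @examples
#' calibrate_rate(2400, 30) # 80 Ma per 1% identity loss
#' @export
calibrate_rate <- function(mrca_age_ma, anchor_divergence_pct) {
  if (!is.numeric(mrca_age_ma) || mrca_age_ma <= 0) {
    abort("mrca_age_ma must be a positive number of Ma")
  }
  if (!is.numeric(anchor_divergence_pct) || anchor_divergence_pct <= 0) {
    abort("anchor_divergence_pct must be a positive percentage")
  }
  structure(
    list(
      ma_per_pct = mrca_age_ma / anchor_divergence_pct,
      mrca_age_ma = mrca_age_ma,
      anchor_divergence_pct = anchor_divergence_pct
    ),
    class = "decay_rate"
  )
}

#' @export
print.decay_rate <- function(x, ...) {
  cat(sprintf(
    "Identity-decay rate: %d Ma per 1%% identity loss\n  (anchor: %.4g%% divergence since %.4g Ma; exact rate %.6g Ma/%%)\n",
    floor(x$ma_per_pct), x$anchor_divergence_pct, x$mrca_age_ma,
    x$ma_per_pct
  ))
  invisible(x)
}

#' @export
tidy.decay_rate <- function(x, ...) {
  tibble::tibble(
    ma_per_pct = x$ma_per_pct,
    mrca_age_ma = x$mrca_age_ma,
    anchor_divergence_pct = x$anchor_divergence_pct
  )
}

# Accept either a decay_rate object or a bare Ma-per-percent number.
as_decay_rate <- function(rate) {
  if (inherits(rate, "decay_rate")) return(rate)
  if (is.numeric(rate) && length(rate) == 1 && rate > 0) {
    return(structure(
      list(ma_per_pct = rate, mrca_age_ma = NA_real_,
           anchor_divergence_pct = NA_real_),
      class = "decay_rate"
    ))
  }
  abort("rate must be a decay_rate object or a positive Ma-per-percent value")
}

#' Average divergence accumulated by two paralogues
#'
#' Converts two percent identities (each measured between orthologues of
#' one paralogue) to divergences (100 - identity) and averages them,
#' producing the anchoring divergence used by [calibrate_rate()].
#'
#' @param identity_a_pct,identity_b_pct Percent identities in `[0, 100]`.
#' @return Mean percent divergence.
#' @examples
#' anchor_divergence(66.5, 72.8) # 30.35, conventionally rounded to 30
#' @export
anchor_divergence <- function(identity_a_pct, identity_b_pct) {
  for (x in c(identity_a_pct, identity_b_pct)) {
    if (!is.numeric(x) || x < 0 || x > 100) {
      abort("identities must lie in [0, 100]")
    }
  }
  mean(c(100 - identity_a_pct, 100 - identity_b_pct))
}

#' Predict percent identity after a given elapsed time
#'
#' Under the linear chronometer, identity declines from 100% at a constant
#' rate; predictions are floored at 0% for ages beyond the rate's range
#' (no correction for multiple substitutions is attempted -- the model is
#' deliberately a straight line).
#'
#' @param rate A `decay_rate` (or Ma-per-percent value).
#' @param age_ma Elapsed time in Ma (vectorised, each >= 0).
#' @return Predicted percent identity.
#' @examples
#' r <- calibrate_rate(2400, 30)
#' predict_identity(r, c(449, 1024)) # 94.39, 87.2
#' @export
predict_identity <- function(rate, age_ma) {
  rate <- as_decay_rate(rate)
  if (any(!is.finite(age_ma)) || any(age_ma < 0)) {
    abort("age_ma must be non-negative")
  }
  pmax(0, 100 - age_ma / rate$ma_per_pct)
}

#' Extrapolate a divergence age from percent identity
#'
#' Inverts the linear chronometer: an observed identity of `p` percent
#' implies `(100 - p) * ma_per_pct` Ma of divergence.
#'
#' @param rate A `decay_rate` (or Ma-per-percent value).
#' @param identity_pct Observed percent identity in `[0, 100]` (vectorised).
#' @return A tibble with columns `identity_pct`, `ma_per_pct`,
#'   `mrca_age_ma`, `age_ma` and `age_ga`.
#' @examples
#' extrapolate_age(calibrate_rate(2400, 30), 42.5) # 4600 Ma = 4.6 Ga
#' @export
extrapolate_age <- function(rate, identity_pct) {
  rate <- as_decay_rate(rate)
  if (any(!is.finite(identity_pct)) || any(identity_pct < 0) ||
      any(identity_pct > 100)) {
    abort("identity_pct must lie in [0, 100]")
  }
  age_ma <- (100 - identity_pct) * rate$ma_per_pct
  tibble::tibble(
    identity_pct = identity_pct,
    ma_per_pct = rate$ma_per_pct,
    mrca_age_ma = rate$mrca_age_ma,
    age_ma = age_ma,
    age_ga = age_ma / 1000
  )
}

#' Scan duplication-age extrapolations over MRCA assumptions
#'
#' Recalibrates the decay rate for each assumed MRCA age and extrapolates
#' the age implied by a target percent identity, exposing how the inferred
#' duplication age depends on the anchoring assumption. Because the
#' chronometer is linear, the extrapolated age is strictly increasing in
#' the MRCA age at fixed divergence and identity.
#'
#' @param mrca_ages_ma Non-empty vector of candidate MRCA ages, Ma.
#' @param anchor_divergence_pct Anchoring divergence, percent.
#' @param target_identity_pct Identity whose age is extrapolated.
#' @param use_reported_rate Extrapolate with the rate constant floored to
#'   whole Ma per percent (the convention for printed rates, under which a
#'   2000 Ma anchor gives 66 Ma/% and hence 3795 Ma at 42.5% identity).
#'   Set `FALSE` for full-precision rates, which also makes the scan
#'   strictly monotone in the MRCA age.
#' @return A tibble with one row per MRCA age.
#' @examples
#' mrca_sensitivity_scan(c(2000, 2400, 3000), 30, 42.5)
#' @export
mrca_sensitivity_scan <- function(mrca_ages_ma, anchor_divergence_pct,
                                  target_identity_pct,
                                  use_reported_rate = TRUE) {
  if (length(mrca_ages_ma) == 0) {
    abort("mrca_ages_ma must be non-empty")
  }
  purrr::map_dfr(mrca_ages_ma, function(m) {
    r <- calibrate_rate(m, anchor_divergence_pct)
    if (use_reported_rate) r <- as_decay_rate(floor(r$ma_per_pct))
    out <- extrapolate_age(r, target_identity_pct)
    out$mrca_age_ma <- m
    out
  })
}

#' Check observed identities against fossil age windows
#'
#' For each record carrying at least one fossil age bound, predicts the
#' identity expected at the bound(s) under a calibrated decay rate and
#' reports whether the observed identity falls inside the predicted band.
#' Older ages predict lower identity, so a `[age_min, age_max]` window maps
#' to the identity band `[predict(age_max), predict(age_min)]`. Records
#' with no age information are skipped with a warning.
#'
#' @param records An identity tibble (see [identity_table()]).
#' @param rate A `decay_rate` (or Ma-per-percent value).
#' @return A tibble with predicted identities at each bound, the
#'   back-extrapolated age of each record, and a `consistent` flag.
#' @export
fossil_consistency_check <- function(records, rate) {
  rate <- as_decay_rate(rate)
  records <- tibble::as_tibble(records)
  lo <- if ("age_min_ma" %in% names(records)) records$age_min_ma else
    rep(NA_real_, nrow(records))
  hi <- if ("age_max_ma" %in% names(records)) records$age_max_ma else
    rep(NA_real_, nrow(records))
  pt <- if ("divergence_age_ma" %in% names(records))
    records$divergence_age_ma else rep(NA_real_, nrow(records))
  # a point age stands in for both bounds when no window is given
  lo <- ifelse(is.na(lo), pt, lo)
  hi <- ifelse(is.na(hi), pt, hi)
  no_age <- is.na(lo) & is.na(hi)
  if (any(no_age)) {
    warn(paste0(sum(no_age), " record(s) without age bounds were skipped"))
  }
  out <- records[!no_age, , drop = FALSE]
  lo <- lo[!no_age]
  hi <- hi[!no_age]
  pred_at_min <- ifelse(is.na(lo), NA_real_,
                        predict_identity(rate, pmax(lo, 0)))
  pred_at_max <- ifelse(is.na(hi), NA_real_,
                        predict_identity(rate, pmax(hi, 0)))
  obs <- out$identity_pct
  consistent <- (is.na(pred_at_min) | obs <= pred_at_min) &
    (is.na(pred_at_max) | obs >= pred_at_max)
  mid <- ifelse(is.na(lo), hi, ifelse(is.na(hi), lo, (lo + hi) / 2))
  dplyr::bind_cols(
    out,
    tibble::tibble(
      pred_identity_at_min = pred_at_min,
      pred_identity_at_max = pred_at_max,
      # observed minus predicted at the window midpoint: the informative
      # summary for point-dated records, whose window has zero width
      deviation_pct = obs - predict_identity(rate, pmax(mid, 0)),
      extrapolated_age_ma = (100 - obs) * rate$ma_per_pct,
      consistent = consistent
    )
  )
}

#' Presentation rounding for ages and rates
#'
#' Ages are reported in Ga truncated to two decimals (3795 Ma prints as
#' 3.79 Ga) or in Ma to the nearest integer; rate constants are floored to
#' whole Ma per percent (so a 2000 Ma anchor over 30% reports as 66 Ma/%).
#' Internal arithmetic is never rounded.
#'
#' @param age_ma Age in Ma.
#' @param rate A `decay_rate` or Ma-per-percent value.
#' @return A formatted number.
#' @export
report_age_ga <- function(age_ma) {
  trunc(age_ma / 10) / 100
}

#' @rdname report_age_ga
#' @export
report_age_ma <- function(age_ma) {
  round(age_ma)
}

#' @rdname report_age_ga
#' @export
report_rate <- function(rate) {
  floor(as_decay_rate(rate)$ma_per_pct)
}
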