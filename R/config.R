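#' Study configuration
#'
#' Bundles every analysis-wide constant: the study window, the referral-gap
#' window (inclusive, in days), the low-productivity factor, the significance
#' level and the root random seed. All downstream stages read their settings
#' from this object so a whole analysis is reproducible from one value.
#'
#' @param study_start,study_end Calendar dates (anything `as.Date()` accepts)
#'   bounding the visit extraction window.
#' @param referral_min_gap,referral_max_gap Inclusive bounds, in days, of the
#'   gap between two visits that defines a referral. Defaults 7 and 45: the
#'   interval in which most referrals between office-based physicians occur.
#' @param productivity_factor A physician is flagged as having low consultation
#'   productivity when their volume is strictly below this fraction of the mean
#'   volume of their specialty. Default 0.2.
#' @param alpha Two-tailed significance level for all tests. Default 0.05.
#' @param seed Root random seed; every stochastic stage derives its own seed
#'   from it.
#' @param consecutive_only If `TRUE`, only consecutive visit pairs of a patient
#'   are eligible as referrals; the default considers every ordered pair.
#' @param unique_patients If `TRUE`, several qualifying pairs from one patient
#'   between the same two physicians count once; the default counts each event.
#' @param dedupe_visits If `TRUE`, identical visit rows are collapsed on read;
#'   default keeps them (claims can legitimately repeat).
#' @param window_action What to do with visits dated outside the study window:
#'   `"flag"` (keep, mark), `"drop"` or `"error"`.
#' @param weighted_distance How edge weights enter shortest-path computations:
#'   `"as_is"` passes Ew directly as edge length (the toolchain default the
#'   source analyses relied on); `"inverse_weight"` uses 1/Ew so stronger ties
#'   are shorter.
#'
#' @return A list with class `"study_config"`.
#' @examples
#' cfg <- study_config("2021-04-01", "2022-05-15", seed = 1)
#' cfg$referral_max_gap
#' @export
study_config <- function(study_start = "2021-04-01",
                         study_end = "2022-05-15",
                         referral_min_gap = 7L,
                         referral_max_gap = 45L,
                         productivity_factor = 0.2,
                         alpha = 0.05,
                         seed = 1L,
                         consecutive_only = FALSE,
                         unique_patients = FALSE,
                         dedupe_visits = FALSE,
                         window_action = c("flag", "drop", "error"),
                         weighted_distance = c("as_is", "inverse_weight")) {
  window_action <- match.arg(window_action)
  weighted_distance <- match.arg(weighted_distance)
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (is.na(study_start) || is.na(study_end) || study_start > study_end) {
    abort("`study_start` must be a valid date not after `study_end`.")
  }
  referral_min_gap <- as.integer(referral_min_gap)
  referral_max_gap <- as.integer(referral_max_gap)
  if (referral_min_gap <= 0L || referral_min_gap > referral_max_gap) {
    abort("Need 0 < referral_min_gap <= referral_max_gap.")
  }
  if (productivity_factor <= 0 || productivity_factor >= 1) {
    abort("`productivity_factor` must lie strictly between 0 and 1.")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1.")
  }
  structure(
    list(
      study_start = study_start,
      study_end = study_end,
      referral_min_gap = referral_min_gap,
      referral_max_gap = referral_max_gap,
      productivity_factor = productivity_factor,
      alpha = alpha,
      seed = as.integer(seed),
      consecutive_only = isTRUE(consecutive_only),
      unique_patients = isTRUE(unique_patients),
      dedupe_visits = isTRUE(dedupe_visits),
      window_action = window_action,
      weighted_distance = weighted_distance
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  window      :", format(x$study_start), "to", format(x$study_end), "\n")
  cat("  referral gap: [", x$referral_min_gap, ",", x$referral_max_gap, "] days\n")
  cat("  productivity:", x$productivity_factor, " alpha:", x$alpha,
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Read or write a study configuration as YAML
#'
#' @param path Path to a YAML file whose keys match [study_config()] arguments.
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(study_config, vals)
}

#' @rdname read_study_config
#' @param config A `study_config` object.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  vals <- unclass(config)
  vals$study_start <- format(vals$study_start)
  vals$study_end <- format(vals$study_end)
  yaml::write_yaml(vals, path)
  invisible(path)
}

# derive a stage-specific seed from the root seed (kept < 2^31)
stage_seed <- function(config, stage) {
  offsets <- c(simulate = 11L, build = 23L, measure = 37L,
               profile = 53L, communities = 71L, associate = 89L)
  off <- offsets[[stage]] %||% 101L
  as.integer((as.numeric(config$seed) * 1000 + off) %% 2147483647)
}
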