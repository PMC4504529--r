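# Subjective-analysis bookkeeping: the segment x patient x dose-level score
# ledger with exclusion propagation, dichotomization of the 1-5 quality
# score, and a synthetic score generator standing in for human readers.

#' Build an empty score ledger
#'
#' One cell per (vessel segment x patient x dose level). A segment excluded
#' for a patient (occluded or surgically absent vessels cannot be scored at
#' any dose) is excluded at *every* dose level, so each exclusion pair
#' removes `n_dose_levels` cells.
#'
#' @param n_segments,n_patients,n_dose_levels positive axis sizes (the
#'   canonical study: 40 segments x 30 patients x 4 dose levels).
#' @param exclusions data.frame with columns `segment`, `patient` (1-based
#'   indices) and optionally `reason`; duplicate pairs are an error.
#' @param dose_levels optional labels for the dose axis (default
#'   `"dose_1"`, ...).
#' @return a data.frame of class `score_ledger` with columns `segment`,
#'   `patient`, `dose_level`, `excluded`, `reason`, `score` (all `NA`
#'   until filled).
#' @export
build_ledger <- function(n_segments, n_patients, n_dose_levels,
                         exclusions = NULL, dose_levels = NULL) {
  if (n_segments < 1 || n_patients < 1 || n_dose_levels < 1)
    stop("ledger axis sizes must be positive", call. = FALSE)
  if (is.null(dose_levels))
    dose_levels <- paste0("dose_", seq_len(n_dose_levels))
  stopifnot(length(dose_levels) == n_dose_levels)
  led <- expand.grid(
    segment = seq_len(n_segments),
    patient = seq_len(n_patients),
    dose_level = dose_levels,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  led$excluded <- FALSE
  led$reason <- NA_character_
  led$score <- NA_integer_
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    if (!all(c("segment", "patient") %in% names(exclusions)))
      stop("exclusions need columns 'segment' and 'patient'", call. = FALSE)
    key <- paste(exclusions$segment, exclusions$patient)
    if (anyDuplicated(key))
      stop("duplicate exclusion entries", call. = FALSE)
    if (any(exclusions$segment < 1 | exclusions$segment > n_segments |
            exclusions$patient < 1 | exclusions$patient > n_patients))
      stop("exclusion indices out of range", call. = FALSE)
    reason <- if ("reason" %in% names(exclusions)) exclusions$reason
              else rep("occluded_or_resected", nrow(exclusions))
    hit <- match(paste(led$segment, led$patient), key)
    led$excluded <- !is.na(hit)
    led$reason[led$excluded] <- reason[hit[led$excluded]]
  }
  class(led) <- c("score_ledger", "data.frame")
  led
}

#' Ledger cell counts
#'
#' @param ledger a `score_ledger`.
#' @return list with `total`, `scored` (= scorable, i.e. not excluded) and
#'   `excluded` cell counts; `scored + excluded = total` always.
#' @export
ledger_counts <- function(ledger) {
  stopifnot(inherits(ledger, "score_ledger"))
  total <- nrow(ledger)
  excluded <- sum(ledger$excluded)
  list(total = total, scored = total - excluded, excluded = excluded)
}

#' @export
print.score_ledger <- function(x, ...) {
  ct <- ledger_counts(x)
  cat(sprintf(
    "<score_ledger> %d cells (%d scorable, %d excluded), %d dose level(s)\n",
    ct$total, ct$scored, ct$excluded, length(unique(x$dose_level))
  ))
  invisible(x)
}

#' Dichotomize quality scores
#'
#' Maps the ordinal 1-5 vessel-definition score to diagnostic categories:
#' 1-2 (no diagnostic / poor definition) are `"nondiagnostic"`, 3-5
#' (moderate / good / excellent) are `"diagnostic"`. `NA` (unscored or
#' excluded) stays `NA`.
#'
#' @param score integer vector of scores in 1..5 (NA allowed).
#' @return character vector of `"diagnostic"` / `"nondiagnostic"`.
#' @export
dichotomize <- function(score) {
  ok <- is.na(score) | (score %in% 1:5)
  if (!all(ok))
    stop("scores must be integers in 1..5", call. = FALSE)
  ifelse(is.na(score), NA_character_,
         ifelse(score <= 2, "nondiagnostic", "diagnostic"))
}

#' Fill a ledger with synthetic reader scores
#'
#' Stands in for human readers: each scorable cell gets a latent quality
#' `a * log(SNR)` for its dose level plus Gaussian reader noise, rounded
#' and clamped to the 1-5 scale. Monotone in SNR, so higher-dose (higher
#' SNR) levels stochastically dominate; with `reader_sd = 0` the mapping
#' is deterministic. Purely a fixture - it models no actual reader.
#'
#' @param ledger a `score_ledger` from [build_ledger()].
#' @param snr_by_dose named numeric vector mapping every dose level of the
#'   ledger to an SNR.
#' @param seed integer seed.
#' @param a latent-scale gain on `log(SNR)`.
#' @param reader_sd SD of the additive reader noise on the latent scale.
#' @return the ledger with `score` filled for all non-excluded cells.
#' @export
synth_scores <- function(ledger, snr_by_dose, seed = 1L, a = 1.35,
                         reader_sd = 0.6) {
  stopifnot(inherits(ledger, "score_ledger"))
  lev <- unique(ledger$dose_level)
  if (!all(lev %in% names(snr_by_dose)))
    stop("snr_by_dose is missing dose level(s): ",
         paste(setdiff(lev, names(snr_by_dose)), collapse = ", "),
         call. = FALSE)
  if (any(snr_by_dose <= 0)) stop("SNR values must be positive", call. = FALSE)
  latent <- a * log(as.numeric(snr_by_dose[ledger$dose_level]))
  set.seed(substream_seed(seed, "reader"))
  latent <- latent + stats::rnorm(nrow(ledger), 0, reader_sd)
  sc <- pmin(5L, pmax(1L, as.integer(round(latent))))
  sc[ledger$excluded] <- NA_integer_
  ledger$score <- sc
  ledger
}

#' Per-dose-level score summary
#'
#' @param ledger a filled `score_ledger`.
#' @return data.frame per dose level: median score, 25th/75th percentiles,
#'   counts of diagnostic and nondiagnostic segments.
#' @export
summarize_scores <- function(ledger) {
  stopifnot(inherits(ledger, "score_ledger"))
  sp <- split(ledger[!ledger$excluded, ], ledger$dose_level[!ledger$excluded])
  out <- do.call(rbind, lapply(names(sp), function(lv) {
    s <- sp[[lv]]$score
    di <- dichotomize(s)
    data.frame(
      dose_level = lv, n = length(s),
      median = stats::median(s, na.rm = TRUE),
      q25 = as.numeric(stats::quantile(s, 0.25, na.rm = TRUE)),
      q75 = as.numeric(stats::quantile(s, 0.75, na.rm = TRUE)),
      diagnostic = sum(di == "diagnostic", na.rm = TRUE),
      nondiagnostic = sum(di == "nondiagnostic", na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
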