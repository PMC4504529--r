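# Statistical toolkit for comparing true and simulated dose series: exact
# sign test, Mann-Whitney U with exact small-sample enumeration, and
# unweighted Cohen's kappa with the conventional agreement bands.

new_test_result <- function(statistic, p_value, n_effective, method_note) {
  structure(
    list(statistic = statistic, p_value = p_value,
         n_effective = n_effective, method_note = method_note),
    class = "ldct_test"
  )
}

#' @export
print.ldct_test <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %g, p = %.4g, n = %d\n",
              x$method_note, x$statistic, x$p_value, x$n_effective))
  invisible(x)
}

#' Exact sign test for paired samples
#'
#' Two-sided exact binomial test on the signs of the paired differences
#' `a - b`; tied pairs are dropped. The p-value doubles the smaller tail of
#' `Binomial(n, 1/2)` and is capped at 1. Used to compare per-ROI noise
#' (SD) between true scans and matched dose simulations.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return an `ldct_test` with `statistic` = number of positive
#'   differences and `n_effective` = number of untied pairs. All pairs
#'   tied gives p = 1 with a warning.
#' @export
sign_test <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all pairs tied; sign test p-value is 1", call. = FALSE)
    return(new_test_result(0, 1, 0L, "exact sign test (all pairs tied)"))
  }
  k <- sum(d > 0)
  p <- min(1, 2 * min(stats::pbinom(k, n, 0.5),
                      stats::pbinom(n - k, n, 0.5)))
  new_test_result(k, p, as.integer(n),
                  "exact sign test (two-sided, ties dropped)")
}

# U statistic for sample x against pooled midranks; used by both the main
# path and the exact enumeration.
.u_stat <- function(ranks_x, n1) {
  sum(ranks_x) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent samples,
#' with midranks for ties. For combined sample sizes `n1 + n2 <= 12` the
#' two-sided p-value is exact, by enumeration of all assignments of the
#' pooled values to groups (ties handled naturally through the midranks);
#' larger samples use the normal approximation with tie correction and
#' continuity correction. Used to compare mean attenuation between true and
#' simulated scans.
#'
#' @param x,y numeric samples (non-empty).
#' @return an `ldct_test` with `statistic` = U for `x`.
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- .u_stat(rk[seq_len(n1)], n1)
  mu <- n1 * n2 / 2

  if (n1 + n2 <= 12) {
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2, function(ii) .u_stat(rk[ii], n1))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    note <- "Mann-Whitney U (exact enumeration, midranks)"
  } else {
    nt <- table(pooled)
    N <- n1 + n2
    tie_term <- sum(nt^3 - nt) / (N * (N - 1))
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sig2)
      p <- 2 * stats::pnorm(-max(z, 0))
    }
    note <- "Mann-Whitney U (normal approximation, tie + continuity correction)"
  }
  new_test_result(U, min(p, 1), as.integer(n1 + n2), note)
}

#' Unweighted Cohen's kappa with agreement bands
#'
#' Chance-corrected agreement between two raters on a shared category set:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginal distributions. The label uses
#' the conventional bands: <= 0 none, (0, 0.2] slight, (0.2, 0.4] fair,
#' (0.4, 0.6] moderate, (0.6, 0.8] substantial, (0.8, 1] almost perfect.
#'
#' @param r1,r2 equal-length rating vectors (coerced to a shared factor).
#' @return list of class `kappa_result`: `kappa`, `band`, `p_o`, `p_e`,
#'   `n`, `defined` (`FALSE` when both raters use a single category, where
#'   `p_e = 1` leaves kappa undefined).
#' @export
cohen_kappa <- function(r1, r2) {
  if (length(r1) != length(r2))
    stop("ratings must have equal length", call. = FALSE)
  if (length(r1) == 0) stop("ratings are empty", call. = FALSE)
  keep <- !(is.na(r1) | is.na(r2))
  r1 <- r1[keep]; r2 <- r2[keep]
  lev <- sort(unique(c(as.character(r1), as.character(r2))))
  f1 <- factor(as.character(r1), levels = lev)
  f2 <- factor(as.character(r2), levels = lev)
  n <- length(f1)
  tab <- table(f1, f2)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < .Machine$double.eps^0.5) {
    return(structure(
      list(kappa = NA_real_, band = NA_character_, p_o = p_o, p_e = p_e,
           n = n, defined = FALSE),
      class = "kappa_result"
    ))
  }
  k <- (p_o - p_e) / (1 - p_e)
  structure(
    list(kappa = k, band = kappa_band(k), p_o = p_o, p_e = p_e, n = n,
         defined = TRUE),
    class = "kappa_result"
  )
}

#' Agreement band for a kappa value
#' @param kappa numeric kappa in [-1, 1].
#' @return character band label.
#' @export
kappa_band <- function(kappa) {
  stopifnot(is.numeric(kappa), kappa >= -1, kappa <= 1 + 1e-12)
  if (kappa <= 0) "no agreement"
  else if (kappa <= 0.2) "slight"
  else if (kappa <= 0.4) "fair"
  else if (kappa <= 0.6) "moderate"
  else if (kappa <= 0.8) "substantial"
  else "almost perfect"
}

#' @export
print.kappa_result <- function(x, ...) {
  if (!x$defined) {
    cat("Cohen's kappa undefined (single category used by both raters)\n")
  } else {
    cat(sprintf("Cohen's kappa = %.3f (%s agreement), n = %d\n",
                x$kappa, x$band, x$n))
  }
  invisible(x)
}
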