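# Paired dual-time-point cohort statistics: PET-1 vs PET-2 comparisons
# with automatic parametric/non-parametric selection, Spearman
# associations of texture with MTV/TLG, and MTV stratification.

# Aligned PET1/PET2 values of one variable for complete pairs.
paired_values <- function(cohort, variable) {
  stopifnot(inherits(cohort, "paired_cohort"))
  if (!variable %in% names(cohort))
    stop("unknown variable: ", variable, call. = FALSE)
  ids <- complete_pairs(cohort)
  w1 <- cohort[cohort$timepoint == "PET1" & cohort$patient %in% ids, ]
  w2 <- cohort[cohort$timepoint == "PET2" & cohort$patient %in% ids, ]
  w2 <- w2[match(w1$patient, w2$patient), ]
  list(patient = w1$patient, pet1 = w1[[variable]], pet2 = w2[[variable]])
}

#' Paired PET-1 vs PET-2 comparison of one variable
#'
#' Compares a variable between the standard and the delayed acquisition
#' over complete patient pairs. The test is selected from the paired
#' differences: Shapiro-Wilk at the 0.05 level decides between the paired
#' T test (normal differences) and the Wilcoxon signed-rank test
#' (otherwise). The reported statistic (T, or the signed-rank normal
#' deviate Z) is signed so that a negative value means the PET-1 value was
#' lower than PET-2.
#'
#' @param cohort A [paired_cohort()].
#' @param variable Feature column name.
#' @param alpha Significance level, default 0.05.
#' @return An object of class `test_result`: variable, per-timepoint mean
#'   and SD, test used, signed statistic, p value, significance flag, n.
#' @export
paired_compare <- function(cohort, variable, alpha = 0.05) {
  pv <- paired_values(cohort, variable)
  n <- length(pv$pet1)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  d <- pv$pet1 - pv$pet2
  res <- list(variable = variable, n = n,
              mean_pet1 = mean(pv$pet1), sd_pet1 = stats::sd(pv$pet1),
              mean_pet2 = mean(pv$pet2), sd_pet2 = stats::sd(pv$pet2),
              alpha = alpha)
  if (all(d == 0)) {
    warning("degenerate paired test for '", variable,
            "': all differences are zero", call. = FALSE)
    res$test <- "wilcoxon"
    res$statistic <- 0
    res$p <- 1
    res$significant <- FALSE
    class(res) <- "test_result"
    return(res)
  }
  normal <- stats::sd(d) > 0 &&
    tryCatch(stats::shapiro.test(d)$p.value >= 0.05,
             error = function(e) FALSE)
  if (normal) {
    tt <- stats::t.test(pv$pet1, pv$pet2, paired = TRUE)
    res$test <- "paired-T"
    res$statistic <- unname(tt$statistic)   # sign of mean(PET1 - PET2)
    res$p <- tt$p.value
  } else {
    dz <- d[d != 0]
    rk <- rank(abs(dz))                     # midranks for tied magnitudes
    w_pos <- sum(rk[dz > 0])
    nz <- length(dz)
    mu <- nz * (nz + 1) / 4
    ties <- table(rk)
    sig2 <- nz * (nz + 1) * (2 * nz + 1) / 24 - sum(ties^3 - ties) / 48
    res$test <- "wilcoxon"
    res$statistic <- (w_pos - mu) / sqrt(sig2)  # negative: PET1 < PET2
    res$p <- suppressWarnings(
      stats::wilcox.test(pv$pet1, pv$pet2, paired = TRUE)$p.value)
  }
  res$significant <- res$p < alpha
  class(res) <- "test_result"
  res
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: %.3f +/- %.3f (PET-1) vs %.3f +/- %.3f (PET-2)\n",
              x$variable, x$mean_pet1, x$sd_pet1, x$mean_pet2, x$sd_pet2))
  cat(sprintf("  %s: statistic %.3f, p = %.4g%s (n = %d)\n", x$test,
              x$statistic, x$p, if (x$significant) " *" else "", x$n))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties; the p value comes from the
#' standard large-sample t approximation
#' `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom. Correlations
#' with `|r| > strong_cutoff` (default 0.75) are flagged strong.
#'
#' @param x,y Numeric vectors of equal length.
#' @param strong_cutoff Absolute-r threshold for the strong flag.
#' @return An object of class `correlation_result`: `r`, `p`, `strong`,
#'   `n`.
#' @export
spearman <- function(x, y, strong_cutoff = 0.75) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Spearman correlation undefined (constant input or n < 3)",
            call. = FALSE)
    return(structure(list(r = NA_real_, p = NA_real_, strong = NA, n = n),
                     class = "correlation_result"))
  }
  r <- stats::cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p = p, strong = abs(r) > strong_cutoff, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman r = %.3f (p = %.4g, n = %d)%s\n", x$r, x$p, x$n,
              if (isTRUE(x$strong)) " [strong]" else ""))
  invisible(x)
}

#' Texture vs volume association table
#'
#' Spearman correlations of every textural variable at each timepoint
#' against MTV and TLG at each timepoint, with strong associations
#' (|r| > 0.75) flagged — the texture-volume confounding structure of the
#' cohort.
#'
#' @param cohort A [paired_cohort()].
#' @param strong_cutoff Absolute-r threshold for the strong flag.
#' @return A data.frame (class `texture_volume_table`) with columns
#'   `texture_var`, `texture_tp`, `volume_var`, `volume_tp`, `r`, `p`,
#'   `strong`.
#' @export
texture_volume_table <- function(cohort, strong_cutoff = 0.75) {
  stopifnot(inherits(cohort, "paired_cohort"))
  tex <- setdiff(feature_columns(),
                 c("suv_max", "suv_mean", "suv_peak", "mtv_cm3", "tlg"))
  ids <- complete_pairs(cohort)
  grab <- function(var, tp) {
    w <- cohort[cohort$timepoint == tp & cohort$patient %in% ids, ]
    w[[var]][match(ids, w$patient)]
  }
  grid <- expand.grid(texture_var = tex, texture_tp = c("PET1", "PET2"),
                      volume_var = c("mtv_cm3", "tlg"),
                      volume_tp = c("PET1", "PET2"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cr <- withCallingHandlers(
      spearman(grab(grid$texture_var[i], grid$texture_tp[i]),
               grab(grid$volume_var[i], grid$volume_tp[i]),
               strong_cutoff = strong_cutoff),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(grid[i, ], r = cr$r, p = cr$p, strong = cr$strong)
  })
  out <- do.call(rbind, res)
  if (anyNA(out$r))
    warning("some correlations are undefined (constant variables)",
            call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("texture_volume_table", "data.frame")
  out
}

#' Stratify patients by metabolic tumor volume
#'
#' Splits the cohort at an MTV cutoff measured at one timepoint:
#' group I has MTV <= cutoff (boundary inclusive), group II has
#' MTV > cutoff.
#'
#' @param cohort A [paired_cohort()].
#' @param cutoff_cm3 MTV cutoff in cm^3, default 10.
#' @param timepoint Timepoint whose MTV defines the split, default PET1.
#' @return A list with [paired_cohort()] elements `group_I` and
#'   `group_II`.
#' @export
stratify_by_mtv <- function(cohort, cutoff_cm3 = 10, timepoint = "PET1") {
  stopifnot(inherits(cohort, "paired_cohort"))
  ref <- cohort[cohort$timepoint == timepoint, ]
  small <- ref$patient[ref$mtv_cm3 <= cutoff_cm3]
  sub <- function(ids) {
    out <- cohort[cohort$patient %in% ids, ]
    class(out) <- c("paired_cohort", "data.frame")
    out
  }
  g1 <- sub(small)
  g2 <- sub(setdiff(ref$patient, small))
  if (nrow(g1) == 0L || nrow(g2) == 0L)
    warning("MTV stratification produced an empty group", call. = FALSE)
  list(group_I = g1, group_II = g2)
}

#' Full PET-1 vs PET-2 comparison report
#'
#' Runs [paired_compare()] for every feature column — the five SUV/volume
#' metrics and the eighteen textural features, 23 rows — with optional
#' multiple-testing correction of the p column (off by default).
#'
#' @param cohort A [paired_cohort()].
#' @param alpha Significance level, default 0.05.
#' @param correction `"none"` (default), `"holm"` or `"bonferroni"`.
#' @return A data.frame (class `timepoint_report`) with one row per
#'   variable: means and SDs per timepoint, test used, signed statistic
#'   (negative: PET-1 lower), p (corrected if requested), significance.
#' @export
compare_timepoints <- function(cohort, alpha = 0.05,
                               correction = c("none", "holm", "bonferroni")) {
  correction <- match.arg(correction)
  rows <- lapply(feature_columns(), function(v) {
    r <- withCallingHandlers(paired_compare(cohort, v, alpha = alpha),
                             warning = function(w)
                               invokeRestart("muffleWarning"))
    data.frame(variable = v, mean_pet1 = r$mean_pet1, sd_pet1 = r$sd_pet1,
               mean_pet2 = r$mean_pet2, sd_pet2 = r$sd_pet2,
               test = r$test, statistic = r$statistic, p = r$p)
  })
  out <- do.call(rbind, rows)
  if (correction != "none") out$p <- stats::p.adjust(out$p, correction)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  class(out) <- c("timepoint_report", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  out
}

#' @export
print.timepoint_report <- function(x, digits = 3, ...) {
  cat("PET-1 vs PET-2 paired comparison (alpha =", attr(x, "alpha"),
      ", correction =", attr(x, "correction"), ")\n")
  df <- as.data.frame(x)
  df$mean_pet1 <- sprintf("%.*f +/- %.*f", digits, df$mean_pet1,
                          digits, df$sd_pet1)
  df$mean_pet2 <- sprintf("%.*f +/- %.*f", digits, df$mean_pet2,
                          digits, df$sd_pet2)
  df$sd_pet1 <- df$sd_pet2 <- NULL
  df$statistic <- sprintf("%.2f", df$statistic)
  df$p <- sprintf("%.4f%s", df$p, ifelse(df$significant, " *", ""))
  df$significant <- NULL
  names(df) <- c("variable", "PET-1", "PET-2", "test", "T/Z", "p")
  print(df, row.names = FALSE)
  invisible(x)
}
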