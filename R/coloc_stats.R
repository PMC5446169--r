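# Ki-67/CD31 co-localization statistics and Gleason group comparisons.

#' Proliferative vascular index (PVI)
#'
#' The PVI of a sample is the ratio of its Ki-67 stain fraction
#' (proliferation) to its CD31 stain fraction (vascularity), measured on
#' consecutive sections of the same tissue. A zero CD31 fraction leaves the
#' ratio undefined and is an error; such samples must be excluded upstream.
#'
#' @param ki67_fraction,cd31_fraction Stain fractions in [0, 1]; vectors are
#'   accepted and divided elementwise.
#' @return Numeric vector of ratios.
#' @examples
#' compute_pvi(0.02, 0.04)
#' @export
compute_pvi <- function(ki67_fraction, cd31_fraction) {
  stopifnot(length(ki67_fraction) == length(cd31_fraction))
  if (any(is.na(ki67_fraction)) || any(is.na(cd31_fraction)))
    stop("undefined stain fractions: exclude samples with NA before ",
         "computing ratios")
  if (any(cd31_fraction == 0))
    stop("PVI undefined for sample(s) with CD31 fraction 0: ",
         paste(which(cd31_fraction == 0), collapse = ", "))
  if (any(ki67_fraction < 0 | ki67_fraction > 1) ||
      any(cd31_fraction < 0 | cd31_fraction > 1))
    stop("stain fractions must lie in [0, 1]")
  ki67_fraction / cd31_fraction
}

#' Categorize a Gleason score as low or high grade
#'
#' Scores of 7 or less are low grade; 8 or more are high grade.
#'
#' @param score Integer Gleason scores (valid range 2 to 10).
#' @return Factor with levels \code{low}, \code{high}.
#' @examples
#' categorize_gleason(c(6, 7, 8, 9))
#' @export
categorize_gleason <- function(score) {
  if (any(is.na(score)) || any(score != as.integer(score)) ||
      any(score < 2) || any(score > 10))
    stop("Gleason scores must be integers between 2 and 10")
  if (any(score < 6))
    warning("Gleason score(s) below 6 are unusual in modern cohorts")
  factor(ifelse(score <= 7, "low", "high"), levels = c("low", "high"))
}

#' Compare a measurement between low- and high-grade groups
#'
#' Runs the classical two-sample equal-variance Student's t-test
#' (two-tailed, df = n1 + n2 - 2) on per-sample values split by grade
#' category, and flags significance at \code{alpha_level}. Welch's unequal
#' variance form is available for sensitivity analysis.
#'
#' @param values Numeric per-sample measurements (stain fractions or PVI).
#' @param labels Group labels, coercible to a factor with levels
#'   \code{low}, \code{high} (see [categorize_gleason()]).
#' @param alpha_level Significance level for the flag.
#' @param welch Use Welch's test instead of the pooled-variance form.
#' @return An object of class \code{group_comparison}: \code{t_stat}
#'   (low minus high), \code{df}, \code{p_value}, \code{significant},
#'   \code{alpha_level}, group sizes and means.
#' @examples
#' compare_groups(c(2, 4, 6, 8, 10, 12),
#'                rep(c("low", "high"), each = 3))
#' @export
compare_groups <- function(values, labels, alpha_level = 0.05,
                           welch = FALSE) {
  labels <- factor(labels, levels = c("low", "high"))
  stopifnot(length(values) == length(labels), !any(is.na(labels)))
  x <- values[labels == "low"]
  y <- values[labels == "high"]
  for (nm in c("low", "high")) {
    v <- if (nm == "low") x else y
    if (length(v) < 2)
      stop(sprintf("group '%s' has fewer than 2 values", nm))
  }
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero pooled variance: both groups are constant")
  tt <- stats::t.test(x, y, var.equal = !welch)
  structure(
    list(t_stat = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value,
         significant = tt$p.value < alpha_level,
         alpha_level = alpha_level,
         n_low = length(x), n_high = length(y),
         mean_low = mean(x), mean_high = mean(y),
         welch = welch),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s t-test (two-tailed): t = %.3f, df = %.4g, p = %.4g%s\n",
              if (x$welch) "Welch" else "Student",
              x$t_stat, x$df, x$p_value,
              if (x$significant) " *" else ""))
  cat(sprintf("  low:  n = %d, mean = %.4g\n", x$n_low, x$mean_low))
  cat(sprintf("  high: n = %d, mean = %.4g\n", x$n_high, x$mean_high))
  invisible(x)
}

#' Per-category summary of marker fractions and PVI
#'
#' Means and standard deviations of the Ki-67 fraction, CD31 fraction, and
#' PVI for the low- and high-grade categories, in that order. The SD of a
#' single-sample category is undefined (NA).
#'
#' @param pairs A data.frame with columns \code{ki67_fraction},
#'   \code{cd31_fraction}, and either \code{gleason} or \code{category}.
#' @return A data.frame with one row per category and columns \code{category},
#'   \code{n}, and mean/sd for each endpoint.
#' @export
marker_summary <- function(pairs) {
  stopifnot(all(c("ki67_fraction", "cd31_fraction") %in% names(pairs)))
  cat_lab <- if ("category" %in% names(pairs))
    factor(pairs$category, levels = c("low", "high"))
  else categorize_gleason(pairs$gleason)
  if (any(table(cat_lab) == 0))
    stop("each category must contain at least one sample")
  pvi <- compute_pvi(pairs$ki67_fraction, pairs$cd31_fraction)
  one <- function(lv) {
    k <- pairs$ki67_fraction[cat_lab == lv]
    c <- pairs$cd31_fraction[cat_lab == lv]
    p <- pvi[cat_lab == lv]
    sdv <- function(v) if (length(v) > 1) stats::sd(v) else NA_real_
    data.frame(category = lv, n = length(k),
               ki67_mean = mean(k), ki67_sd = sdv(k),
               cd31_mean = mean(c), cd31_sd = sdv(c),
               pvi_mean = mean(p), pvi_sd = sdv(p))
  }
  out <- rbind(one("low"), one("high"))
  rownames(out) <- NULL
  out
}

#' Compare every endpoint between grade groups
#'
#' Convenience wrapper running [compare_groups()] on the Ki-67 fraction, the
#' CD31 fraction, and the PVI of a marker-pair table.
#'
#' @inheritParams marker_summary
#' @param alpha_level Significance level.
#' @return A named list of \code{group_comparison} objects
#'   (\code{ki67}, \code{cd31}, \code{pvi}).
#' @export
compare_markers <- function(pairs, alpha_level = 0.05) {
  cat_lab <- if ("category" %in% names(pairs))
    factor(pairs$category, levels = c("low", "high"))
  else categorize_gleason(pairs$gleason)
  pvi <- compute_pvi(pairs$ki67_fraction, pairs$cd31_fraction)
  list(ki67 = compare_groups(pairs$ki67_fraction, cat_lab, alpha_level),
       cd31 = compare_groups(pairs$cd31_fraction, cat_lab, alpha_level),
       pvi = compare_groups(pvi, cat_lab, alpha_level))
}
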