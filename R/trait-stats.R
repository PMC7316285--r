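#' Standard error of a difference between two group means
#'
#' `sqrt(se_a^2 + se_b^2)` — the quantity printed as "SEM" alongside
#' two-group trait comparisons.
#'
#' @param se_a,se_b group standard errors (>= 0).
#' @return SED.
#' @export
#' @examples
#' sed_from_se(7.82, 5.88)  # 9.784
sed_from_se <- function(se_a, se_b) {
  if (any(c(se_a, se_b) < 0)) stop("standard errors must be >= 0")
  sqrt(se_a^2 + se_b^2)
}

#' Two-sample t-test from group summary statistics
#'
#' Reconstructs an independent-sample t-test from printed means, standard
#' errors and group sizes: `t = (mean_a - mean_b) / SED`. The default uses
#' the pooled degrees of freedom `n_a + n_b - 2`; `welch = TRUE` switches to
#' the Welch-Satterthwaite approximation.
#'
#' @param a,b one-row lists/tibbles with `mean`, `se`, `n` (n >= 2); a
#'   `trait` field is carried through when present.
#' @param welch use Welch degrees of freedom instead of pooled.
#' @return one-row tibble: `trait`, `mean_diff`, `sed`, `t_stat`, `df`,
#'   `pvalue`, `tier`.
#' @export
ttest_from_summary <- function(a, b, welch = FALSE) {
  if (a$n < 2 || b$n < 2) stop("both groups need n >= 2")
  sed <- sed_from_se(a$se, b$se)
  diff <- a$mean - b$mean
  if (sed == 0) {
    if (diff != 0) stop("zero SED with unequal means: t is undefined")
    t_stat <- 0; p <- 1; df <- a$n + b$n - 2
  } else {
    t_stat <- diff / sed
    df <- if (welch)
      sed^4 / (a$se^4 / (a$n - 1) + b$se^4 / (b$n - 1))
    else a$n + b$n - 2
    p <- 2 * pt(-abs(t_stat), df)
  }
  tibble::tibble(trait = if (!is.null(a$trait)) a$trait else NA_character_,
                 mean_diff = diff, sed = sed, t_stat = t_stat, df = df,
                 pvalue = p, tier = significance_tier(p))
}

#' Two-sample t-test from raw values
#'
#' Computes group summaries (mean, SE = sd/sqrt(n)) and delegates to
#' [ttest_from_summary()], so the two entry points agree exactly.
#'
#' @param values_a,values_b numeric vectors, length >= 2 each.
#' @param trait optional trait label.
#' @inheritParams ttest_from_summary
#' @return one-row tibble as for [ttest_from_summary()].
#' @export
ttest_from_raw <- function(values_a, values_b, trait = NA_character_,
                           welch = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("both groups need at least 2 values")
  mk <- function(v) list(trait = trait, mean = mean(v),
                         se = sd(v) / sqrt(length(v)), n = length(v))
  ttest_from_summary(mk(values_a), mk(values_b), welch = welch)
}

#' Kolmogorov-Smirnov normality check with fitted parameters
#'
#' One-sample KS statistic against a normal distribution with the sample
#' mean and SD; the p-value uses the Lilliefors correction for the fitted
#' parameters (the behaviour of common statistics suites). Pass means
#' p > 0.05.
#'
#' @param values numeric vector, n >= 4, non-constant.
#' @return list with `statistic`, `pvalue`, `pass`.
#' @export
ks_normality <- function(values) {
  if (length(values) < 4) stop("need at least 4 values")
  if (sd(values) == 0) stop("constant vector: normality test undefined")
  lt <- nortest::lillie.test(values)
  list(statistic = unname(lt$statistic), pvalue = lt$p.value,
       pass = lt$p.value > 0.05)
}

#' Significance tier for a p-value
#'
#' `p <= 0.01` is highly significant, `0.01 < p <= 0.05` significant,
#' `0.05 < p < 0.1` a trend, anything else not significant.
#'
#' @param p p-value in (0, 1].
#' @return one of "highly_significant", "significant", "trend", "ns".
#' @export
significance_tier <- function(p) {
  if (is.na(p) || p <= 0 || p > 1) stop("p must lie in (0, 1]")
  if (p <= 0.01) "highly_significant"
  else if (p <= 0.05) "significant"
  else if (p < 0.1) "trend"
  else "ns"
}

#' Compare all traits in a phenotype or summary table
#'
#' Raw mode expects columns `trait`, `group`, `animal_id`, `value`; summary
#' mode expects `trait`, `group`, `mean`, `se`, `n`. Exactly two groups are
#' compared, `group_a` minus `group_b`.
#'
#' @param x phenotype/summary tibble.
#' @param mode "raw" or "summary".
#' @param group_a,group_b the two group labels (difference is a - b).
#' @inheritParams ttest_from_summary
#' @return tibble with one comparison row per trait, p-values and SED
#'   reported in full precision.
#' @export
compare_traits <- function(x, mode = c("raw", "summary"),
                           group_a = "bull", group_b = "steer",
                           welch = FALSE) {
  mode <- match.arg(mode)
  traits <- unique(x$trait)
  rows <- lapply(traits, function(tr) {
    xa <- x[x$trait == tr & x$group == group_a, ]
    xb <- x[x$trait == tr & x$group == group_b, ]
    if (nrow(xa) == 0 || nrow(xb) == 0)
      stop("trait ", tr, " missing one of the groups")
    if (mode == "raw")
      ttest_from_raw(xa$value, xb$value, trait = tr, welch = welch)
    else
      ttest_from_summary(list(trait = tr, mean = xa$mean, se = xa$se, n = xa$n),
                         list(mean = xb$mean, se = xb$se, n = xb$n),
                         welch = welch)
  })
  dplyr::bind_rows(rows)
}
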