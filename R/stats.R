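#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' The two-tailed p-value under the "probability at most that of the
#' observed table" rule: with the margins fixed, p is the sum of
#' hypergeometric probabilities of all tables whose probability does not
#' exceed the observed one (within relative tolerance 1e-7 for ties) — the
#' convention of `stats::fisher.test()` and of the common online
#' calculators. Degenerate tables (a zero row or column margin) return
#' p = 1.
#'
#' @param tab A 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = outcome yes/no), or a length-4 vector `c(a, b, c, d)` filled
#'   by row.
#' @return The two-tailed p-value in (0, 1].
#' @export
fisher_exact_two_tailed <- function(tab) {
  if (is.vector(tab) && length(tab) == 4L) {
    tab <- matrix(tab, nrow = 2L, byrow = TRUE)
  }
  stopifnot(is.matrix(tab), all(dim(tab) == 2L))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cell counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(1)
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Modified-Wald (adjusted Wald) confidence interval on a proportion
#'
#' The add-two-successes/add-two-failures adjustment: the interval is
#' centered at p' = (x+2)/(n+4) with half-width z * sqrt(p'(1-p')/(n+4)),
#' where z is the standard-normal quantile for the confidence level; bounds
#' are clipped to \[0, 1\] and the clipping is flagged. With 95% confidence
#' this reproduces the intervals printed by the common proportion
#' calculators.
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level, default 0.95.
#' @return A one-row tibble: `x`, `n`, `point` (x/n), `adjusted_center`,
#'   `lower`, `upper`, `clipped_low`, `clipped_high`, `confidence`.
#' @export
modified_wald_ci <- function(x, n, confidence = 0.95) {
  stopifnot(length(x) == 1L, length(n) == 1L,
            x == round(x), n == round(n))
  if (n < 1 || x < 0 || x > n) stop("need 0 <= x <= n with n >= 1")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p_adj <- (x + 2) / (n + 4)
  half <- z * sqrt(p_adj * (1 - p_adj) / (n + 4))
  raw_lower <- p_adj - half
  raw_upper <- p_adj + half
  tibble::tibble(
    x = as.integer(x), n = as.integer(n),
    point = x / n,
    adjusted_center = p_adj,
    lower = max(0, raw_lower),
    upper = min(1, raw_upper),
    clipped_low = raw_lower < 0,
    clipped_high = raw_upper > 1,
    confidence = confidence
  )
}

#' Format a proportion CI the way the study tables print it
#'
#' Whole-percent rounding (half away from zero); a clipped lower bound with
#' a positive point estimate renders as `"<0.01%"`.
#'
#' @param ci A one-row tibble from [modified_wald_ci()].
#' @return A string like `"9.1% (95% CI: 3% to 22%)"`.
#' @export
format_ci <- function(ci) {
  pct <- function(p) round_half_up(100 * p, 0)
  lower <- if (ci$clipped_low && ci$point > 0) "<0.01%" else
    sprintf("%g%%", pct(ci$lower))
  sprintf("%s%% (%d%% CI: %s to %g%%)",
          format(round_half_up(100 * ci$point, 1)),
          round(100 * ci$confidence), lower, pct(ci$upper))
}

# Round half away from zero (the convention of the printed tables; R's
# round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Welch two-sample t statistic from summary statistics
#'
#' t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2), with Welch-Satterthwaite
#' degrees of freedom. With equal group sizes this coincides numerically
#' with the pooled-variance statistic. Zero pooled variance with equal
#' means gives t = 0; with unequal means the statistic is infinite and
#' flagged.
#'
#' @param mean1,sd1,n1 First group's mean, standard deviation and size.
#' @param mean2,sd2,n2 Second group's.
#' @return A one-row tibble: `t`, `df`, `p_value` (two-sided), `infinite`.
#' @export
two_sample_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  se2 <- sd1^2 / n1 + sd2^2 / n2
  if (se2 == 0) {
    if (mean1 == mean2) {
      return(tibble::tibble(t = 0, df = n1 + n2 - 2, p_value = 1,
                            infinite = FALSE))
    }
    return(tibble::tibble(t = sign(mean1 - mean2) * Inf, df = n1 + n2 - 2,
                          p_value = 0, infinite = TRUE))
  }
  t_stat <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  tibble::tibble(
    t = t_stat, df = df,
    p_value = 2 * stats::pt(-abs(t_stat), df),
    infinite = FALSE
  )
}

#' Transition:transversion ratio
#'
#' @param transitions,transversions Non-negative counts.
#' @return A list with `ratio` (transitions/transversions; `Inf` flagged
#'   when transversions = 0), `label` (the ratio rounded to the nearest
#'   integer, as `"k:1"`) and `infinite`.
#' @export
tstv_ratio <- function(transitions, transversions) {
  stopifnot(transitions >= 0, transversions >= 0)
  if (transversions == 0) {
    return(list(ratio = Inf, label = "Inf:1", infinite = TRUE))
  }
  r <- transitions / transversions
  list(ratio = r, label = sprintf("%d:1", as.integer(round_half_up(r, 0))),
       infinite = FALSE)
}

#' Classification grid of observed variant instances
#'
#' The (previously reported / novel) x (transition / transversion /
#' insertions,deletions) grid of variant instances, per group, with
#' percentages of each group's total — the cohort's variant-spectrum
#' summary table.
#'
#' @param callsets A cohort call tibble with `sample`, `group` and variant
#'   columns, normalized.
#' @param catalog An `mt_catalog` defining novelty.
#' @return A tibble: `group`, `novelty` (`"reported"`/`"novel"`),
#'   `class_group`, `n`, `pct`.
#' @export
variation_table <- function(callsets, catalog) {
  groups <- unique(callsets$group)
  grid <- tidyr::expand_grid(
    group = groups,
    novelty = c("reported", "novel"),
    class_group = c("transition", "transversion", "indel")
  )
  if (nrow(callsets) == 0L) {
    grid$n <- 0L
    grid$pct <- 0
    return(grid)
  }
  d <- callsets |>
    dplyr::mutate(
      novelty = ifelse(is_novel(callsets, catalog), "novel", "reported"),
      class_group = class_group(.data$class)
    ) |>
    dplyr::count(.data$group, .data$novelty, .data$class_group)
  out <- dplyr::left_join(grid, d,
                          by = c("group", "novelty", "class_group")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n)
                  else 0) |>
    dplyr::ungroup()
  out
}

#' Share of instances previously reported
#'
#' @param grid Output of [variation_table()] (or any tibble with `novelty`
#'   and `n`).
#' @return Proportion of variant instances whose variant was previously
#'   reported, in \[0, 1\] (`NaN` for an empty cohort).
#' @export
reported_share <- function(grid) {
  sum(grid$n[grid$novelty == "reported"]) / sum(grid$n)
}

#' Variant rarity histogram
#'
#' Distinct variants binned by their number of observations across the
#' cohort (cases and controls pooled). Most mtDNA variants are expected to
#' be observed once.
#'
#' @param callsets A cohort call tibble.
#' @return A tibble `n_observations`, `n_variants`, plus attributes
#'   `singleton_share` (fraction of distinct variants observed once) and
#'   `n_distinct`.
#' @export
rarity_histogram <- function(callsets) {
  if (nrow(callsets) == 0L) {
    out <- tibble::tibble(n_observations = integer(0),
                          n_variants = integer(0))
    attr(out, "singleton_share") <- NaN
    attr(out, "n_distinct") <- 0L
    return(out)
  }
  obs <- table(variant_key(callsets))
  h <- table(factor(as.integer(obs)))
  out <- tibble::tibble(
    n_observations = as.integer(names(h)),
    n_variants = as.integer(h)
  )
  attr(out, "singleton_share") <-
    sum(out$n_variants[out$n_observations == 1L]) / sum(out$n_variants)
  attr(out, "n_distinct") <- length(obs)
  out
}

#' Disease-associated variant table
#'
#' Per disease-associated variant (catalog entries carrying at least one
#' disease annotation) the number of observations in each group, with
#' per-group totals, mean observations per subject, SD, and the share of
#' disease-associated instances that are transversions.
#'
#' @param callsets A cohort call tibble with `sample` and `group`.
#' @param catalog An `mt_catalog`.
#' @param group_sizes Named integer vector of subjects per group (defaults
#'   to the number of distinct samples per group in `callsets`).
#' @return A list with `table` (per-variant counts), `totals`, `means`,
#'   `sds` and `transversion_share` (all named by group).
#' @export
disease_variant_table <- function(callsets, catalog, group_sizes = NULL) {
  groups <- sort(unique(callsets$group))
  if (is.null(group_sizes)) {
    gs <- callsets |>
      dplyr::distinct(.data$sample, .data$group) |>
      dplyr::count(.data$group)
    group_sizes <- stats::setNames(gs$n, gs$group)
  }
  flag <- is_disease_associated(callsets, catalog)
  da <- callsets[flag, , drop = FALSE]
  per_sample <- lapply(groups, function(g) {
    samples <- unique(callsets$sample[callsets$group == g])
    counts <- table(factor(da$sample[da$group == g], levels = samples))
    as.integer(counts)
  })
  names(per_sample) <- groups
  tab <- if (nrow(da) == 0L) {
    tibble::tibble(label = character(0), locus = character(0),
                   aa_change = character(0))
  } else {
    da |>
      dplyr::mutate(key = variant_key(da)) |>
      dplyr::count(.data$key, .data$group) |>
      tidyr::pivot_wider(names_from = "group", values_from = "n",
                         values_fill = 0L) |>
      dplyr::left_join(
        dplyr::mutate(catalog$entries,
                      label = hgvs_label(catalog$entries))[,
          c("key", "label", "locus", "aa_change", "disease_annotations",
            "position")],
        by = "key") |>
      dplyr::arrange(.data$position)
  }
  list(
    table = tab,
    totals = vapply(per_sample, sum, integer(1)),
    means = vapply(per_sample, mean, numeric(1)),
    sds = vapply(per_sample, stats::sd, numeric(1)),
    transversion_share = vapply(groups, function(g) {
      m <- da$group == g
      if (!any(m)) return(NaN)
      mean(class_group(da$class[m]) == "transversion")
    }, numeric(1))
  )
}
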