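#' Assign hindgut regions to flux estimates
#'
#' Ileum sites keep the label `"ileum"`. Within each preparation the rectum
#' sites are split by their position along the tissue axis into anterior and
#' posterior halves; with an odd count the extra site goes to the anterior
#' half.
#'
#' @param estimates Data frame from [estimate_fluxes()] (one or several
#'   preparations row-bound together) carrying `region_hint` and `ordinal`.
#' @return The same data frame with a `region` column added, one of
#'   `"ileum"`, `"anterior_rectum"`, `"posterior_rectum"`.
#' @examples
#' est <- data.frame(preparation_id = "p", region_hint = rep("rectum", 7),
#'                   ordinal = 1:7)
#' table(assign_regions(est)$region)  # 4 anterior, 3 posterior
#' @export
assign_regions <- function(estimates) {
  stopifnot(is.data.frame(estimates))
  if (!all(c("region_hint", "ordinal") %in% names(estimates)))
    stop("estimates must carry region_hint and ordinal columns",
         call. = FALSE)
  bad <- !estimates$region_hint %in% c("ileum", "rectum")
  if (any(bad))
    stop("unknown region_hint value(s): ",
         paste(unique(estimates$region_hint[bad]), collapse = ", "),
         call. = FALSE)
  prep <- if ("preparation_id" %in% names(estimates))
    estimates$preparation_id else "all"
  estimates$region <- NA_character_
  estimates$region[estimates$region_hint == "ileum"] <- "ileum"
  for (p in unique(prep)) {
    idx <- which(prep == p & estimates$region_hint == "rectum")
    if (!length(idx)) next
    ords <- estimates$ordinal[idx]
    if (any(is.na(ords)))
      stop("rectum sites in preparation '", p,
           "' are missing tissue-axis ordinals", call. = FALSE)
    n_ant <- ceiling(length(idx) / 2)
    r <- rank(ords, ties.method = "first")
    estimates$region[idx] <- ifelse(r <= n_ant, "anterior_rectum",
                                    "posterior_rectum")
  }
  estimates
}

#' Per-preparation mean flux by region
#'
#' Collapses site-level flux estimates to one value per preparation and
#' region — the preparation is the unit of replication for all statistics.
#'
#' @param estimates Output of [assign_regions()] (must have `region`).
#' @return Data frame with `preparation_id`, `treatment` (if present),
#'   `region`, `mean_flux`, `n_sites`.
#' @export
preparation_means <- function(estimates) {
  stopifnot(is.data.frame(estimates))
  if (!"region" %in% names(estimates))
    stop("run assign_regions() first", call. = FALSE)
  key <- list(preparation_id = estimates$preparation_id,
              region = estimates$region)
  if ("treatment" %in% names(estimates))
    key <- c(key[1], list(treatment = estimates$treatment), key[2])
  agg <- stats::aggregate(estimates$flux, key, mean)
  names(agg)[names(agg) == "x"] <- "mean_flux"
  cnt <- stats::aggregate(estimates$flux, key, length)
  agg$n_sites <- cnt$x
  agg[order(agg$preparation_id, agg$region), , drop = FALSE]
}

#' Mean and SEM of per-preparation fluxes
#'
#' @param fluxes Numeric vector of per-preparation mean fluxes for one
#'   region and treatment (pmol cm-2 s-1).
#' @return List with `n`, `mean_flux`, `sem_flux` (`NA` when n = 1: a
#'   single preparation has no between-preparation scatter to estimate).
#' @examples
#' summarize_region(c(1, 2, 3))  # mean 2, SEM 0.577
#' @export
summarize_region <- function(fluxes) {
  if (!length(fluxes)) stop("no flux values supplied", call. = FALSE)
  n <- length(fluxes)
  list(n = n, mean_flux = mean(fluxes),
       sem_flux = if (n > 1) stats::sd(fluxes) / sqrt(n) else NA_real_)
}

#' Region-wise summary table across preparations
#'
#' @param prep_means Output of [preparation_means()].
#' @return Data frame with one row per (treatment, region): `n`,
#'   `mean_flux`, `sem_flux`.
#' @export
summarize_regions <- function(prep_means) {
  stopifnot(is.data.frame(prep_means))
  if (!"treatment" %in% names(prep_means)) prep_means$treatment <- "all"
  groups <- split(prep_means,
                  list(prep_means$treatment, prep_means$region), drop = TRUE)
  rows <- lapply(groups, function(g) {
    s <- summarize_region(g$mean_flux)
    data.frame(treatment = g$treatment[1], region = g$region[1],
               n = s$n, mean_flux = s$mean_flux, sem_flux = s$sem_flux)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$region, out$treatment), , drop = FALSE]
}

#' Percent change in flux magnitude between conditions
#'
#' Computed on magnitudes so that a 75% reduction of secretion (negative
#' fluxes) and a 68% reduction of absorption (positive fluxes) share one
#' formula: `100 * (|treatment| - |control|) / |control|`, negative values
#' meaning the transport weakened. A change of transport direction between
#' conditions is reported in the `sign_reversal` flag; the magnitude-based
#' percentage is still returned but should be read alongside the flag.
#'
#' @param control_mean,treatment_mean Mean fluxes, pmol cm-2 s-1; the
#'   control mean must be nonzero.
#' @return List with `percent` and logical `sign_reversal`.
#' @examples
#' percent_change(-53.2, -13.3)$percent  # -75: secretion reduced 75%
#' @export
percent_change <- function(control_mean, treatment_mean) {
  if (control_mean == 0)
    stop("undefined effect: control mean flux is zero", call. = FALSE)
  list(percent = 100 * (abs(treatment_mean) - abs(control_mean)) /
         abs(control_mean),
       sign_reversal = treatment_mean != 0 &&
         sign(treatment_mean) != sign(control_mean))
}

#' One-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Classical equal-variance one-way ANOVA across the supplied groups,
#' followed by pairwise t tests using the pooled within-group SD; each raw
#' pairwise p-value is multiplied by `n_comparisons` and capped at 1
#' (Bonferroni). The comparison count is a caller decision — when the same
#' contrast is tested in several regions, pass the total number of
#' comparisons across regions.
#'
#' @param groups Named list of numeric vectors of per-preparation fluxes
#'   (>= 2 groups, each with >= 2 values).
#' @param n_comparisons Bonferroni multiplier; defaults to the number of
#'   pairs among the supplied groups.
#' @param alpha Significance threshold applied to adjusted p-values.
#' @param welch Use Welch's unequal-variance ANOVA/t tests instead of the
#'   classical pooled form.
#' @return List with `f`, `p`, `df`, `pairwise` (data frame: `group1`,
#'   `group2`, `p_raw`, `p_adjusted`, `significant`), `n_comparisons`.
#' @examples
#' anova_bonferroni(list(a = c(1, 2, 3), b = c(11, 12, 13)))$f  # 150
#' @export
anova_bonferroni <- function(groups, n_comparisons = NULL, alpha = 0.05,
                             welch = FALSE) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need >= 2 groups", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("insufficient replication: every group needs >= 2 values",
         call. = FALSE)
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                  levels = names(groups))
  if (welch) {
    ow <- stats::oneway.test(value ~ group, var.equal = FALSE)
    f <- unname(ow$statistic)
    p <- ow$p.value
    df <- unname(ow$parameter)
    pt <- stats::pairwise.t.test(value, group, p.adjust.method = "none",
                                 pool.sd = FALSE)
  } else {
    fit <- stats::aov(value ~ group)
    tab <- summary(fit)[[1]]
    f <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
    df <- tab[["Df"]]
    pt <- stats::pairwise.t.test(value, group, p.adjust.method = "none",
                                 pool.sd = TRUE)
  }
  m <- if (is.null(n_comparisons)) choose(length(groups), 2) else n_comparisons
  pm <- pt$p.value
  pairs <- which(!is.na(pm), arr.ind = TRUE)
  pairwise <- data.frame(
    group1 = colnames(pm)[pairs[, "col"]],
    group2 = rownames(pm)[pairs[, "row"]],
    p_raw = pm[pairs])
  pairwise$p_adjusted <- pmin(1, pairwise$p_raw * m)
  pairwise$significant <- pairwise$p_adjusted < alpha
  list(f = f, p = p, df = df, pairwise = pairwise, n_comparisons = m)
}

#' Region-wise control vs treatment comparison
#'
#' For each region shared by the two conditions: mean and SEM per condition,
#' percent change in flux magnitude, and the control-vs-treatment ANOVA with
#' Bonferroni adjustment across the regions compared (so testing three
#' regions triples each raw p-value, as a multiple-comparison post-test
#' does).
#'
#' @param control,treatment [preparation_means()] tables for the two
#'   conditions.
#' @param n_comparisons Bonferroni multiplier; defaults to the number of
#'   shared regions.
#' @param alpha Significance threshold.
#' @param welch Passed to [anova_bonferroni()].
#' @return Data frame with one row per region: sample sizes, means, SEMs,
#'   `percent_change`, `sign_reversal`, `anova_f`, `anova_p`,
#'   `bonferroni_p`, `significant`.
#' @export
compare_treatments <- function(control, treatment, n_comparisons = NULL,
                               alpha = 0.05, welch = FALSE) {
  stopifnot(is.data.frame(control), is.data.frame(treatment))
  regions <- intersect(unique(control$region), unique(treatment$region))
  if (!length(regions)) stop("no shared regions to compare", call. = FALSE)
  m <- if (is.null(n_comparisons)) length(regions) else n_comparisons
  rows <- lapply(regions, function(r) {
    cf <- control$mean_flux[control$region == r]
    tf <- treatment$mean_flux[treatment$region == r]
    sc <- summarize_region(cf)
    st <- summarize_region(tf)
    ab <- anova_bonferroni(list(control = cf, treatment = tf),
                           n_comparisons = m, alpha = alpha, welch = welch)
    pc <- percent_change(sc$mean_flux, st$mean_flux)
    data.frame(
      region = r, n_control = sc$n, n_treatment = st$n,
      control_mean = sc$mean_flux, control_sem = sc$sem_flux,
      treatment_mean = st$mean_flux, treatment_sem = st$sem_flux,
      percent_change = pc$percent, sign_reversal = pc$sign_reversal,
      anova_f = ab$f, anova_p = ab$p,
      bonferroni_p = ab$pairwise$p_adjusted[1],
      significant = ab$pairwise$significant[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
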