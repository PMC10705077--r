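# Group-comparison statistics for cohort morphometry: Lilliefors normality
# testing with Monte-Carlo p-values, Bartlett variance homogeneity, the
# one-way ANOVA F-test, and the standard three-tier significance flags
# (p < 0.05, p < 0.01, p < 0.001). No multiple-testing correction is
# applied by default; raw thresholds are reported.

#' Significance tier for a p-value
#'
#' @param p p-value in `[0, 1]`.
#' @param tiers decreasing significance thresholds (strict `<`).
#' @return `"ns"` or the strictest satisfied tier, e.g. `"p<0.001"`;
#'   `NA` for an empty tier list.
#' @export
significance_tier <- function(p, tiers = c(0.05, 0.01, 0.001)) {
  if (length(tiers) == 0) return(NA_character_)
  tiers <- sort(tiers, decreasing = TRUE)
  hit <- tiers[p < tiers]
  if (length(hit) == 0) "ns" else paste0("p<", format(min(hit)))
}

.test_result <- function(test, statistic, df, p_value,
                         tiers = c(0.05, 0.01, 0.001),
                         assumptions = list(), notes = character(0)) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value,
                 tier = significance_tier(p_value, tiers),
                 assumptions = assumptions, notes = notes),
            class = "ov_test")
}

#' @export
print.ov_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g, df = %s, p = %.4g [%s]\n",
              x$test, x$statistic, paste(x$df, collapse = ", "),
              x$p_value, x$tier))
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# Lilliefors statistic: sup distance between the EDF and the normal CDF
# with mean and SD estimated from the sample.
.lilliefors_stat <- function(x) {
  n <- length(x)
  z <- (sort(x) - mean(x)) / sd(x)
  p <- pnorm(z)
  i <- seq_len(n)
  max(pmax(i / n - p, p - (i - 1) / n))
}

# statistics for each column of a matrix of null samples
.lilliefors_stat_cols <- function(m) {
  n <- nrow(m)
  ms <- apply(m, 2L, sort)
  mu <- colMeans(ms)
  sdv <- sqrt(colSums(sweep(ms, 2L, mu)^2) / (n - 1))
  p <- pnorm(sweep(sweep(ms, 2L, mu), 2L, sdv, `/`))
  i <- seq_len(n)
  d <- pmax(i / n - p, p - (i - 1) / n)
  apply(d, 2L, max)
}

#' Lilliefors test of normality with a Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov-type test with mean and variance estimated from the
#' sample. The p-value is obtained from a Monte-Carlo null: `n_montecarlo`
#' standard-normal samples of the same size, run through the same
#' estimation step, with the add-one p-value estimator. Exact table lookups
#' are avoided so small sample sizes are handled correctly.
#'
#' @param sample numeric vector, length >= 4, non-constant.
#' @param n_montecarlo number of null replicates (>= 1000).
#' @param seed RNG seed for the null simulation (the result is
#'   deterministic given the seed).
#' @param tiers significance thresholds, see [significance_tier()].
#' @return an `ov_test` result.
#' @export
lilliefors_test <- function(sample, n_montecarlo = 2000, seed = 1,
                            tiers = c(0.05, 0.01, 0.001)) {
  sample <- as.numeric(sample)
  n <- length(sample)
  if (n < 4) stop("Lilliefors test needs at least 4 observations")
  if (n_montecarlo < 1000) stop("n_montecarlo must be at least 1000")
  if (sd(sample) == 0) stop("constant sample: normality test is undefined")
  d <- .lilliefors_stat(sample)
  null_d <- .with_seed(seed, {
    m <- matrix(rnorm(n * n_montecarlo), nrow = n)
    .lilliefors_stat_cols(m)
  })
  p <- (1 + sum(null_d >= d)) / (n_montecarlo + 1)
  .test_result("lilliefors", d, df = n, p_value = p, tiers = tiers)
}

#' Bartlett test of variance homogeneity
#'
#' Classical companion check to one-way ANOVA; chi-square p-value.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2, none
#'   with zero variance).
#' @param tiers significance thresholds.
#' @return an `ov_test` result.
#' @export
variance_homogeneity <- function(groups, tiers = c(0.05, 0.01, 0.001)) {
  .check_groups(groups)
  if (any(vapply(groups, sd, 0) == 0)) {
    stop("zero-variance group: Bartlett test is undefined")
  }
  bt <- bartlett.test(groups)
  .test_result("bartlett", unname(bt$statistic), unname(bt$parameter),
               bt$p.value, tiers = tiers)
}

#' One-way ANOVA F-test
#'
#' `F = (between-group SS / (k - 1)) / (within-group SS / (N - k))` with a
#' p-value from the F distribution. For two groups this equals the square
#' of the pooled-variance t statistic.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @param tiers significance thresholds.
#' @return an `ov_test` result with `df = c(k - 1, N - k)`.
#' @export
anova_f <- function(groups, tiers = c(0.05, 0.01, 0.001)) {
  .check_groups(groups)
  k <- length(groups)
  ni <- lengths(groups)
  N <- sum(ni)
  if (N <= k) stop("total sample size must exceed the number of groups")
  mi <- vapply(groups, mean, 0)
  m <- sum(ni * mi) / N
  ssb <- sum(ni * (mi - m)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1
  df2 <- N - k
  notes <- character(0)
  if (ssw == 0) {
    if (ssb == 0) {
      f <- 0
      p <- 1
    } else {
      f <- Inf
      p <- 0
      notes <- "degenerate data: zero within-group variance"
      warning("zero within-group variance with nonzero group differences")
    }
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  .test_result("anova_f", f, df = c(df1, df2), p_value = p, tiers = tiers)
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least 2 groups")
  }
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  if (any(vapply(groups, function(g) anyNA(g), TRUE))) {
    stop("groups contain NA values")
  }
  invisible(TRUE)
}

#' Build the cohort morphometry table
#'
#' Runs the full morphometry on every sample of a cohort and assembles the
#' long-format table feeding the hypothesis tests: global BV/TV, VV/TV,
#' Me.V/TV, V.Th and VMI per sample, plus the VOI-restricted local VV/TV
#' and local V.Th at the given distance threshold.
#'
#' @param samples list of samples from [generate_cohort()] (or any list
#'   with `sample_id`, `group`, `timepoint`, `labels`).
#' @param local_threshold_um VOI distance threshold for the local metrics.
#' @param closing_radius_um TV closing radius, see [total_volume_mask()].
#' @return data.frame with columns `sample_id`, `timepoint`, `group`,
#'   `metric`, `value`. Undefined values (e.g. local V.Th in a VOI without
#'   vessels) are `NA`.
#' @export
cohort_table <- function(samples, local_threshold_um = 700,
                         closing_radius_um = NULL) {
  rows <- lapply(samples, function(s) {
    labels <- s$labels
    vs <- voxel_size(labels)
    tv <- total_volume_mask(labels, closing_radius_um)
    rep <- compartment_volumes(labels, tv)
    vessel <- class_mask(labels, "vessel")
    met <- class_mask(labels, "metastasis")
    th <- if (any(vessel)) local_thickness(vessel, vs) else NULL
    vth <- if (is.null(th)) NA_real_ else th$mean_um
    if (any(met)) {
      # one metastasis distance map serves both VMI and the VOI restriction
      dmet <- distance_transform(met, vs)
      vmi_um <- if (any(vessel)) mean(dmet[vessel]) else NA_real_
      voi <- (unclass(dmet) < local_threshold_um) & tv
      dim(voi) <- dim(tv)
      loc <- local_metrics(labels, voi,
                           thickness_map = if (is.null(th)) NULL else th$map,
                           threshold_um = local_threshold_um)
      lvv <- loc$vvtv
      lvth <- loc$vth_um
    } else {
      vmi_um <- NA_real_
      lvv <- NA_real_
      lvth <- NA_real_
    }
    data.frame(sample_id = s$sample_id, timepoint = s$timepoint,
               group = s$group,
               metric = c("BV/TV", "VV/TV", "Me.V/TV", "V.Th", "VMI",
                          "local VV/TV", "local V.Th"),
               value = c(rep$bvtv, rep$vvtv, rep$mevtv, vth, vmi_um,
                         lvv, lvth),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the study's group comparisons on a cohort table
#'
#' Two families of one-way ANOVA F-tests, each preceded by per-group
#' Lilliefors normality checks and a Bartlett variance-homogeneity check
#' whose outcomes are recorded alongside: (a) first vs second time point
#' for BV/TV, VV/TV, V.Th and Me.V/TV; (b) the second-time-point treatment
#' groups for the VOI-restricted local VV/TV and local V.Th. Results are
#' reported at raw significance thresholds without multiple-testing
#' correction; when an assumption check fails the ANOVA is still computed
#' and flagged.
#'
#' @param table data.frame from [cohort_table()] with columns `sample_id`,
#'   `timepoint`, `group`, `metric`, `value`.
#' @param timepoints character pair: the two time-point labels compared in
#'   family (a); the second is the one whose treatment groups are compared
#'   in family (b).
#' @param global_metrics,local_metrics metric names for the two families.
#' @param tiers significance thresholds; empty means p-values without tier
#'   flags.
#' @param lilliefors_mc,seed Monte-Carlo settings for the normality checks.
#' @param adjust optional p-value adjustment method (see
#'   [stats::p.adjust()]); `"none"` by default, mirroring raw-threshold
#'   reporting.
#' @return data.frame with one row per comparison: `family`, `metric`,
#'   groups compared, F statistic, degrees of freedom, p-value, tier and
#'   assumption-check outcomes.
#' @export
run_study_comparisons <- function(table,
                                  timepoints = c("T1", "T2"),
                                  global_metrics = c("BV/TV", "VV/TV",
                                                     "V.Th", "Me.V/TV"),
                                  local_metrics = c("local VV/TV",
                                                    "local V.Th"),
                                  tiers = c(0.05, 0.01, 0.001),
                                  lilliefors_mc = 1000, seed = 1,
                                  adjust = "none") {
  need_cols <- c("sample_id", "timepoint", "group", "metric", "value")
  if (!all(need_cols %in% names(table))) {
    stop("cohort table must have columns ",
         paste(need_cols, collapse = ", "))
  }
  out <- list()
  run_one <- function(family, metric, split_by, subset_rows, labels) {
    rows <- table[subset_rows & table$metric == metric, ]
    if (nrow(rows) == 0) stop("metric not found in table: ", metric)
    groups <- split(rows$value, rows[[split_by]])
    groups <- groups[labels[labels %in% names(groups)]]
    if (length(groups) < length(labels)) {
      stop("missing group(s) for metric ", metric, ": ",
           paste(setdiff(labels, names(groups)), collapse = ", "))
    }
    n_na <- sum(vapply(groups, function(g) sum(is.na(g)), 0))
    groups <- lapply(groups, function(g) g[!is.na(g)])
    norm_ok <- vapply(seq_along(groups), function(i) {
      g <- groups[[i]]
      if (length(g) < 4 || sd(g) == 0) return(NA)
      lilliefors_test(g, n_montecarlo = lilliefors_mc,
                      seed = seed + i)$p_value >= 0.05
    }, NA)
    var_ok <- tryCatch(
      variance_homogeneity(groups)$p_value >= 0.05,
      error = function(e) NA)
    res <- anova_f(groups, tiers = tiers)
    data.frame(family = family, metric = metric,
               groups = paste(names(groups), collapse = " vs "),
               n = paste(lengths(groups), collapse = ","),
               statistic = res$statistic, df1 = res$df[1], df2 = res$df[2],
               p_value = res$p_value, tier = res$tier,
               normality_ok = all(norm_ok, na.rm = TRUE),
               variance_ok = isTRUE(var_ok),
               assumptions_ok = all(norm_ok, na.rm = TRUE) & isTRUE(var_ok),
               n_dropped_na = n_na,
               stringsAsFactors = FALSE)
  }
  for (m in global_metrics) {
    out[[length(out) + 1L]] <- run_one(
      "timepoint", m, "timepoint",
      table$timepoint %in% timepoints, timepoints)
  }
  t2_groups <- unique(table$group[table$timepoint == timepoints[2]])
  for (m in local_metrics) {
    out[[length(out) + 1L]] <- run_one(
      "treatment", m, "group",
      table$timepoint == timepoints[2], sort(t2_groups))
  }
  res <- do.call(rbind, out)
  if (!identical(adjust, "none")) {
    res$p_value <- stats::p.adjust(res$p_value, method = adjust)
    res$tier <- vapply(res$p_value, significance_tier, "", tiers = tiers)
  }
  rownames(res) <- NULL
  res
}
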