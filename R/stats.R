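# Cohort statistics: exact Mann-Whitney, Pearson correlation, Cohen's
# kappa, interobserver variability, and group summary tables.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test between two independent samples. For small,
#' tie-free samples the exact p-value is computed from the count-based null
#' distribution of U (all rank assignments equally likely); otherwise a
#' normal approximation with tie correction and continuity correction is
#' used. The two-sided exact p is twice the smaller one-sided tail
#' probability, capped at 1.
#'
#' @param x,y Numeric samples (no NaN/NA).
#' @param mode `"auto"` (exact when tie-free and `min(n) <= exact_cutoff`
#'   or `n1*n2 <= 200`), `"exact"` (errors on ties), or `"approx"`.
#' @param exact_cutoff Largest `min(n1, n2)` for which auto mode stays
#'   exact (default 8).
#' @return An object of class `stat_result`: `method`, `statistic` (U for
#'   the first sample), `p_value`, `n1`, `n2`, `exact`, `mode`.
#' @export
#' @examples
#' mann_whitney(1:5, 6:10)$p_value  # complete separation: 2/252
mann_whitney <- function(x, y, mode = c("auto", "exact", "approx"),
                         exact_cutoff = 8) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA/NaN",
                                 call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  ties <- any(duplicated(pooled))
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = !ties && (min(n1, n2) <= exact_cutoff || n1 * n2 <= 200))
  if (mode == "exact" && ties)
    stop("exact mode requires tie-free data: the enumerated U null ",
         "distribution is only defined without ties; use mode = 'approx'",
         call. = FALSE)
  if (use_exact && !ties) {
    p_le <- pwilcox(u, n1, n2)
    p_ge <- pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)  # continuity-corrected
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(method = "Mann-Whitney U", statistic = u, p_value = p,
                 n1 = n1, n2 = n2, exact = exact,
                 mode = if (exact) "exact" else "approx"),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$method, ": statistic ", signif(x$statistic, 6),
      ", p = ", signif(x$p_value, 4),
      " (n = ", x$n1, if (!is.null(x$n2)) paste0(" vs ", x$n2),
      if (isTRUE(x$exact)) ", exact" else "", ")\n", sep = "")
  invisible(x)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric samples of equal length (n >= 3, both with nonzero
#'   variance).
#' @return A `stat_result` with `statistic` = r and a two-sided p from the
#'   t transform on n - 2 degrees of freedom.
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("samples must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  structure(list(method = "Pearson correlation",
                 statistic = unname(ct$estimate), p_value = ct$p.value,
                 n1 = length(x), n2 = NULL, exact = FALSE, mode = "t"),
            class = "stat_result")
}

#' Cohen's kappa for two categorical labelings
#'
#' Chance-corrected agreement kappa = (po - pe) / (1 - pe), with po the
#' observed agreement and pe the agreement expected from the marginal label
#' frequencies. Kappa is 1 exactly when the labelings agree everywhere
#' (including the degenerate single-category case).
#'
#' @param labels_a,labels_b Equal-length categorical vectors.
#' @return An object of class `kappa_result`: `kappa`,
#'   `observed_agreement`, `expected_agreement`, `n`.
#' @export
#' @examples
#' cohens_kappa(c("a", "a", "b"), c("a", "a", "b"))$kappa  # 1
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length (", length(labels_a), " vs ",
         length(labels_b), ")", call. = FALSE)
  n <- length(labels_a)
  if (n < 1) stop("need at least one pair", call. = FALSE)
  levels_all <- union(unique(labels_a), unique(labels_b))
  a <- factor(labels_a, levels = levels_all)
  b <- factor(labels_b, levels = levels_all)
  tab <- table(a, b) / n
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  kappa <- if (pe == 1) { if (po == 1) 1 else 0 } else (po - pe) / (1 - pe)
  structure(list(kappa = kappa, observed_agreement = po,
                 expected_agreement = pe, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat("<kappa_result> kappa = ", signif(x$kappa, 4), " (po = ",
      signif(x$observed_agreement, 4), ", pe = ",
      signif(x$expected_agreement, 4), ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Interobserver variability
#'
#' Per pair, the signed relative difference 100 (a - b) / ((a + b)/2),
#' summarized as mean and SD in percent (reported in the field as
#' "mean +/- SD %").
#'
#' @param a,b Equal-length positive paired measurements (two observers).
#' @return List with `mean_pct` and `sd_pct`.
#' @export
interobserver_variability <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired measurements must have equal ",
                                   "length", call. = FALSE)
  if (length(a) < 2) stop("need >= 2 pairs", call. = FALSE)
  pm <- (a + b) / 2
  if (any(pm <= 0)) stop("nonpositive pair mean at pair(s) ",
                         paste(which(pm <= 0), collapse = ", "),
                         call. = FALSE)
  pct <- 100 * (a - b) / pm
  list(mean_pct = mean(pct), sd_pct = sd(pct))
}

.COHORT_METRICS <- c("edvi", "esvi", "ef", "co", "ci",
                     "peak_systolic_ke_sv", "peak_diastolic_ke_sv",
                     "peak_systolic_ke_bsa", "peak_diastolic_ke_bsa",
                     "peak_systolic_ke_ci", "peak_diastolic_ke_ci")

#' Cohort summary table
#'
#' Mean, SD and n per group x ventricular morphology for the volumetric and
#' indexed-KE metrics of a subject-record table: EDVI, ESVI, EF, CO, CI and
#' the six peak-KE indexings (to SV, BSA, CI, systole and diastole each).
#' Groups or strata with a single subject report SD = 0 with `n = 1`
#' flagging the convention; empty strata are omitted with a notice.
#'
#' @param records Data frame of subject records (one row per subject) with
#'   columns `group`, `morphology` and the metric columns above (missing
#'   metric columns are skipped).
#' @return Long-format data frame: `group`, `morphology`, `n`, `metric`,
#'   `mean`, `sd`; CSV-writable.
#' @export
cohort_table <- function(records) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("need at least one record", call. = FALSE)
  if (!"morphology" %in% names(records)) records$morphology <- "all"
  metrics <- intersect(.COHORT_METRICS, names(records))
  strata <- split(records, list(records$group, records$morphology),
                  drop = FALSE, sep = " / ")
  empty <- names(strata)[vapply(strata, nrow, integer(1)) == 0]
  if (length(empty))
    message("omitting empty group/morphology strata: ",
            paste(empty, collapse = "; "))
  strata <- strata[vapply(strata, nrow, integer(1)) > 0]
  rows <- lapply(strata, function(df) {
    data.frame(group = df$group[1], morphology = df$morphology[1],
               n = nrow(df), metric = metrics,
               mean = vapply(metrics, function(m) mean(df[[m]]), numeric(1)),
               sd = vapply(metrics, function(m)
                 if (nrow(df) > 1) sd(df[[m]]) else 0, numeric(1)),
               row.names = NULL)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Compare a metric between two groups
#'
#' Mann-Whitney comparison of one record metric between two groups, with
#' small-subgroup suppression: when either group has fewer than `min_n`
#' subjects no p-value is computed and a suppression notice is returned
#' instead (underpowered subgroup comparisons are not reported).
#'
#' @param records Subject-record data frame with a grouping column and the
#'   metric column.
#' @param metric Metric column name.
#' @param groups Length-2 character vector of group labels to compare;
#'   defaults to the first two observed.
#' @param group_col Grouping column name (default `"group"`).
#' @param min_n Minimum per-group n below which the test is suppressed
#'   (default 5).
#' @param mode Passed to [mann_whitney()].
#' @return A `stat_result`, or an object of class `stat_suppressed` with a
#'   `notice` element.
#' @export
compare_groups <- function(records, metric, groups = NULL,
                           group_col = "group", min_n = 5,
                           mode = "auto") {
  records <- as.data.frame(records)
  if (!metric %in% names(records))
    stop("unknown metric column: ", metric, call. = FALSE)
  if (is.null(groups)) groups <- unique(records[[group_col]])[1:2]
  xa <- records[records[[group_col]] == groups[1], metric]
  xb <- records[records[[group_col]] == groups[2], metric]
  if (length(xa) < min_n || length(xb) < min_n) {
    return(structure(list(
      metric = metric, groups = groups, n1 = length(xa), n2 = length(xb),
      notice = paste0("comparison suppressed: group sizes ", length(xa),
                      " vs ", length(xb), " below minimum n = ", min_n)),
      class = "stat_suppressed"))
  }
  res <- mann_whitney(xa, xb, mode = mode)
  res$metric <- metric
  res$groups <- groups
  res
}

#' @export
print.stat_suppressed <- function(x, ...) {
  cat("<stat_suppressed> ", x$metric, ": ", x$notice, "\n", sep = "")
  invisible(x)
}
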