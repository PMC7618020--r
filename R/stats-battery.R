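## Group-comparison and regression battery on the subject marker table:
## unequal-variance t for LZsum, Shapiro-Wilk normality check driving a
## Wilcoxon rank-sum for TAR, and the OLS model set (group with
## age/sex/site/TAR covariates; MMSE models on all subjects and on the
## patient group alone).

#' Unequal-variance (Welch) two-sample t test
#'
#' Welch t statistic with Satterthwaite fractional degrees of freedom and a
#' two-sided p value. Thin wrapper over \code{stats::t.test(var.equal =
#' FALSE)} presenting the module's result contract.
#'
#' @param a,b numeric samples (>= 2 values each; at least one sample must
#'   have nonzero variance).
#' @return list: \code{testName = "welch_t"}, \code{statistic} (t), \code{df}
#'   (fractional), \code{pValue}, \code{groupMeans} (named c(a, b)).
#' @examples
#' welchTTest(c(1, 2, 3), c(2, 4, 6))  # t = -1.549, df = 2.941
#' @export
welchTTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both samples: degenerate input")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(testName = "welch_t",
       statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       pValue = ht$p.value,
       groupMeans = c(a = mean(a), b = mean(b)))
}

#' Wilcoxon rank-sum test
#'
#' Reports W as the sum of the pooled ranks of sample \code{a} (midranks for
#' ties). The p value is exact by enumeration when \code{length(a) +
#' length(b) <= 20} and the data are tie-free, otherwise the normal
#' approximation with tie correction and continuity correction is used
#' (via \code{stats::wilcox.test}; its Mann-Whitney U equals
#' \code{W - n1 (n1 + 1) / 2}).
#'
#' @param a,b numeric samples (non-empty).
#' @return list: \code{testName = "wilcoxon_rank_sum"}, \code{statistic} (W,
#'   rank-sum of \code{a}), \code{pValue}, \code{groupMedians}.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))  # W = 3, p = 1/3
#' @export
wilcoxonRankSum <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("samples must be non-empty")
  n1 <- length(a)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  hasTies <- anyDuplicated(c(a, b)) > 0
  exact <- (n1 + length(b) <= 20L) && !hasTies
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(testName = "wilcoxon_rank_sum",
       statistic = W,
       pValue = ht$p.value,
       groupMedians = c(a = stats::median(a), b = stats::median(b)))
}

#' Normality check (Shapiro-Wilk at alpha = 0.05)
#'
#' Drives the choice to append a rank-based group test for a marker whose
#' distribution departs from normality.
#'
#' @param values numeric vector.
#' @return list: \code{normal} (TRUE/FALSE/NA; NA = inconclusive, e.g. n < 8
#'   or constant input), \code{statistic} (Shapiro-Wilk W), \code{pValue}.
#' @export
checkNormality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 8L)
    return(list(normal = NA, statistic = NA_real_, pValue = NA_real_,
                note = "n < 8: inconclusive"))
  if (stats::var(values) == 0)
    return(list(normal = NA, statistic = NA_real_, pValue = NA_real_,
                note = "constant input: inconclusive"))
  sw <- stats::shapiro.test(values)
  list(normal = sw$p.value >= 0.05,
       statistic = unname(sw$statistic), pValue = sw$p.value)
}

# canonical factor coding: control / first-alphabetical / first site level
.codeTable <- function(table) {
  if ("group" %in% names(table))
    table$group <- factor(table$group, levels = c("control", "patient"))
  if ("sex" %in% names(table))
    table$sex <- factor(table$sex, levels = sort(unique(as.character(table$sex))))
  if ("site" %in% names(table))
    table$site <- factor(table$site, levels = sort(unique(as.character(table$site))))
  table
}

#' Fit one OLS model from the battery
#'
#' Ordinary least squares with intercept. Categorical terms (group, sex,
#' site) are dummy-coded with control / first-alphabetical / first site as
#' reference levels. Complete-case analysis; the number of dropped rows is
#' reported.
#'
#' @param table subject marker table (data.frame with at least the outcome
#'   and term columns).
#' @param outcome \code{"lzsum"} or \code{"tar"} (any numeric column works).
#' @param terms character vector of predictor column names.
#' @param modelName optional label stored in the result.
#' @return list: \code{modelName}, \code{coefficients} (named numeric),
#'   \code{pValues} (per term), \code{rSquared}, \code{fStatistic},
#'   \code{df1}, \code{df2}, \code{overallP}, \code{n}, \code{nDropped}.
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10))
#' fitMarkerModel(d, "y", "x")$coefficients[["x"]]  # 2
#' @export
fitMarkerModel <- function(table, outcome, terms,
                           modelName = paste(outcome, "~",
                                             paste(terms, collapse = " + "))) {
  missingCols <- setdiff(c(outcome, terms), names(table))
  if (length(missingCols))
    stop("missing columns in marker table: ",
         paste(missingCols, collapse = ", "))
  table <- .codeTable(table)
  dat <- table[, c(outcome, terms), drop = FALSE]
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  if (nrow(dat) < length(terms) + 2L)
    stop("not enough complete cases to fit the model")
  form <- stats::as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design (collinear terms): ",
         paste(bad, collapse = ", "))
  }
  sm <- suppressWarnings(summary(fit))
  fs <- sm$fstatistic
  overallP <- if (is.null(fs)) NA_real_
  else stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)
  list(modelName = modelName,
       coefficients = stats::coef(fit),
       pValues = sm$coefficients[, "Pr(>|t|)"],
       rSquared = sm$r.squared,
       fStatistic = if (is.null(fs)) NA_real_ else unname(fs[1L]),
       df1 = if (is.null(fs)) NA_real_ else unname(fs[2L]),
       df2 = if (is.null(fs)) NA_real_ else unname(fs[3L]),
       overallP = unname(overallP),
       n = nrow(dat), nDropped = sum(!cc))
}

#' Run the full analysis battery
#'
#' Executes, in order: cohort descriptives; Welch t on LZsum between groups;
#' normality checks on both markers; Wilcoxon rank-sum on TAR; then the OLS
#' model set — \code{lzsum ~ group + age}, \code{lzsum ~ group + site},
#' \code{lzsum ~ group + sex}, \code{lzsum ~ group + tar},
#' \code{tar ~ group + age}, \code{tar ~ group + site}, \code{lzsum ~ mmse}
#' and \code{tar ~ mmse} on all subjects, and \code{lzsum ~ mmse},
#' \code{tar ~ mmse} on the patient group alone. Unadjusted group models
#' (\code{lzsum ~ group}, \code{tar ~ group}) are also recorded for audit.
#' No multiple-testing correction is applied to verdicts; a
#' Benjamini-Hochberg adjusted column is emitted alongside for transparency.
#'
#' @param table subject marker table: one row per subject with columns
#'   participant_id, group, age, sex, site, mmse, lzsum, tar.
#' @return an \code{AnalysisReport} (S3 list) with elements
#'   \code{descriptives}, \code{groupTests}, \code{normality},
#'   \code{models}, \code{coefficientTable} (flat data.frame incl. BH
#'   column), and \code{coding}.
#' @export
runBattery <- function(table) {
  needed <- c("participant_id", "group", "age", "sex", "site", "mmse",
              "lzsum", "tar")
  absent <- setdiff(needed, names(table))
  if (length(absent))
    stop("marker table is missing required columns: ",
         paste(absent, collapse = ", "))
  if (anyDuplicated(table$participant_id))
    stop("duplicated participant_id in marker table")
  table <- .codeTable(table)
  nByGroup <- table(table$group)
  if (any(nByGroup < 2L) || length(nByGroup) < 2L)
    stop("both groups must have >= 2 subjects (degenerate design)")

  ctrl <- table[table$group == "control", ]
  pat <- table[table$group == "patient", ]

  descr <- data.frame(
    variable = c("n", "age_mean", "age_min", "age_max", "male", "female",
                 "mmse_mean", "mmse_min", "mmse_max", "lzsum_mean",
                 "tar_mean", "tar_median"),
    control = c(nrow(ctrl), mean(ctrl$age), min(ctrl$age), max(ctrl$age),
                sum(ctrl$sex == "M"), sum(ctrl$sex == "F"),
                mean(ctrl$mmse), min(ctrl$mmse), max(ctrl$mmse),
                mean(ctrl$lzsum, na.rm = TRUE), mean(ctrl$tar, na.rm = TRUE),
                stats::median(ctrl$tar, na.rm = TRUE)),
    patient = c(nrow(pat), mean(pat$age), min(pat$age), max(pat$age),
                sum(pat$sex == "M"), sum(pat$sex == "F"),
                mean(pat$mmse), min(pat$mmse), max(pat$mmse),
                mean(pat$lzsum, na.rm = TRUE), mean(pat$tar, na.rm = TRUE),
                stats::median(pat$tar, na.rm = TRUE)))

  groupTests <- list(
    lzsum_welch_t = welchTTest(ctrl$lzsum[is.finite(ctrl$lzsum)],
                               pat$lzsum[is.finite(pat$lzsum)]),
    tar_wilcoxon = wilcoxonRankSum(ctrl$tar[is.finite(ctrl$tar)],
                                   pat$tar[is.finite(pat$tar)]))

  normality <- list(lzsum = checkNormality(table$lzsum),
                    tar = checkNormality(table$tar))

  modelSpecs <- list(
    list("lzsum", "group",                 NULL),
    list("tar",   "group",                 NULL),
    list("lzsum", c("group", "age"),       NULL),
    list("lzsum", c("group", "site"),      NULL),
    list("lzsum", c("group", "sex"),       NULL),
    list("lzsum", c("group", "tar"),       NULL),
    list("tar",   c("group", "age"),       NULL),
    list("tar",   c("group", "site"),      NULL),
    list("lzsum", "mmse",                  NULL),
    list("tar",   "mmse",                  NULL),
    list("lzsum", "mmse",                  "patient"),
    list("tar",   "mmse",                  "patient"))
  models <- list()
  for (ms in modelSpecs) {
    sub <- if (is.null(ms[[3]])) table else table[table$group == ms[[3]], ]
    nm <- paste0(ms[[1]], " ~ ", paste(ms[[2]], collapse = " + "),
                 if (!is.null(ms[[3]])) " [patients]" else "")
    models[[nm]] <- fitMarkerModel(sub, ms[[1]], ms[[2]], modelName = nm)
  }

  coefTab <- do.call(rbind, lapply(models, function(m) {
    data.frame(model = m$modelName, term = names(m$coefficients),
               beta = unname(m$coefficients), p = unname(m$pValues),
               r_squared = m$rSquared, f_statistic = m$fStatistic,
               df1 = m$df1, df2 = m$df2, n = m$n, row.names = NULL)
  }))
  coefTab$p_bh <- stats::p.adjust(coefTab$p, method = "BH")

  report <- list(
    descriptives = descr,
    groupTests = groupTests,
    normality = normality,
    models = models,
    coefficientTable = coefTab,
    coding = list(group = "control = reference",
                  sex = "first alphabetical level = reference",
                  site = "first alphabetical level = reference"))
  class(report) <- "AnalysisReport"
  report
}

#' @export
print.AnalysisReport <- function(x, ...) {
  gt <- x$groupTests
  cat("AnalysisReport\n")
  cat(sprintf("  LZsum  Welch t = %.3f, df = %.2f, p = %.4g\n",
              gt$lzsum_welch_t$statistic, gt$lzsum_welch_t$df,
              gt$lzsum_welch_t$pValue))
  cat(sprintf("  TAR    Wilcoxon W = %.0f, p = %.4g (TAR normal: %s)\n",
              gt$tar_wilcoxon$statistic, gt$tar_wilcoxon$pValue,
              as.character(x$normality$tar$normal)))
  cat(sprintf("  %d regression models fitted\n", length(x$models)))
  invisible(x)
}
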