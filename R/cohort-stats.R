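# Statistical analyses: dichotomization of the cognitive outcome measures,
# label agreement, paired/group nonparametric tests, Spearman association,
# age-adjusted ANCOVA, and FAQ functional-impairment independence checks.

#' Default dichotomization thresholds
#'
#' MMSE: impaired iff total score strictly below 28. FAQ: impaired iff
#' total score >= 6. RAVLT long-delay: impaired iff score strictly below
#' an age-bucket cut; the shipped 5-year-bucket cuts are editable
#' placeholders standing in for published age-group norms (supply your own
#' via `ravlt_age_thresholds`).
#'
#' @return List with `mmse_cut`, `faq_cut` and `ravlt_age_thresholds`
#'   (data.frame: `age_min`, `age_max`, `cut`).
#' @export
defaultThresholds <- function() {
  list(mmse_cut = 28, faq_cut = 6,
       ravlt_age_thresholds = data.frame(
         age_min = c(60, 65, 70, 75, 80),
         age_max = c(64, 69, 74, 79, 85),
         cut = c(7, 6, 5, 4, 3)))
}

.ravlt_cut <- function(age, tab) {
  i <- findInterval(age, tab$age_min)
  i[i < 1] <- 1
  tab$cut[i]
}

#' Dichotomize cognitive outcome measures into impaired / intact
#'
#' Schemes: `cohort3` (healthy / MCI / ADRD, three levels), `cohort2`
#' (impaired = MCI or ADRD, intact = healthy), `mmse` (impaired iff total
#' < 28), `ravlt_long` (impaired iff long-delay score below the age-bucket
#' cut), `faq` (functionally impaired iff total >= 6). Missing scores (or
#' cohort `"missing"`) yield missing labels.
#'
#' @param metadata participant metadata data.frame.
#' @param scheme one of `"cohort3"`, `"cohort2"`, `"mmse"`,
#'   `"ravlt_long"`, `"faq"`.
#' @param thresholds list as from [defaultThresholds()].
#' @return data.frame `participant_id`, `label` (factor; levels
#'   `impaired`/`intact`, or healthy/MCI/ADRD for `cohort3`).
#' @export
dichotomize <- function(metadata, scheme, thresholds = defaultThresholds()) {
  schemes <- c("cohort3", "cohort2", "mmse", "ravlt_long", "faq")
  if (!scheme %in% schemes)
    stop(sprintf("unknown scheme '%s'; allowed: %s", scheme,
                 paste(schemes, collapse = ", ")))
  lab <- switch(scheme,
    cohort3 = {
      l <- as.character(metadata$cohort)
      l[l == "missing"] <- NA
      factor(l, levels = c("healthy", "MCI", "ADRD"))
    },
    cohort2 = {
      l <- as.character(metadata$cohort)
      out <- ifelse(l %in% c("MCI", "ADRD"), "impaired",
                    ifelse(l == "healthy", "intact", NA))
      factor(out, levels = c("impaired", "intact"))
    },
    mmse = factor(ifelse(is.na(metadata$mmse_total), NA,
                         ifelse(metadata$mmse_total < thresholds$mmse_cut,
                                "impaired", "intact")),
                  levels = c("impaired", "intact")),
    ravlt_long = {
      cut <- .ravlt_cut(metadata$age, thresholds$ravlt_age_thresholds)
      factor(ifelse(is.na(metadata$ravlt_long_delay), NA,
                    ifelse(metadata$ravlt_long_delay < cut,
                           "impaired", "intact")),
             levels = c("impaired", "intact"))
    },
    faq = factor(ifelse(is.na(metadata$faq_total), NA,
                        ifelse(metadata$faq_total >= thresholds$faq_cut,
                               "impaired", "intact")),
                 levels = c("impaired", "intact")))
  data.frame(participant_id = metadata$participant_id, label = lab,
             stringsAsFactors = FALSE)
}

#' Agreement between two binary label sets
#'
#' @param a,b data.frames as returned by [dichotomize()] (binary schemes).
#' @return List with `confusion` (2x2 table, rows = `a`), `accuracy`
#'   (percent agreement) and `n`.
#' @export
labelAgreement <- function(a, b) {
  m <- merge(a, b, by = "participant_id", suffixes = c("_a", "_b"))
  m <- m[!is.na(m$label_a) & !is.na(m$label_b), ]
  if (!nrow(m)) stop("no overlapping labelled participants")
  conf <- table(a = m$label_a, b = m$label_b)
  list(confusion = conf,
       accuracy = 100 * sum(diag(conf)) / sum(conf),
       n = nrow(m))
}

.stat_result <- function(statistic, p, n, method)
  list(statistic = unname(statistic), p_value = unname(p), n = n,
       method = method)

#' Paired single- vs dual-task comparison (Wilcoxon signed rank)
#'
#' @param st,dt paired feature values. Pairs with missing values are
#'   dropped.
#' @return A stat-result list (`statistic`, `p_value`, `n`, `method`).
#' @export
pairedConditionTest <- function(st, dt) {
  keep <- !is.na(st) & !is.na(dt)
  st <- st[keep]; dt <- dt[keep]
  d <- st - dt
  if (all(d == 0)) {
    warning("all paired differences are zero; degenerate test, p = 1")
    return(.stat_result(0, 1, length(d), "Wilcoxon signed rank"))
  }
  wt <- suppressWarnings(wilcox.test(st, dt, paired = TRUE))
  .stat_result(wt$statistic, wt$p.value, length(d), "Wilcoxon signed rank")
}

#' Impaired vs intact group comparison (Wilcoxon rank sum)
#'
#' @param values_a,values_b feature values for the two groups.
#' @return A stat-result list.
#' @export
groupDifferenceTest <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(values_a, values_b))
  .stat_result(wt$statistic, wt$p.value,
               length(values_a) + length(values_b), "Wilcoxon rank sum")
}

#' Spearman rank association between a feature and a cognitive score
#'
#' Ties are mid-ranked; a constant input yields a missing rho.
#'
#' @param feature,score paired numeric vectors.
#' @return A stat-result list with `statistic` = rho.
#' @export
spearmanAssoc <- function(feature, score) {
  keep <- !is.na(feature) & !is.na(score)
  feature <- feature[keep]; score <- score[keep]
  if (length(feature) < 5) stop("need at least 5 complete pairs")
  if (sd(feature) == 0 || sd(score) == 0)
    return(.stat_result(NA_real_, NA_real_, length(feature),
                        "Spearman rank correlation"))
  ct <- suppressWarnings(cor.test(feature, score, method = "spearman",
                                  exact = FALSE))
  .stat_result(ct$estimate, ct$p.value, length(feature),
               "Spearman rank correlation")
}

.group_term_anova <- function(y, group, covars) {
  keep <- !is.na(y) & !is.na(group) & complete.cases(covars)
  y <- y[keep]; group <- droplevels(factor(group[keep]))
  covars <- covars[keep, , drop = FALSE]
  if (nlevels(group) < 2) stop("group factor needs at least 2 levels")
  dat <- data.frame(y = y, group = group, covars)
  rhs0 <- paste(names(covars), collapse = " + ")
  f0 <- lm(stats::as.formula(paste("y ~", rhs0)), data = dat)
  f1 <- lm(stats::as.formula(paste("y ~ group +", rhs0)), data = dat)
  if (f1$rank < nlevels(group) - 1 + f0$rank)
    stop("rank-deficient design: 'group' collinear with covariates")
  an <- anova(f0, f1)
  .stat_result(an$F[2], an$`Pr(>F)`[2], nrow(dat),
               sprintf("ANCOVA (F test for group | %s)", rhs0))
}

#' Age-adjusted group effect on a feature (ANCOVA)
#'
#' Fits `feature ~ group + age` and reports the F test for the group term
#' against the age-only model, examining the effect of cognitive status on
#' each feature while controlling for age. Apply across the `cohort3`,
#' `cohort2`, `mmse` and `ravlt_long` label schemes.
#'
#' @param feature numeric feature values.
#' @param group group labels (factor or data.frame from [dichotomize()]).
#' @param age ages in years.
#' @return A stat-result list.
#' @export
ancovaCohort <- function(feature, group, age) {
  if (is.data.frame(group)) group <- group$label
  .group_term_anova(feature, group, data.frame(age = age))
}

#' Functional-impairment association independent of cognition (FAQ)
#'
#' Fits `feature ~ faq_label + covariate + age` and reports the F test for
#' the functional-impairment term, i.e. whether the feature relates to
#' functional impairment independent of the cognitive measure (MMSE total
#' or RAVLT long-delay) and age. Run once per covariate choice.
#'
#' @param feature numeric feature values.
#' @param faq_labels FAQ-based labels (factor or [dichotomize()] output).
#' @param covariate numeric cognitive covariate (MMSE or RAVLT long delay).
#' @param age ages in years.
#' @return A stat-result list.
#' @export
faqIndependence <- function(feature, faq_labels, covariate, age) {
  if (is.data.frame(faq_labels)) faq_labels <- faq_labels$label
  if (missing(covariate) || is.null(covariate))
    stop("covariate (mmse or ravlt_long) is required")
  .group_term_anova(feature, faq_labels,
                    data.frame(covariate = covariate, age = age))
}

#' Tidy statistics report over a feature table
#'
#' One row per (feature, condition, scheme, test): paired ST-vs-DT signed
#' rank per feature; impaired-vs-intact rank sum and age-adjusted ANCOVA
#' per feature x condition x binary scheme; Spearman association with the
#' MMSE and RAVLT long-delay scores; FAQ independence per cognitive
#' covariate. Raw p-values are reported alongside a Benjamini-Hochberg
#' adjusted column (adjusted within each test family).
#'
#' @param ft a [BallFeatureTable-class].
#' @param features feature names to analyse (default: all).
#' @param conditions conditions to analyse (default st, dt, dtc).
#' @param thresholds dichotomization thresholds ([defaultThresholds()]).
#' @return data.frame with columns feature, condition, scheme, test,
#'   statistic, p_value, p_adjusted, n.
#' @export
statsReport <- function(ft, features = rownames(ft),
                        conditions = c("st", "dt", "dtc"),
                        thresholds = defaultThresholds()) {
  stopifnot(is(ft, "BallFeatureTable"))
  meta <- as.data.frame(colData(ft))
  meta$participant_id <- colnames(ft)
  labs <- lapply(c(cohort2 = "cohort2", mmse = "mmse",
                   ravlt_long = "ravlt_long", faq = "faq"),
                 function(s) dichotomize(meta, s, thresholds)$label)
  rows <- list()
  add <- function(feature, condition, scheme, test, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      feature = feature, condition = condition, scheme = scheme,
      test = test, statistic = res$statistic, p_value = res$p_value,
      n = res$n, stringsAsFactors = FALSE)
  }
  safely <- function(expr) tryCatch(suppressWarnings(expr),
                                    error = function(e) NULL)
  for (f in features) {
    stv <- assay(ft, "st")[f, ]; dtv <- assay(ft, "dt")[f, ]
    res <- safely(pairedConditionTest(stv, dtv))
    if (!is.null(res)) add(f, "paired", "none", "signed_rank", res)
    for (cond in conditions) {
      v <- assay(ft, cond)[f, ]
      for (sch in c("cohort2", "mmse", "ravlt_long")) {
        l <- labs[[sch]]
        res <- safely(groupDifferenceTest(v[which(l == "impaired")],
                                          v[which(l == "intact")]))
        if (!is.null(res)) add(f, cond, sch, "rank_sum", res)
        res <- safely(ancovaCohort(v, l, meta$age))
        if (!is.null(res)) add(f, cond, sch, "ancova_age", res)
      }
      res <- safely(ancovaCohort(v, dichotomize(meta, "cohort3")$label,
                                 meta$age))
      if (!is.null(res)) add(f, cond, "cohort3", "ancova_age", res)
      res <- safely(spearmanAssoc(v, meta$mmse_total))
      if (!is.null(res)) add(f, cond, "mmse", "spearman", res)
      res <- safely(spearmanAssoc(v, meta$ravlt_long_delay))
      if (!is.null(res)) add(f, cond, "ravlt_long", "spearman", res)
      res <- safely(faqIndependence(v, labs$faq, meta$mmse_total, meta$age))
      if (!is.null(res)) add(f, cond, "faq_mmse", "faq_independence", res)
      res <- safely(faqIndependence(v, labs$faq, meta$ravlt_long_delay,
                                    meta$age))
      if (!is.null(res)) add(f, cond, "faq_ravlt", "faq_independence", res)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  for (tst in unique(out$test)) {
    i <- out$test == tst
    out$p_adjusted[i] <- p.adjust(out$p_value[i], method = "BH")
  }
  out
}
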