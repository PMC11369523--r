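# Cross-validated logistic-regression classification of binary cognitive
# status with wrapper-based sequential forward feature selection (SFS).
# Selection is nested: within each outer training fold, candidates are
# greedily added by inner-CV accuracy, so held-out folds never influence
# the selected feature set.

#' Candidate feature set for classification
#'
#' @slot scope `"st"`, `"dt"`, `"dtc"`, `"all"` or `"age_only"`.
#' @slot baseFeatures character vector of base feature column names.
#' @slot interactions 2-column character matrix of pairwise interaction
#'   terms among the base features.
#' @slot includesAgeSex whether age and sex are appended as candidates.
#' @export
setClass("CandidateFeatureSet",
  representation(scope = "character", baseFeatures = "character",
                 interactions = "matrix", includesAgeSex = "logical"))

setValidity("CandidateFeatureSet", function(object) {
  if (object@scope == "age_only" &&
      (length(object@baseFeatures) || object@includesAgeSex))
    return("age_only scope must contain exactly the age column")
  TRUE
})

#' Classifier report: pooled cross-validated confusion metrics per stratum
#'
#' @slot metrics data.frame with one row per stratum (`all`, `male`,
#'   `female`, `mean`) and columns accuracy, sensitivity, specificity,
#'   ppv, npv (percent).
#' @slot selected list: per stratum, the features selected in each outer
#'   fold.
#' @slot scheme outcome scheme (`cohort2`, `mmse`, `ravlt_long`).
#' @slot scope candidate scope used.
#' @slot folds number of outer folds.
#' @slot seed RNG seed used.
#' @export
setClass("ClassifierReport",
  representation(metrics = "data.frame", selected = "list",
                 scheme = "character", scope = "character",
                 folds = "numeric", seed = "numeric"))

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf("ClassifierReport: scheme=%s scope=%s folds=%d seed=%d\n",
              object@scheme, object@scope, object@folds, object@seed))
  print(round(object@metrics, 2))
})

#' Build the candidate feature set for a scope
#'
#' Base features are the feature-table columns with the scope's condition
#' suffix (`all` takes the union of st, dt and dtc); pairwise interaction
#' terms among the bases are included, and age and sex are appended unless
#' the scope is `age_only`.
#'
#' @param frame flattened feature frame ([featureFrame()]) or a
#'   [BallFeatureTable-class].
#' @param scope `"st"`, `"dt"`, `"dtc"`, `"all"` or `"age_only"`.
#' @param features optional restriction of the base feature names (without
#'   condition suffix).
#' @return A [CandidateFeatureSet-class].
#' @export
buildCandidates <- function(frame, scope, features = NULL) {
  if (is(frame, "BallFeatureTable")) frame <- featureFrame(frame)
  scope <- match.arg(scope, c("st", "dt", "dtc", "all", "age_only"))
  if (scope == "age_only")
    return(new("CandidateFeatureSet", scope = scope,
               baseFeatures = character(0),
               interactions = matrix(character(0), 0, 2),
               includesAgeSex = FALSE))
  sufs <- if (scope == "all") c("st", "dt", "dtc") else scope
  base <- unlist(lapply(sufs, function(s) {
    nm <- grep(paste0("_", s, "$"), names(frame), value = TRUE)
    if (!is.null(features))
      nm <- nm[sub(paste0("_", s, "$"), "", nm) %in% features]
    nm
  }))
  # drop columns that are entirely missing or constant
  ok <- vapply(base, function(nm) {
    v <- frame[[nm]]
    sum(!is.na(v)) > 2 && sd(v, na.rm = TRUE) > 0
  }, logical(1))
  base <- base[ok]
  if (!length(base)) stop("empty candidate scope after missing-value filter")
  inter <- if (length(base) >= 2) t(utils::combn(base, 2))
           else matrix(character(0), 0, 2)
  new("CandidateFeatureSet", scope = scope, baseFeatures = base,
      interactions = inter, includesAgeSex = TRUE)
}

#' Confusion-derived classification metrics
#'
#' Standard definitions times 100, with the positive class = impaired.
#' Zero-denominator cells are reported as 0.00 and flagged in the
#' `"degenerate"` attribute (the convention for degenerate strata, e.g. no
#' positives predicted).
#'
#' @param tp,fp,tn,fn confusion-matrix counts.
#' @return Named numeric vector accuracy, sensitivity, specificity, ppv,
#'   npv (percent) with attribute `degenerate`.
#' @export
metricsFromConfusion <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("negative confusion counts")
  if (sum(counts) == 0) stop("empty confusion matrix")
  safe <- function(num, den) if (den == 0) 0 else 100 * num / den
  out <- c(accuracy = 100 * (tp + tn) / sum(counts),
           sensitivity = safe(tp, tp + fn),
           specificity = safe(tn, tn + fp),
           ppv = safe(tp, tp + fp),
           npv = safe(tn, tn + fn))
  attr(out, "degenerate") <-
    c(sensitivity = tp + fn == 0, specificity = tn + fp == 0,
      ppv = tp + fp == 0, npv = tn + fn == 0)
  out
}

.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in unique(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.fit_logit <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(glm.fit(Xi, y, family = binomial(),
                                  control = list(maxit = 25)))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  cf
}

.predict_logit <- function(cf, X) {
  as.numeric(plogis(cbind(1, X) %*% cf) > 0.5)
}

.inner_cv_accuracy <- function(X, y, cols, k) {
  fold <- .stratified_folds(y, k)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) return(NA_real_)
    cf <- .fit_logit(X[tr, cols, drop = FALSE], y[tr])
    pred <- .predict_logit(cf, X[!tr, cols, drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

.candidate_matrix <- function(frame, cand) {
  if (cand@scope == "age_only")
    return(as.matrix(data.frame(age = frame$age)))
  cols <- lapply(cand@baseFeatures, function(nm) frame[[nm]])
  names(cols) <- cand@baseFeatures
  if (nrow(cand@interactions)) {
    for (i in seq_len(nrow(cand@interactions))) {
      a <- cand@interactions[i, 1]; b <- cand@interactions[i, 2]
      cols[[paste0(a, ":", b)]] <- frame[[a]] * frame[[b]]
    }
  }
  if (cand@includesAgeSex) {
    cols$age <- frame$age
    cols$sex <- as.numeric(frame$sex == "female")
  }
  do.call(cbind, cols)
}

#' Sequential-forward-selection logistic regression with nested CV
#'
#' Stratified outer k-fold cross-validation; within each outer training
#' fold, candidates are first standardized (training statistics only) and
#' reduced to the `max_candidates` with the largest univariate
#' separation, then greedy forward selection adds the candidate that
#' maximizes inner-CV accuracy, stopping when no addition improves
#' accuracy by more than `tol` or the feature budget is reached. Held-out
#' predictions are pooled into one confusion matrix. Deterministic given
#' `seed`.
#'
#' @param candidates a [CandidateFeatureSet-class].
#' @param frame flattened feature frame with metadata columns.
#' @param labels factor with levels `impaired`, `intact` (impaired =
#'   positive class), aligned with `frame` rows.
#' @param folds outer folds (default 10).
#' @param seed RNG seed.
#' @param inner_folds inner CV folds used by the selection (default 5).
#' @param budget maximum number of selected features (default 10).
#' @param tol minimum inner-CV accuracy improvement to continue (0.001).
#' @param max_candidates univariate prescreen size per training fold.
#' @return List with `metrics` (from [metricsFromConfusion()]),
#'   `confusion`, `selected` (per fold), `n`.
#' @export
sfsLogisticCv <- function(candidates, frame, labels, folds = 10, seed = 1,
                          inner_folds = 5, budget = 10, tol = 0.001,
                          max_candidates = 40) {
  X_all <- .candidate_matrix(frame, candidates)
  keep <- complete.cases(X_all) & !is.na(labels)
  X_all <- X_all[keep, , drop = FALSE]
  y <- as.numeric(labels[keep] == "impaired")
  n <- length(y)
  if (length(unique(y)) < 2) stop("need both classes present")
  if (n < folds) stop("fewer observations than folds")
  withr::with_seed(seed, {
    fold <- .stratified_folds(y, folds)
    pred <- rep(NA_real_, n)
    selected <- vector("list", folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
        stop("stratification guard: single-class fold")
      mu <- colMeans(X_all[tr, , drop = FALSE])
      sg <- apply(X_all[tr, , drop = FALSE], 2, sd)
      sg[sg == 0] <- 1
      X <- sweep(sweep(X_all, 2, mu), 2, sg, "/")
      # univariate prescreen on training rows only
      if (ncol(X) > max_candidates) {
        score <- abs(colMeans(X[tr & y == 1, , drop = FALSE]) -
                     colMeans(X[tr & y == 0, , drop = FALSE]))
        pool <- order(score, decreasing = TRUE)[seq_len(max_candidates)]
      } else pool <- seq_len(ncol(X))
      sel <- integer(0)
      best_acc <- mean(y[tr] == as.numeric(mean(y[tr]) > 0.5))
      repeat {
        if (length(sel) >= budget) break
        remaining <- setdiff(pool, sel)
        if (!length(remaining)) break
        accs <- vapply(remaining, function(cand)
          .inner_cv_accuracy(X[tr, , drop = FALSE], y[tr],
                             c(sel, cand), inner_folds), numeric(1))
        if (all(is.na(accs))) break
        j <- which.max(accs)
        if (accs[j] > best_acc + tol) {
          sel <- c(sel, remaining[j])
          best_acc <- accs[j]
        } else break
      }
      if (!length(sel)) sel <- pool[1]  # never predict from nothing
      cf <- .fit_logit(X[tr, sel, drop = FALSE], y[tr])
      pred[!tr] <- .predict_logit(cf, X[!tr, sel, drop = FALSE])
      selected[[f]] <- colnames(X_all)[sel]
    }
    tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
    tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
    list(metrics = metricsFromConfusion(tp, fp, tn, fn),
         confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
         selected = selected, n = n)
  })
}

#' Sex-stratified classification run
#'
#' Fits the nested-CV SFS logistic classifier on all participants and on
#' the male-only and female-only strata, and reports the unweighted mean
#' of the male and female metrics as the `mean` stratum. Outcome schemes:
#' `cohort2` (consensus cohort status), `ravlt_long`, `mmse`.
#'
#' @param ft a [BallFeatureTable-class] or flattened feature frame.
#' @param scheme outcome scheme for [dichotomize()].
#' @param scope candidate scope for [buildCandidates()].
#' @param folds outer folds (default 10).
#' @param seed RNG seed.
#' @param thresholds dichotomization thresholds.
#' @param features optional restriction of base features.
#' @param ... further arguments to [sfsLogisticCv()].
#' @return A [ClassifierReport-class].
#' @export
stratifiedRun <- function(ft, scheme = "cohort2", scope = "dt", folds = 10,
                          seed = 1, thresholds = defaultThresholds(),
                          features = NULL, ...) {
  frame <- if (is(ft, "BallFeatureTable")) featureFrame(ft) else ft
  labels <- dichotomize(frame, scheme, thresholds)$label
  run_one <- function(rows, sub_seed) {
    sub <- frame[rows, , drop = FALSE]
    cand <- buildCandidates(sub, scope, features)
    sfsLogisticCv(cand, sub, labels[rows], folds = folds, seed = sub_seed,
                  ...)
  }
  strata <- list(all = rep(TRUE, nrow(frame)),
                 male = frame$sex == "male",
                 female = frame$sex == "female")
  res <- list(); sel <- list()
  for (s in names(strata)) {
    rows <- which(strata[[s]])
    ok <- sum(!is.na(labels[rows])) >= 2 * folds
    if (!ok) {
      warning(sprintf("stratum '%s' below 2 x folds; skipped", s))
      next
    }
    r <- run_one(rows, seed + match(s, names(strata)) - 1L)
    res[[s]] <- r$metrics
    sel[[s]] <- r$selected
  }
  metrics <- do.call(rbind, lapply(res, function(m) as.data.frame(t(m))))
  if (all(c("male", "female") %in% names(res)))
    metrics <- rbind(metrics,
                     mean = (metrics["male", ] + metrics["female", ]) / 2)
  new("ClassifierReport", metrics = metrics, selected = sel,
      scheme = scheme, scope = scope, folds = folds, seed = seed)
}

#' Serialize a classifier report to JSON
#' @param report a [ClassifierReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClassifierReport <- function(report, path) {
  obj <- list(scheme = report@scheme, scope = report@scope,
              folds = report@folds, seed = report@seed,
              metrics = cbind(stratum = rownames(report@metrics),
                              report@metrics),
              selected_features = report@selected)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
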