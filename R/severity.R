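#' Encode ACS groups as a numeric severity response
#'
#' Uses the clinical ordering unstable angina < NSTEMI < STEMI: `UA = 1`,
#' `NSTEMI = 2`, `STEMI = 3`. Healthy controls are either excluded (default)
#' or encoded as 0.
#'
#' @param groups character vector with values in `control`, `UA`, `NSTEMI`,
#'   `STEMI`.
#' @param includeControls if `TRUE`, controls are kept with severity 0;
#'   otherwise they get `NA` (and are dropped casewise downstream).
#' @return numeric vector parallel to `groups`.
#' @export
encodeSeverity <- function(groups, includeControls = FALSE) {
  codes <- c(control = if (includeControls) 0 else NA_real_,
             UA = 1, NSTEMI = 2, STEMI = 3)
  bad <- setdiff(unique(groups), names(codes))
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  unname(codes[groups])
}

#' Fit the severity model for one DMR
#'
#' Ordinary least squares of the full model
#' `Y ~ beta0 + beta1 * DNAmeth + beta2 * ccfDNAlevel`, where `Y` is the
#' numeric severity (or a clinical marker), `DNAmeth` the per-sample percent
#' methylation of the DMR, and `ccfDNAlevel` the plasma ccfDNA concentration
#' used as a covariate. The methylation coefficient is tested by t-test, and
#' the full model is compared with the reduced model `Y ~ beta0 + beta2 *
#' ccfDNAlevel` by a nested ANOVA F-test with (1, n - 3) df. For this
#' single-parameter nesting, `F == t^2` identically.
#'
#' @param y numeric response (severity encoding or clinical marker).
#' @param meth per-sample DMR methylation (percent).
#' @param ccfdna per-sample ccfDNA level (ng per ml plasma).
#' @param dmrID label carried into the result.
#' @return one-row data.frame: `dmr`, `beta0`, `beta1`, `beta2`, `t_beta1`,
#'   `p_beta1`, `F_nested`, `p_F`, `n_samples`, `flag` (TRUE when the fit was
#'   degenerate: constant methylation or too few complete cases).
#' @export
fitDMRModel <- function(y, meth, ccfdna, dmrID = "dmr") {
  cc <- stats::complete.cases(y, meth, ccfdna)
  y <- y[cc]; meth <- meth[cc]; ccfdna <- ccfdna[cc]
  n <- length(y)
  degenerate <- n < 5 || stats::sd(meth) == 0 || stats::sd(y) == 0
  if (degenerate) {
    return(data.frame(dmr = dmrID, beta0 = NA_real_, beta1 = NA_real_,
                      beta2 = NA_real_, t_beta1 = NA_real_, p_beta1 = 1,
                      F_nested = NA_real_, p_F = 1, n_samples = n,
                      flag = TRUE, stringsAsFactors = FALSE))
  }
  full <- stats::lm(y ~ meth + ccfdna)
  reduced <- stats::lm(y ~ ccfdna)
  sm <- summary(full)$coefficients
  tb1 <- sm["meth", "t value"]
  pb1 <- sm["meth", "Pr(>|t|)"]
  an <- stats::anova(reduced, full)
  data.frame(dmr = dmrID,
             beta0 = unname(stats::coef(full)[1]),
             beta1 = unname(stats::coef(full)["meth"]),
             beta2 = unname(stats::coef(full)["ccfdna"]),
             t_beta1 = tb1, p_beta1 = pb1,
             F_nested = an$F[2], p_F = an$`Pr(>F)`[2],
             n_samples = n, flag = FALSE, stringsAsFactors = FALSE)
}

#' Fit severity models across all DMRs
#'
#' @param methMatrix DMR x sample percent-methylation matrix (e.g. from
#'   [methylationMatrix()]).
#' @param y numeric response per sample (see [encodeSeverity()]).
#' @param ccfdna ccfDNA level per sample.
#' @return data.frame with one [fitDMRModel()] row per DMR.
#' @export
fitSeverityModels <- function(methMatrix, y, ccfdna) {
  stopifnot(ncol(methMatrix) == length(y), length(y) == length(ccfdna))
  out <- do.call(rbind, lapply(rownames(methMatrix), function(d) {
    fitDMRModel(y, methMatrix[d, ], ccfdna, dmrID = d)
  }))
  rownames(out) <- NULL
  out
}

#' Select DMRs significantly associated with the response
#'
#' @param fits data.frame from [fitSeverityModels()].
#' @param alpha p-value threshold on the methylation coefficient (default
#'   0.05).
#' @return list with `selected` (the retained rows) and `fraction` (percent
#'   of input DMRs retained).
#' @export
selectAssociatedDMRs <- function(fits, alpha = 0.05) {
  if (!nrow(fits)) return(list(selected = fits, fraction = NA_real_))
  keep <- fits$p_beta1 <= alpha
  list(selected = fits[keep, , drop = FALSE],
       fraction = 100 * mean(keep))
}

#' Associate DMRs with clinical markers
#'
#' Re-uses the severity machinery with each clinical marker as the response:
#' `marker ~ beta0 + beta1 * DNAmeth + beta2 * ccfDNAlevel`. Markers with
#' fewer than 5 non-missing samples are skipped with a warning.
#'
#' @param methMatrix DMR x sample percent-methylation matrix.
#' @param markers data.frame of numeric marker columns (samples in rows,
#'   aligned with `methMatrix` columns).
#' @param ccfdna ccfDNA level per sample.
#' @param alpha significance threshold for the per-marker summary.
#' @return list with `fits` (long data.frame: marker + [fitDMRModel()]
#'   columns) and `summary` (per-marker percent of DMRs with
#'   `p_beta1 <= alpha`).
#' @export
fitMarkerModels <- function(methMatrix, markers, ccfdna, alpha = 0.05) {
  res <- list()
  for (mk in names(markers)) {
    y <- markers[[mk]]
    if (sum(!is.na(y)) < 5) {
      warning(sprintf("marker '%s' has < 5 non-missing values; skipped", mk))
      next
    }
    f <- fitSeverityModels(methMatrix, y, ccfdna)
    f$marker <- mk
    res[[mk]] <- f
  }
  if (!length(res)) stop("no marker could be modeled")
  fits <- do.call(rbind, res)
  rownames(fits) <- NULL
  summary <- vapply(res, function(f) 100 * mean(f$p_beta1 <= alpha), numeric(1))
  list(fits = fits, summary = summary)
}

#' Misclassification rate of a single-marker multinomial model
#'
#' Fits a one-predictor multinomial logistic regression of ACS type on a
#' clinical marker (samples with missing marker values are excluded),
#' predicts in-sample classes by maximum probability, and reports the percent
#' misclassified.
#'
#' @param marker numeric predictor (missing values excluded).
#' @param labels class labels (factor or character), e.g. ACS types.
#' @return list with `rate` (percent misclassified), `n` (samples used) and
#'   `fit` (the `nnet::multinom` object); `separation = TRUE` flags a
#'   quasi-separated fit refit with a small weight decay.
#' @export
singleMarkerMultinomial <- function(marker, labels) {
  ok <- !is.na(marker) & !is.na(labels)
  marker <- marker[ok]; labels <- factor(labels[ok])
  if (nlevels(labels) < 2) stop("need >= 2 classes with non-missing marker values")
  df <- data.frame(y = labels, x = marker)
  if (stats::sd(marker) == 0) {
    # constant predictor: the MLE fits the class frequencies; the argmax
    # prediction is the majority class (ties broken by factor level order)
    freq <- table(labels)
    pred <- factor(rep(names(freq)[which.max(freq)], nrow(df)),
                   levels = levels(labels))
    return(list(rate = 100 * mean(pred != labels), n = nrow(df),
                fit = NULL, separation = FALSE))
  }
  fit <- nnet::multinom(y ~ x, data = df, trace = FALSE)
  separation <- any(abs(stats::coef(fit)) > 1e4)
  if (separation)
    fit <- nnet::multinom(y ~ x, data = df, trace = FALSE, decay = 1e-3)
  pred <- stats::predict(fit, df)
  list(rate = 100 * mean(pred != labels), n = nrow(df), fit = fit,
       separation = separation)
}

# Stratified index split: ~trainFrac of each class into training.
.stratified_split <- function(labels, trainFrac) {
  labels <- factor(labels)
  train <- integer(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    nTr <- max(2L, round(trainFrac * length(idx)))
    nTr <- min(nTr, length(idx) - 1L)
    if (nTr < 1L) nTr <- length(idx)   # tiny class: all to training
    train <- c(train, sample(idx, nTr))
  }
  sort(train)
}

.fit_one_classifier <- function(model, x, y, tune, seed) {
  set.seed(seed)
  switch(model,
    rf = randomForest::randomForest(x, y, ntree = 500, mtry = tune),
    pls = mixOmics::plsda(x, y, ncomp = tune),
    # small-class warnings are expected at these cohort sizes
    pmr = suppressWarnings(glmnet::glmnet(x, y, family = "multinomial",
                                          alpha = 0, lambda = tune))
  )
}

.predict_classifier <- function(model, fit, x) {
  switch(model,
    rf = stats::predict(fit, x),
    pls = {
      pr <- stats::predict(fit, x)
      cls <- pr$class$max.dist[, ncol(pr$class$max.dist)]
      factor(cls, levels = levels(fit$Y))
    },
    pmr = factor(drop(stats::predict(fit, x, type = "class")),
                 levels = fit$classnames)
  )
}

.tune_grid <- function(model, x) {
  p <- ncol(x)
  switch(model,
    rf = unique(pmax(1, round(c(sqrt(p), p / 3, p / 10)))),
    pls = seq_len(min(5L, p, 8L)),
    pmr = 10^seq(-3, 1, length.out = 8)
  )
}

# Repeated k-fold CV accuracy for one tuning value.
.cv_accuracy <- function(model, x, y, tune, folds, repeats, seed) {
  accs <- numeric(0)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    fold <- stats::ave(seq_along(y), y,
                       FUN = function(i) sample(rep_len(seq_len(folds), length(i))))
    for (f in unique(fold)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < nlevels(y)) next
      acc <- try({
        fit <- .fit_one_classifier(model, x[tr, , drop = FALSE],
                                   droplevels(y[tr]), tune, seed + r)
        pred <- .predict_classifier(model, fit, x[!tr, , drop = FALSE])
        mean(as.character(pred) == as.character(y[!tr]))
      }, silent = TRUE)
      if (!inherits(acc, "try-error")) accs <- c(accs, acc)
    }
  }
  if (!length(accs)) NA_real_ else mean(accs)
}

#' Train ACS-type classifiers on DMR methylation features
#'
#' Trains random forest (`rf`), PLS discriminant analysis (`pls`) and
#' L2-penalized multinomial regression (`pmr`) on a stratified 70/30
#' train/test split. Features are centered and scaled with parameters learned
#' on the training split only and applied to all evaluation data. Tuning uses
#' repeated k-fold cross-validation (default 10-fold, 10 repeats) on the
#' training split; held-out and optional external-cohort accuracies are
#' reported per model.
#'
#' @param features samples x DMR percent-methylation matrix (complete cases;
#'   DMRs with any missing value are dropped with a message).
#' @param labels class labels per sample.
#' @param models subset of `c("rf", "pls", "pmr")`.
#' @param trainFrac training fraction of the split (default 0.7).
#' @param cvFolds,cvRepeats cross-validation design (default 10 x 10).
#' @param seed integer seed controlling the split, fold assignment and model
#'   randomness.
#' @param external optional list `list(features = ..., labels = ...)` of an
#'   external cohort scored with the trained models (scaled by the training
#'   parameters).
#' @return list with per-model entries (`tuned` value, `cv_accuracy`,
#'   `test_accuracy`, `external_accuracy` when given, `fit`) plus `split`
#'   (train indices) and `scaling` (centers/scales).
#' @export
trainACSClassifiers <- function(features, labels,
                                models = c("rf", "pls", "pmr"),
                                trainFrac = 0.7, cvFolds = 10L,
                                cvRepeats = 10L, seed = 1L,
                                external = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  if (any(models == "pls") && !requireNamespace("mixOmics", quietly = TRUE))
    stop("the 'pls' model requires the mixOmics package")
  x <- as.matrix(features)
  keep <- colSums(is.na(x)) == 0
  if (!all(keep)) {
    message(sprintf("dropping %d DMRs with missing values", sum(!keep)))
    x <- x[, keep, drop = FALSE]
  }
  y <- factor(labels)
  if (any(table(y) < 2)) stop("need >= 2 samples per class")
  set.seed(deriveSeed(seed, "split"))
  tr <- .stratified_split(y, trainFrac)
  xtr <- x[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
  xte <- x[-tr, , drop = FALSE]; yte <- y[-tr]
  ctr <- colMeans(xtr)
  scl <- apply(xtr, 2, stats::sd); scl[scl == 0] <- 1
  scale_to <- function(m) sweep(sweep(m, 2, ctr), 2, scl, "/")
  xtr <- scale_to(xtr); xte <- scale_to(xte)
  out <- list(split = tr, scaling = list(center = ctr, scale = scl))
  for (m in models) {
    grid <- .tune_grid(m, xtr)
    cvs <- vapply(grid, function(g) {
      .cv_accuracy(m, xtr, ytr, g, cvFolds, cvRepeats, deriveSeed(seed, paste0("cv_", m)))
    }, numeric(1))
    best <- grid[which.max(cvs)]
    res <- tryCatch({
      fit <- .fit_one_classifier(m, xtr, ytr, best,
                                 deriveSeed(seed, paste0("fit_", m)))
      pred <- .predict_classifier(m, fit, xte)
      r <- list(tuned = best, cv_accuracy = max(cvs, na.rm = TRUE),
                test_accuracy = mean(as.character(pred) == as.character(yte)),
                fit = fit)
      if (!is.null(external)) {
        xe <- scale_to(as.matrix(external$features)[, colnames(x), drop = FALSE])
        pe <- .predict_classifier(m, fit, xe)
        r$external_accuracy <- mean(as.character(pe) == as.character(external$labels))
      }
      r
    }, error = function(e) {
      warning(sprintf("model '%s' failed: %s", m, conditionMessage(e)))
      list(tuned = best, cv_accuracy = max(c(cvs, NA), na.rm = TRUE),
           test_accuracy = NA_real_, fit = NULL,
           error = conditionMessage(e))
    })
    out[[m]] <- res
  }
  out
}

#' Principal-component embedding of samples on DMR methylation
#'
#' Centered (not scaled) PCA; returns the first two components and their
#' explained-variance fractions.
#'
#' @param m samples x DMR methylation matrix (complete).
#' @param scale. scale columns to unit variance (default `FALSE`).
#' @return list with `coords` (samples x 2), `explained` (length-2 fractions)
#'   and the full `prcomp` object.
#' @export
pcaEmbed <- function(m, scale. = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need >= 2 samples for PCA")
  if (anyNA(m)) stop("matrix must be complete for PCA")
  constant <- apply(m, 2, stats::sd) == 0
  if (scale. && any(constant)) m <- m[, !constant, drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  k <- min(2L, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x[, seq_len(k), drop = FALSE],
       explained = ev[seq_len(k)], prcomp = pc)
}

#' Mean silhouette width of groups in a 2-D embedding
#'
#' Small helper to quantify group separation in the PC1-PC2 plane (Euclidean
#' distances, standard silhouette definition).
#'
#' @param coords samples x 2 coordinate matrix.
#' @param groups group label per sample.
#' @return mean silhouette width across samples.
#' @export
meanSilhouette <- function(coords, groups) {
  groups <- as.character(groups)
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- groups == groups[i]; own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    bs <- vapply(setdiff(unique(groups), groups[i]),
                 function(g) mean(d[i, groups == g]), numeric(1))
    b <- min(bs)
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}
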