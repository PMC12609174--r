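# Biomarker classification: leave-one-out logistic scores, ROC/AUC with
# Youden threshold, and DeLong comparison of paired AUCs.
#
# The classifier is logistic regression: for a single feature its LOOCV
# score is a monotone transform of the feature (so the AUC matches simple
# thresholding), and it extends naturally to the two-feature "combined"
# model. ROC machinery is delegated to pROC; brute-force pair counting
# serves as the independent oracle in the test suite.

# Ridge-penalised logistic IRLS, used only as the separation fallback
# (lambda on non-intercept coefficients keeps estimates finite).
.ridgeLogistic <- function(X, y, weights = rep(1, length(y)),
                           lambda = 1e-2, maxit = 100L) {
  X1 <- cbind(1, X)
  beta <- numeric(ncol(X1))
  pen <- diag(c(0, rep(lambda, ncol(X1) - 1L)), ncol(X1))
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    v <- pmax(mu * (1 - mu), 1e-10)
    w <- v * weights
    z <- eta + (y - mu) / v
    XtW <- t(X1 * w)
    betaNew <- solve(XtW %*% X1 + pen, XtW %*% z)
    if (max(abs(betaNew - beta)) < 1e-10) {
      beta <- betaNew
      break
    }
    beta <- betaNew
  }
  drop(beta)
}

#' Leave-one-out cross-validated logistic scores
#'
#' For every subject, fits a logistic model on the remaining `n - 1`
#' subjects and records the held-out predicted probability of the positive
#' class. Works for one feature or several (the "combined" model). A
#' training fold missing one class scores the held-out subject with the
#' fold's class prior (with a warning); separation falls back to a
#' ridge-penalised fit. The procedure is deterministic.
#'
#' @param features numeric vector or matrix (subjects x features).
#' @param labels binary vector; the positive class is `positive`.
#' @param positive value of `labels` treated as the positive class
#'   (default the larger/last sorted unique value).
#' @return numeric vector of out-of-fold probabilities, one per subject.
#' @export
loocvScores <- function(features, labels, positive = NULL) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 subjects for leave-one-out scoring")
  ulab <- sort(unique(labels))
  if (length(ulab) != 2L) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- ulab[2]
  y <- as.integer(labels == positive)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    if (length(unique(yi)) < 2L) {
      warning("training fold lost a class: scoring by prior")
      scores[i] <- mean(yi)
      next
    }
    # standardise features on the training fold (held-out subject mapped
    # with the fold's statistics) so fits are scale-free, and balance the
    # class weights so the fold's class prior does not leak into the
    # held-out score (pooled LOOCV-ROC is otherwise pessimistically
    # biased under the null)
    mu <- colMeans(Xi)
    sdv <- apply(Xi, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Zi <- sweep(sweep(Xi, 2, mu), 2, sdv, "/")
    zHeld <- (X[i, ] - mu) / sdv
    w <- ifelse(yi == 1L, 0.5 / mean(yi == 1L), 0.5 / mean(yi == 0L))
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, Zi), yi, weights = w,
                     family = stats::binomial()))
    sep <- !fit$converged || any(fit$fitted.values > 1 - 1e-8) ||
      any(fit$fitted.values < 1e-8)
    beta <- if (sep) {
      .logMsg("separation in LOOCV fold %d: ridge-penalised fallback", i)
      .ridgeLogistic(Zi, yi, weights = w)
    } else fit$coefficients
    beta[is.na(beta)] <- 0  # aliased (constant) features carry no signal
    eta <- sum(c(1, zHeld) * beta)
    scores[i] <- 1 / (1 + exp(-eta))
  }
  scores
}

#' ROC curve result
#'
#' @slot modelId model label (`"volume"`, `"autocorrelation"`,
#'   `"combined"`, ...).
#' @slot auc area under the ROC curve (ties counted 1/2; equals the
#'   Mann-Whitney statistic).
#' @slot sensitivity,specificity operating characteristics at `threshold`.
#' @slot threshold Youden-optimal score threshold.
#' @slot scores,labels the inputs (out-of-fold scores and binary labels).
#' @seealso [rocCurve()], [delongTest()]
#' @export
setClass("RocResult",
  slots = c(modelId = "character", auc = "numeric",
            sensitivity = "numeric", specificity = "numeric",
            threshold = "numeric", scores = "numeric", labels = "integer"))

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult [%s]: AUC %.3f, sens %.2f / spec %.2f at %.4g (n = %d)\n",
              object@modelId, object@auc, object@sensitivity,
              object@specificity, object@threshold, length(object@labels)))
})

.rocObject <- function(scores, labels) {
  pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
            direction = "<", quiet = TRUE)
}

#' ROC analysis of a score vector
#'
#' Computes the AUC (trapezoid; equal scores contribute 1/2, so the value
#' equals normalised Mann-Whitney pair counting) and the Youden-optimal
#' operating point, ties broken toward higher sensitivity.
#'
#' @param scores numeric scores; larger values indicate the positive class.
#' @param labels binary labels (coerced so that the positive class is 1; a
#'   two-level factor or a 0/1 vector both work).
#' @param modelId label carried into the result.
#' @return A [RocResult-class].
#' @examples
#' rocCurve(c(.1, .2, .8, .9), c(0, 0, 1, 1))
#' @export
rocCurve <- function(scores, labels, modelId = "model") {
  ulab <- sort(unique(labels))
  if (length(ulab) != 2L)
    stop("both classes must be present for ROC analysis")
  y <- as.integer(labels == ulab[2])
  r <- .rocObject(scores, y)
  aucVal <- as.numeric(pROC::auc(r))
  op <- optimalThreshold(scores, y)
  new("RocResult", modelId = modelId, auc = aucVal,
      sensitivity = op$sensitivity, specificity = op$specificity,
      threshold = op$threshold, scores = as.numeric(scores),
      labels = y)
}

#' Youden-optimal threshold
#'
#' Scans all candidate thresholds and maximises Youden's
#' `J = sensitivity + specificity - 1`; among ties the threshold with the
#' higher sensitivity is returned. Subjects score positive when
#' `score >= threshold`.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels (1 = positive).
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
optimalThreshold <- function(scores, labels) {
  y <- as.integer(labels)
  stopifnot(all(y %in% c(0L, 1L)), any(y == 1L), any(y == 0L))
  cand <- sort(unique(scores))
  cand <- c(cand, max(cand) + 1)  # "call nothing positive" endpoint
  best <- NULL
  for (th in cand) {
    pos <- scores >= th
    sens <- sum(pos & y == 1L) / sum(y == 1L)
    spec <- sum(!pos & y == 0L) / sum(y == 0L)
    J <- sens + spec - 1
    if (is.null(best) || J > best$youden + 1e-12 ||
        (abs(J - best$youden) <= 1e-12 && sens > best$sensitivity))
      best <- list(threshold = th, sensitivity = sens,
                   specificity = spec, youden = J)
  }
  best
}

#' DeLong comparison result for two paired AUCs
#'
#' @slot aucA,aucB the two AUCs.
#' @slot varDiff estimated variance of the AUC difference.
#' @slot z normal test statistic (sign matches `aucA - aucB`).
#' @slot p two-sided p-value.
#' @export
setClass("DeLongResult",
  slots = c(aucA = "numeric", aucB = "numeric", varDiff = "numeric",
            z = "numeric", p = "numeric"))

setMethod("show", "DeLongResult", function(object) {
  cat(sprintf("DeLong: AUC %.3f vs %.3f, z = %.3f, p = %.4g\n",
              object@aucA, object@aucB, object@z, object@p))
})

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the same subjects
#' and labels, using the midrank structural-component estimator of the
#' paired AUC covariance and a two-sided normal p-value. Identical score
#' vectors have zero variance; by convention `p = 1` is returned (logged).
#'
#' @param scoresA,scoresB paired score vectors.
#' @param labels shared binary labels.
#' @return A [DeLongResult-class].
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  stopifnot(length(scoresA) == length(scoresB),
            length(scoresA) == length(labels))
  ulab <- sort(unique(labels))
  if (length(ulab) != 2L) stop("both classes must be present")
  y <- as.integer(labels == ulab[2])
  rA <- .rocObject(scoresA, y)
  rB <- .rocObject(scoresB, y)
  aucA <- as.numeric(pROC::auc(rA))
  aucB <- as.numeric(pROC::auc(rB))
  if (isTRUE(all.equal(scoresA, scoresB))) {
    .logMsg("identical score vectors: DeLong variance is zero, p = 1")
    return(new("DeLongResult", aucA = aucA, aucB = aucB, varDiff = 0,
               z = 0, p = 1))
  }
  tst <- suppressWarnings(suppressMessages(
    pROC::roc.test(rA, rB, method = "delong", paired = TRUE)))
  z <- unname(tst$statistic)
  p <- tst$p.value
  if (!is.finite(z)) { z <- 0; p <- 1 }
  varDiff <- if (z != 0) ((aucA - aucB) / z)^2 else 0
  new("DeLongResult", aucA = aucA, aucB = aucB, varDiff = varDiff,
      z = z, p = p)
}

#' Two-group classification from a feature table
#'
#' Runs the full biomarker comparison of one region (by default the
#' composite): LOOCV logistic scores for the volume-only, texture-only and
#' combined models, pooled-score ROC with Youden operating point, and the
#' DeLong test between the two single-measure models.
#'
#' @param table feature table with both measures.
#' @param manifest subject manifest.
#' @param regionId region to classify on (default: composite id must be
#'   supplied by the caller via this argument).
#' @param groups character(2): (negative, positive) class groups, e.g.
#'   `c("HC", "mild")`.
#' @param models subset of `c("volume", "autocorrelation", "combined")`.
#' @return list with one [RocResult-class] per model and `delong`, the
#'   [DeLongResult-class] comparing volume vs autocorrelation (when both
#'   are present).
#' @export
classifyGroups <- function(table, manifest, regionId, groups = c("HC", "mild"),
                           models = c("volume", "autocorrelation",
                                      "combined")) {
  validateFeatureTable(table)
  models <- match.arg(models, several.ok = TRUE)
  m <- manifest[manifest$group %in% groups, , drop = FALSE]
  wide <- function(measure) {
    t <- table[table$measure == measure & table$region_id == regionId, ]
    t$value[match(m$subject_id, t$subject_id)]
  }
  vol <- wide("volume"); tex <- wide("autocorrelation")
  keep <- !is.na(vol) & !is.na(tex)
  if (sum(!keep) > 0)
    .logMsg("%d subject(s) dropped for missing features", sum(!keep))
  vol <- vol[keep]; tex <- tex[keep]
  y <- as.integer(m$group[keep] == groups[2])
  if (length(unique(y)) < 2L) stop("both groups must be present")
  featSets <- list(volume = cbind(volume = vol),
                   autocorrelation = cbind(autocorrelation = tex),
                   combined = cbind(volume = vol, autocorrelation = tex))
  out <- list()
  for (mod in models) {
    sc <- loocvScores(featSets[[mod]], y, positive = 1L)
    out[[mod]] <- rocCurve(sc, y, modelId = mod)
  }
  if (all(c("volume", "autocorrelation") %in% models))
    out$delong <- delongTest(out$volume@scores, out$autocorrelation@scores,
                             y)
  out
}
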