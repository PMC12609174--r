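# Group-level statistics: ANCOVA contrasts, FDR, effect sizes, z-scores,
# texture-volume regressions, demographic tests.
#
# All pairwise contrasts come from ONE three-group linear model per region
# (value ~ group + age + sex), so the adjusted differences satisfy the
# transitivity identity (HC - moderate) = (HC - mild) + (mild - moderate)
# exactly. FDR correction is applied across regions, separately per
# (measure, contrast) family; no correction is applied across the three
# contrasts within a region.

.PAIRS <- list(c("HC", "mild"), c("HC", "moderate"), c("mild", "moderate"))

# Merge one measure's rows with the manifest; explicit-NA rows are dropped
# pairwise per region with a logged count.
.measureFrame <- function(table, manifest, measure) {
  validateFeatureTable(table)
  t <- table[table$measure == measure, , drop = FALSE]
  if (nrow(t) == 0L) stop("no rows for measure '", measure, "'")
  merged <- merge(t, manifest, by = "subject_id")
  nmiss <- sum(is.na(merged$value))
  if (nmiss > 0)
    .logMsg("%d missing %s value(s) excluded pairwise", nmiss, measure)
  merged[!is.na(merged$value), , drop = FALSE]
}

# Single-region ANCOVA fit; returns NULL (with a warning) on a
# rank-deficient design.
.fitRegion <- function(df, covariates = TRUE) {
  df$group <- factor(df$group, levels = .groups[.groups %in% df$group])
  if (nlevels(df$group) < 2L) return(NULL)
  form <- value ~ group
  if (covariates) {
    # constant covariates carry no information and are dropped rather than
    # allowed to break the fit
    if (length(unique(df$age)) > 1L)
      form <- stats::update(form, . ~ . + age)
    if (length(unique(df$sex)) > 1L)
      form <- stats::update(form, . ~ . + sex)
  }
  fit <- stats::lm(form, data = df)
  if (anyNA(stats::coef(fit))) {
    warning("rank-deficient design: region skipped")
    return(NULL)
  }
  fit
}

# Adjusted-mean pairwise differences with t-based CIs from one fitted lm.
# With treatment coding, groupX coefficients are adjusted differences from
# the reference level; a pair (I, J) difference is beta_J - beta_I (I - J
# on the response scale: mean_I - mean_J = -(beta_I) + ... ). We build the
# contrast vector explicitly against the coefficient names.
.pairContrast <- function(fit, I, J, level = 0.95) {
  cf <- stats::coef(fit)
  cv <- stats::setNames(numeric(length(cf)), names(cf))
  nmI <- paste0("group", I); nmJ <- paste0("group", J)
  if (nmI %in% names(cv)) cv[nmI] <- 1
  if (nmJ %in% names(cv)) cv[nmJ] <- -1
  est <- sum(cv * cf)
  se <- sqrt(drop(t(cv) %*% stats::vcov(fit) %*% cv))
  dfres <- fit$df.residual
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), dfres)
  crit <- stats::qt(1 - (1 - level) / 2, dfres)
  c(difference = est, ci_low = est - crit * se, ci_high = est + crit * se,
    p = p, se = se, sigma = summary(fit)$sigma)
}

#' Three-group ANCOVA contrasts per region
#'
#' Fits, per region, `value ~ group + age + sex` (group with three levels)
#' and reports the three pairwise adjusted-mean differences (HC - mild,
#' HC - moderate, mild - moderate) with t-based 95% confidence intervals
#' and two-sided p-values on the model's residual degrees of freedom.
#' FDR-adjusted p-values (Benjamini-Hochberg across regions, separately
#' per contrast) are appended.
#'
#' @param table long-format feature table.
#' @param manifest subject manifest (subject_id, group, age, sex).
#' @param measure `"autocorrelation"` or `"volume"`.
#' @param regions region ids to analyse (default: all in the table).
#' @param covariates adjust for age and sex (default TRUE).
#' @param level confidence level (default 0.95).
#' @return data.frame with one row per (region, contrast): `region_id`,
#'   `measure`, `group_i`, `group_j`, `difference` (I - J), `ci_low`,
#'   `ci_high`, `p`, `p_fdr`.
#' @export
ancovaContrasts <- function(table, manifest, measure, regions = NULL,
                            covariates = TRUE, level = 0.95) {
  mf <- .measureFrame(table, manifest, measure)
  if (is.null(regions)) regions <- sort(unique(mf$region_id))
  out <- list()
  for (rid in regions) {
    df <- mf[mf$region_id == rid, , drop = FALSE]
    counts <- tabulate(factor(df$group, levels = unique(df$group)))
    if (any(counts < 2) || nrow(df) < 4) next
    fit <- .fitRegion(df, covariates)
    if (is.null(fit)) next
    for (pr in .PAIRS) {
      if (!all(pr %in% df$group)) next
      ct <- .pairContrast(fit, pr[1], pr[2], level)
      out[[length(out) + 1L]] <- data.frame(
        region_id = rid, measure = measure, group_i = pr[1],
        group_j = pr[2], difference = ct[["difference"]],
        ci_low = ct[["ci_low"]], ci_high = ct[["ci_high"]],
        p = ct[["p"]], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(region_id = integer(), measure = character(),
                      group_i = character(), group_j = character(),
                      difference = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p = numeric(),
                      p_fdr = numeric()))
  res <- do.call(rbind, out)
  res$p_fdr <- NA_real_
  for (pr in .PAIRS) {
    sel <- res$group_i == pr[1] & res$group_j == pr[2]
    if (any(sel)) res$p_fdr[sel] <- fdrAdjust(res$p[sel])$p_adjusted
  }
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (via `stats::p.adjust(method = "BH")`) and
#' rejection flags at level `q`. Applied across regions, one family per
#' (measure, contrast).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `p_adjusted` and logical `rejected`.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))$rejected
#' @export
fdrAdjust <- function(p, q = 0.05) {
  if (length(p) == 0L)
    return(list(p_adjusted = numeric(), rejected = logical()))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), q > 0, q < 1)
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, rejected = !is.na(adj) & adj <= q)
}

#' Covariate-adjusted effect sizes and their volume-texture difference
#'
#' For one pairwise contrast, computes per region the standardised effect
#' (adjusted mean difference divided by the ANCOVA residual standard
#' deviation - a covariate-adjusted Cohen's d) for volume and for
#' autocorrelation, plus their difference (volume minus texture), the map
#' used to judge which measure separates the groups more strongly.
#'
#' @param table feature table holding both measures.
#' @param manifest subject manifest.
#' @param contrast character(2), e.g. `c("HC", "mild")`.
#' @param regions region ids (default all).
#' @return data.frame with `region_id`, `effect_volume`,
#'   `effect_texture`, `effect_difference`.
#' @export
effectSizes <- function(table, manifest, contrast = c("HC", "mild"),
                        regions = NULL) {
  one <- function(measure) {
    mf <- .measureFrame(table, manifest, measure)
    rids <- if (is.null(regions)) sort(unique(mf$region_id)) else regions
    vapply(rids, function(rid) {
      df <- mf[mf$region_id == rid, , drop = FALSE]
      fit <- .fitRegion(df)
      if (is.null(fit) || !all(contrast %in% df$group)) return(NA_real_)
      ct <- .pairContrast(fit, contrast[1], contrast[2])
      ct[["difference"]] / ct[["sigma"]]
    }, numeric(1))
  }
  mfv <- .measureFrame(table, manifest, "volume")
  rids <- if (is.null(regions)) sort(unique(mfv$region_id)) else regions
  ev <- one("volume"); et <- one("autocorrelation")
  data.frame(region_id = rids, effect_volume = ev, effect_texture = et,
             effect_difference = ev - et)
}

#' Standardise features to z-scores against the control group
#'
#' Per region and measure, `(value - mean_HC) / sd_HC`. Intended for
#' visualisation only; inference runs on the raw values.
#'
#' @param table feature table.
#' @param manifest subject manifest.
#' @return feature table of z-scores (regions whose HC standard deviation
#'   is zero or undefined become missing, with a warning).
#' @export
zscoreVsControls <- function(table, manifest) {
  validateFeatureTable(table)
  merged <- merge(table, manifest[, c("subject_id", "group")],
                  by = "subject_id", sort = FALSE)
  out <- table
  key <- paste(merged$region_id, merged$measure)
  for (k in unique(key)) {
    sel <- key == k
    hc <- merged$value[sel & merged$group == "HC"]
    hc <- hc[!is.na(hc)]
    if (length(hc) < 2L || stats::sd(hc) == 0) {
      warning("HC reference undefined for ", k, ": z-scores missing")
      z <- NA_real_
    } else {
      z <- (merged$value[sel] - mean(hc)) / stats::sd(hc)
    }
    idx <- match(paste(merged$subject_id[sel], merged$region_id[sel],
                       merged$measure[sel]),
                 paste(out$subject_id, out$region_id, out$measure))
    out$value[idx] <- z
  }
  out
}

#' Region-wise regression of volume on texture
#'
#' Per region, ordinary least squares `volume ~ autocorrelation + age +
#' sex`, optionally adding `group` as a covariate; reports the texture
#' slope, its p-value and the FDR-adjusted p across regions.
#'
#' @param table feature table with both measures.
#' @param manifest subject manifest.
#' @param includeGroup add group as a covariate (default FALSE).
#' @param regions region ids (default all with both measures).
#' @return data.frame with `region_id`, `beta_texture`, `se`, `p`,
#'   `p_fdr`, `n`, `covariates`.
#' @export
textureVolumeRegression <- function(table, manifest, includeGroup = FALSE,
                                    regions = NULL) {
  vol <- .measureFrame(table, manifest, "volume")
  tex <- .measureFrame(table, manifest, "autocorrelation")
  both <- merge(vol[, c("subject_id", "region_id", "value", "group",
                        "age", "sex")],
                tex[, c("subject_id", "region_id", "value")],
                by = c("subject_id", "region_id"),
                suffixes = c("_volume", "_texture"))
  if (is.null(regions)) regions <- sort(unique(both$region_id))
  rows <- list()
  for (rid in regions) {
    df <- both[both$region_id == rid, , drop = FALSE]
    if (nrow(df) < 4L) next
    form <- value_volume ~ value_texture + age
    if (length(unique(df$sex)) > 1L)
      form <- stats::update(form, . ~ . + sex)
    if (includeGroup && length(unique(df$group)) > 1L)
      form <- stats::update(form, . ~ . + group)
    fit <- stats::lm(form, data = df)
    cf <- summary(fit)$coefficients
    if (!"value_texture" %in% rownames(cf) ||
        anyNA(stats::coef(fit))) {
      warning("collinear design in region ", rid, ": skipped")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = rid, beta_texture = cf["value_texture", 1],
      se = cf["value_texture", 2], p = cf["value_texture", 4],
      n = nrow(df),
      covariates = paste(c("age", "sex",
                           if (includeGroup) "group"), collapse = "+"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(region_id = integer(), beta_texture = numeric(),
                      se = numeric(), p = numeric(), p_fdr = numeric(),
                      n = integer(), covariates = character()))
  res <- do.call(rbind, rows)
  res$p_fdr <- fdrAdjust(res$p)$p_adjusted
  res[, c("region_id", "beta_texture", "se", "p", "p_fdr", "n",
          "covariates")]
}

#' Demographic and clinical comparisons between two groups
#'
#' Continuous variables are compared with the Wilcoxon rank-sum test
#' (normal approximation with tie correction); categorical variables with
#' Fisher's exact test for 2 x 2 tables and the chi-squared test for
#' larger tables. All p-values are two-sided.
#'
#' @param manifest subject manifest.
#' @param groups character(2), the two groups compared.
#' @param continuous named list of extra continuous score vectors aligned
#'   with the manifest rows (age is always tested).
#' @param categorical character vector of manifest column names treated as
#'   categorical (sex is always tested).
#' @return data.frame with `variable`, `test`, `statistic`, `p`.
#' @export
demographicsTests <- function(manifest, groups = c("HC", "mild"),
                              continuous = list(),
                              categorical = character()) {
  sel <- manifest$group %in% groups
  if (!all(groups %in% manifest$group))
    stop("both groups must be present in the manifest")
  m <- manifest[sel, , drop = FALSE]
  g <- factor(m$group, levels = groups)
  rows <- list()
  contVars <- c(list(age = m$age),
                lapply(continuous, function(v) v[sel]))
  for (nm in names(contVars)) {
    v <- contVars[[nm]]
    wt <- stats::wilcox.test(v[g == groups[1]], v[g == groups[2]],
                             exact = FALSE, correct = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = nm, test = "wilcoxon", statistic = unname(wt$statistic),
      p = wt$p.value, stringsAsFactors = FALSE)
  }
  catVars <- unique(c("sex", categorical))
  for (nm in catVars) {
    tab <- table(m[[nm]], droplevels(g))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, test = "degenerate", statistic = NA_real_, p = 1,
        stringsAsFactors = FALSE)
      next
    }
    if (nrow(tab) == 2L) {
      ft <- stats::fisher.test(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, test = "fisher", statistic = NA_real_,
        p = ft$p.value, stringsAsFactors = FALSE)
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, test = "chisq", statistic = unname(ct$statistic),
        p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
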