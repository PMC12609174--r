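# ANCOVA contrasts, FDR, effect sizes, z-scores, regressions, demographics.

test_that("BH adjustment matches the step-up definition and known cases", {
  r <- fdrAdjust(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$rejected))  # p(k) <= k * 0.05 / 4 for every k
  expect_equal(r$p_adjusted, c(0.04, 0.04, 0.04, 0.04))

  allOne <- fdrAdjust(rep(1, 7))
  expect_true(all(allOne$p_adjusted == 1))
  expect_false(any(allOne$rejected))

  single <- fdrAdjust(0.03)
  expect_equal(single$p_adjusted, 0.03)

  empty <- fdrAdjust(numeric(0))
  expect_length(empty$p_adjusted, 0)

  # oracle: random p-vectors against the brute-force definition
  set.seed(41)
  for (rep in 1:200) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    adj <- fdrAdjust(p)$p_adjusted
    expect_equal(adj, bruteBH(p))
    # monotone non-decreasing after sorting by raw p
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("contrasts reduce to raw mean differences without covariate signal", {
  set.seed(42)
  man <- statManifest(c(HC = 20, mild = 20, moderate = 20))
  man$age <- 60          # constant covariates
  man$sex <- "male"
  shift <- c(HC = 0, mild = -1, moderate = -2.5)
  ft <- statFeatureTable(man, regions = 1, groupShift = shift)
  ctr <- ancovaContrasts(ft, man, "volume")
  means <- tapply(ft$value, man$group[match(ft$subject_id, man$subject_id)],
                  mean)
  for (i in seq_len(nrow(ctr))) {
    expect_equal(ctr$difference[i],
                 unname(means[ctr$group_i[i]] - means[ctr$group_j[i]]),
                 tolerance = 1e-10)
  }
  # equivalent, via a plain t-test contrast on two groups
  tt <- t.test(ft$value[man$group == "HC"], ft$value[man$group == "mild"],
               var.equal = TRUE)
  expect_equal(ctr$difference[ctr$group_i == "HC" & ctr$group_j == "mild"],
               unname(diff(rev(tt$estimate))), tolerance = 1e-10)
})

test_that("adjusted differences and CIs agree with emmeans", {
  skip_if_not_installed("emmeans")
  set.seed(43)
  man <- statManifest()
  ft <- statFeatureTable(man, regions = 1,
                         groupShift = c(HC = 0, mild = -1, moderate = -2),
                         ageBeta = 0.05, sexBeta = 0.4)
  ctr <- ancovaContrasts(ft, man, "volume")
  df <- merge(ft, man, by = "subject_id")
  df$group <- factor(df$group, levels = c("HC", "mild", "moderate"))
  fit <- lm(value ~ group + age + sex, data = df)
  em <- as.data.frame(summary(emmeans::emmeans(fit, pairwise ~ group,
                                               adjust = "none")$contrasts,
                              infer = TRUE))
  # emmeans labels contrasts "HC - mild" etc in level order
  for (i in seq_len(nrow(ctr))) {
    lbl <- paste(ctr$group_i[i], "-", ctr$group_j[i])
    row <- em[em$contrast == lbl, ]
    expect_equal(ctr$difference[i], row$estimate, tolerance = 1e-8)
    expect_equal(ctr$ci_low[i], row$lower.CL, tolerance = 1e-8)
    expect_equal(ctr$ci_high[i], row$upper.CL, tolerance = 1e-8)
    expect_equal(ctr$p[i], row$p.value, tolerance = 1e-8)
  }
})

test_that("pairwise contrasts satisfy the transitivity identity", {
  set.seed(44)
  man <- statManifest()
  ft <- statFeatureTable(man, regions = 1:6,
                         groupShift = c(HC = 0, mild = -0.8, moderate = -1.7),
                         ageBeta = 0.02, sexBeta = -0.3)
  ctr <- ancovaContrasts(ft, man, "volume")
  for (rid in unique(ctr$region_id)) {
    cc <- ctr[ctr$region_id == rid, ]
    d <- function(i, j) cc$difference[cc$group_i == i & cc$group_j == j]
    expect_equal(d("HC", "moderate"), d("HC", "mild") + d("mild", "moderate"),
                 tolerance = 1e-12)
  }
})

test_that("CI coverage and type-I error are nominal at the study group sizes", {
  set.seed(45)
  nrep <- 300
  delta <- 1.2  # injected HC - mild difference
  cover <- logical(nrep); reject <- logical(nrep)
  for (r in seq_len(nrep)) {
    man <- statManifest()
    ftA <- statFeatureTable(man, regions = 1,
                            groupShift = c(HC = 0, mild = -delta,
                                           moderate = -delta),
                            ageBeta = 0.03)
    ftN <- statFeatureTable(man, regions = 1, ageBeta = 0.03)
    cA <- ancovaContrasts(ftA, man, "volume")
    cN <- ancovaContrasts(ftN, man, "volume")
    iA <- cA$group_i == "HC" & cA$group_j == "mild"
    iN <- cN$group_i == "HC" & cN$group_j == "mild"
    cover[r] <- cA$ci_low[iA] <= delta & delta <= cA$ci_high[iA]
    reject[r] <- cN$p[iN] <= 0.05
  }
  expect_gt(mean(cover), 0.91)
  expect_lt(mean(cover), 0.99)
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.09)
})

test_that("rank-deficient regions are skipped with a warning", {
  set.seed(46)
  man <- statManifest(c(HC = 5, mild = 5, moderate = 5))
  ft <- statFeatureTable(man, regions = 1)
  # make age perfectly collinear with group coding
  man$age <- c(HC = 1, mild = 2, moderate = 3)[man$group]
  expect_warning(ctr <- ancovaContrasts(ft, man, "volume"),
                 "rank-deficient")
  expect_equal(nrow(ctr), 0L)
})

test_that("effect sizes recover a known standardised difference and its map", {
  set.seed(47)
  man <- statManifest(c(HC = 200, mild = 200, moderate = 4))
  ft <- statFeatureTable(man, regions = 1,
                         groupShift = c(HC = 0, mild = -1, moderate = 0),
                         sd = 1, measure = "volume")
  ft2 <- ft; ft2$measure <- "autocorrelation"
  both <- rbind(ft, ft2)
  es <- effectSizes(both, man, contrast = c("HC", "mild"))
  expect_equal(es$effect_volume, 1, tolerance = 0.15)
  # identical feature passed as both measures: difference map is exactly 0
  expect_equal(es$effect_difference, 0)

  # null generator: effects centred on zero
  nullES <- replicate(30, {
    m <- statManifest(c(HC = 30, mild = 30, moderate = 4))
    f <- statFeatureTable(m, regions = 1)
    f2 <- f; f2$measure <- "autocorrelation"
    effectSizes(rbind(f, f2), m, c("HC", "mild"))$effect_volume
  })
  expect_lt(abs(mean(nullES)), 0.15)
})

test_that("z-scoring against controls self-standardises and tracks shifts", {
  set.seed(48)
  man <- statManifest(c(HC = 30, mild = 10, moderate = 4))
  ft <- statFeatureTable(man, regions = 1:2)
  z <- zscoreVsControls(ft, man)
  hcIds <- man$subject_id[man$group == "HC"]
  for (rid in 1:2) {
    zhc <- z$value[z$subject_id %in% hcIds & z$region_id == rid]
    expect_equal(mean(zhc), 0, tolerance = 1e-12)
    expect_equal(sd(zhc), 1, tolerance = 1e-12)
  }
  # a patient at the HC mean has z = 0
  ft2 <- ft
  hcMean <- mean(ft$value[ft$subject_id %in% hcIds & ft$region_id == 1])
  pid <- man$subject_id[man$group == "mild"][1]
  ft2$value[ft2$subject_id == pid & ft2$region_id == 1] <- hcMean
  z2 <- zscoreVsControls(ft2, man)
  expect_equal(z2$value[z2$subject_id == pid & z2$region_id == 1], 0,
               tolerance = 1e-12)
  # shifting patients only changes their z; shifting everyone does not
  ft3 <- ft
  pat <- !(ft3$subject_id %in% hcIds)
  ft3$value[pat] <- ft3$value[pat] + 5
  z3 <- zscoreVsControls(ft3, man)
  expect_false(isTRUE(all.equal(z3$value[pat], z$value[pat])))
  ft4 <- ft; ft4$value <- ft4$value + 5
  z4 <- zscoreVsControls(ft4, man)
  expect_equal(z4$value, z$value, tolerance = 1e-9)
})

test_that("texture-volume regression finds shared-cause slopes and group attenuation", {
  set.seed(49)
  man <- statManifest(c(HC = 40, mild = 40, moderate = 4))
  # disease drives both measures down: positive association across groups
  disease <- ifelse(man$group == "HC", 0, 1)
  vol <- 10 - 2 * disease + rnorm(nrow(man), sd = 0.5)
  tex <- 500 - 100 * disease + rnorm(nrow(man), sd = 25)
  ft <- rbind(data.frame(subject_id = man$subject_id, region_id = 1,
                         measure = "volume", value = vol),
              data.frame(subject_id = man$subject_id, region_id = 1,
                         measure = "autocorrelation", value = tex))
  rr <- textureVolumeRegression(ft, man)
  expect_gt(rr$beta_texture, 0)
  expect_lt(rr$p, 0.001)
  rrAdj <- textureVolumeRegression(ft, man, includeGroup = TRUE)
  expect_gt(rrAdj$p, 0.01)  # attenuated once group is adjusted for
  expect_lt(abs(rrAdj$beta_texture), abs(rr$beta_texture))

  # independent measures: slope near zero, FDR-null
  vol2 <- 10 + rnorm(nrow(man), sd = 0.5)
  ft$value[ft$measure == "volume"] <- vol2
  rr2 <- textureVolumeRegression(ft, man)
  expect_gt(rr2$p, 0.001)

  # texture passed identical to volume: slope exactly 1
  ft$value[ft$measure == "autocorrelation"] <-
    ft$value[ft$measure == "volume"]
  rr3 <- suppressWarnings(textureVolumeRegression(ft, man))
  expect_equal(rr3$beta_texture, 1, tolerance = 1e-9)
  expect_lt(rr3$p, 1e-12)
})

test_that("demographic tests match their base-R counterparts and edge cases", {
  man <- data.frame(
    subject_id = sprintf("S%02d", 1:20),
    group = rep(c("HC", "mild"), each = 10),
    age = c(rnorm(10, 60, 5), rnorm(10, 65, 5)),
    sex = rep(c("female", "male"), 10))
  dt <- demographicsTests(man, c("HC", "mild"))
  expect_setequal(dt$variable, c("age", "sex"))
  wt <- wilcox.test(man$age[man$group == "HC"], man$age[man$group == "mild"],
                    exact = FALSE)
  expect_equal(dt$p[dt$variable == "age"], wt$p.value)

  # identical continuous samples give p = 1
  man2 <- man; man2$age <- rep(1:10, 2)
  dt2 <- demographicsTests(man2, c("HC", "mild"))
  expect_equal(dt2$p[dt2$variable == "age"], 1)

  # perfectly imbalanced 2x2 table: exact hypergeometric two-sided p
  man3 <- man
  man3$sex <- c(rep("female", 10), rep("male", 10))
  dt3 <- demographicsTests(man3, c("HC", "mild"))
  expect_equal(dt3$p[dt3$variable == "sex"],
               fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value)
  # 5/0 vs 0/5 case computed by direct enumeration: 2 / C(10,5)
  m5 <- data.frame(subject_id = as.character(1:10),
                   group = rep(c("HC", "mild"), each = 5),
                   age = rnorm(10, 60),
                   sex = c(rep("female", 5), rep("male", 5)))
  d5 <- demographicsTests(m5, c("HC", "mild"))
  expect_equal(d5$p[d5$variable == "sex"], 2 / choose(10, 5),
               tolerance = 1e-12)

  # proportional table with equal margins: p = 1
  man4 <- man
  dt4 <- demographicsTests(man4, c("HC", "mild"))
  expect_equal(dt4$p[dt4$variable == "sex"], 1)

  expect_error(demographicsTests(man, c("HC", "moderate")), "present")
})
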