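# Independent brute-force oracles used across the suite. These stay
# deliberately naive (exhaustive enumeration / direct definitions) and
# share no code with the implementations they check.

# Exhaustive GLCM: enumerate every (voxel, offset) pair directly.
bruteGlcm <- function(levels, offsetMat, symmetric, L) {
  d <- dim(levels)
  counts <- matrix(0, L, L)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    for (r in seq_len(nrow(offsetMat))) {
      o <- offsetMat[r, ]
      x2 <- x + o[1]; y2 <- y + o[2]; z2 <- z + o[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
          z2 < 1 || z2 > d[3]) next
      b <- levels[x2, y2, z2]
      if (is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      if (symmetric) counts[b, a] <- counts[b, a] + 1
    }
  }
  n <- sum(counts)
  list(counts = counts, p = if (n > 0) counts / n else counts, nPairs = n)
}

bruteAutocorrelation <- function(p) {
  L <- nrow(p)
  s <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) s <- s + i * j * p[i, j]
  s
}

# Benjamini-Hochberg step-up by its definition: p_adj(k) = min over j >= k
# of m * p(j) / j (on the sorted scale), capped at 1.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    adj[k] <- min(1, min(m * ps[k:m] / (k:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# AUC by counting positive/negative pairs, ties worth 1/2.
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden scan over all distinct thresholds (score >= t positive).
bruteYouden <- function(scores, labels) {
  cand <- c(sort(unique(scores)), max(scores) + 1)
  best <- list(J = -Inf, sens = -Inf)
  for (t in cand) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    J <- sens + spec - 1
    if (J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 && sens > best$sens))
      best <- list(J = J, sens = sens, spec = spec, threshold = t)
  }
  best
}

# Small random masked level grid for fuzzing.
randomLevelGrid <- function(dmax = 6L, L = 8L, maskProb = 0.7) {
  d <- sample(2:dmax, 3, replace = TRUE)
  g <- array(sample.int(L, prod(d), replace = TRUE), dim = d)
  mask <- array(runif(prod(d)) < maskProb, dim = d)
  g[!mask] <- NA_integer_
  g
}

# A tiny cohort configuration that keeps imaging tests fast.
tinyConfig <- function(...) {
  args <- list(gridShape = c(20L, 20L, 20L), nRegions = 2L,
               groupSizes = c(HC = 3L, mild = 3L, moderate = 3L),
               smoothFwhmMm = 2, seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(syntheticConfig, args)
}

# Directly synthesised feature tables (no imaging) for the statistics
# modules: per-region Gaussian values with optional group shifts.
statFeatureTable <- function(manifest, regions = 1:3,
                             groupShift = c(HC = 0, mild = 0, moderate = 0),
                             measure = "volume", sd = 1,
                             ageBeta = 0, sexBeta = 0, baseline = 10) {
  rows <- do.call(rbind, lapply(regions, function(rid) {
    data.frame(subject_id = manifest$subject_id, region_id = rid,
               measure = measure,
               value = baseline + groupShift[manifest$group] +
                 ageBeta * manifest$age +
                 sexBeta * (manifest$sex == "female") +
                 rnorm(nrow(manifest), sd = sd),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

# Manifest with the reference group sizes (or any given ones).
statManifest <- function(n = c(HC = 33, mild = 21, moderate = 11)) {
  groups <- rep(names(n), times = n)
  data.frame(subject_id = sprintf("S%03d", seq_along(groups)),
             group = groups,
             age = round(rnorm(length(groups), 63, 8), 1),
             sex = ifelse(runif(length(groups)) < 0.3, "female", "male"),
             stringsAsFactors = FALSE)
}
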