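test_that("fixed-effects meta-analysis closed forms", {
  # single stratum: identity
  m1 <- metaFixedEffects(0.27, 0.01)
  expect_equal(m1$beta, 0.27)
  expect_equal(m1$se, 0.01)
  # identical strata: se shrinks by 1/sqrt(k)
  m2 <- metaFixedEffects(c(0.2, 0.2), c(0.1, 0.1))
  expect_equal(m2$beta, 0.2, tolerance = 1e-12)
  expect_equal(m2$se, 0.1 / sqrt(2), tolerance = 1e-12)
  m5 <- metaFixedEffects(rep(0.2, 5), rep(0.1, 5))
  expect_equal(m5$se, 0.1 / sqrt(5), tolerance = 1e-12)
  # two-stratum hand computation: w = (100, 25)
  m <- metaFixedEffects(c(0.1, 0.3), c(0.1, 0.2))
  expect_equal(m$beta, 0.14, tolerance = 1e-12)
  expect_equal(m$se, sqrt(1 / 125), tolerance = 1e-12)
  expect_error(metaFixedEffects(numeric()), "no estimable")
  expect_error(metaFixedEffects(c(0.1, 0.2), c(0.1, 0)), "positive")
})

test_that("Cochran's Q hand computation and degenerate cases", {
  q <- cochranQ(c(0.1, 0.3), c(0.1, 0.2))
  expect_equal(q$q, 0.80, tolerance = 1e-12)
  expect_equal(q$df, 1L)
  expect_equal(q$p, pchisq(0.80, 1, lower.tail = FALSE))
  same <- cochranQ(c(0.2, 0.2, 0.2), c(0.1, 0.1, 0.1))
  expect_equal(same$q, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  one <- cochranQ(0.2, 0.1)
  expect_true(is.na(one$q) && is.na(one$p))
})

test_that("meta estimate is a convex combination of stratum estimates", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    b <- rnorm(k); s <- runif(k, 0.01, 1)
    m <- metaFixedEffects(b, s)
    expect_gte(m$beta, min(b))
    expect_lte(m$beta, max(b))
  }
})

test_that("meta-analysis and Q agree with an independent implementation", {
  skip_if_not_installed("metafor")
  set.seed(22)
  b <- rnorm(4, 0.2, 0.1); s <- runif(4, 0.05, 0.3)
  m <- metaFixedEffects(b, s)
  q <- cochranQ(b, s)
  ref <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(m$beta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(m$se, as.numeric(ref$se), tolerance = 1e-10)
  expect_equal(q$q, as.numeric(ref$QE), tolerance = 1e-10)
  expect_equal(q$p, as.numeric(ref$QEp), tolerance = 1e-10)
})

test_that("significance tiers split at the published thresholds", {
  expect_equal(classifySignificance(1e-9), "genome_wide")
  expect_equal(classifySignificance(9e-6), "experiment_wide")
  expect_equal(classifySignificance(0.005), "replication")
  expect_equal(classifySignificance(0.00625), "none")
  expect_equal(classifySignificance(0.01), "none")
  expect_equal(classifySignificance(c(5e-8, 1e-5)),
               c("experiment_wide", "replication"))
  expect_error(classifySignificance(0), "\\(0, 1\\]")
  expect_error(classifySignificance(1.5), "\\(0, 1\\]")
})

test_that("single-SNP fits recover planted effects and flag degeneracy", {
  set.seed(5)
  n <- 4000
  d <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.8 + log(1.5) * d))
  fit <- fitSnpModel(d, y, rsid = "rsX", stratum = "EU")
  expect_true(fit$estimable)
  expect_lt(abs(fit$beta - log(1.5)), 3 * fit$se)
  expect_equal(fit$or_, exp(fit$beta))
  expect_equal(fit$n_cases + fit$n_controls, n)
  # Wald p consistent with beta/se
  expect_equal(fit$p, 2 * pnorm(-abs(fit$beta / fit$se)))

  # continuous outcome takes the least-squares path
  yc <- 2 + 0.5 * d + rnorm(n)
  fitc <- fitSnpModel(d, yc)
  expect_lt(abs(fitc$beta - 0.5), 3 * fitc$se)
  expect_true(is.na(fitc$or_))
  refc <- lm(yc ~ d)
  expect_equal(fitc$beta, unname(coef(refc)["d"]), tolerance = 1e-10)

  # degenerate designs are flagged, not errored
  expect_false(fitSnpModel(rep(1, n), y)$estimable)
  expect_false(fitSnpModel(d, rep(1L, n))$estimable)
  sep <- fitSnpModel(c(rep(0, 50), rep(2, 50)),
                     c(rep(0L, 50), rep(1L, 50)))
  expect_false(sep$estimable)
})

test_that("covariate adjustment leaves a null covariate's SNP effect alone", {
  set.seed(9)
  n <- 5000
  parts <- data.frame(id = sprintf("p%d", 1:n),
                      sex = sample(c("male", "female"), n, TRUE),
                      age_at_enrollment = runif(n, 30, 90),
                      ancestry = "EU",
                      matrix(rnorm(n * 10), n, 10,
                             dimnames = list(NULL, paste0("PC", 1:10))),
                      audit_c = sample(0:12, n, TRUE))
  d <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.8 + log(1.4) * d))
  f1 <- fitSnpModel(d, y, modelCovariates(parts, model = 1))
  f2 <- fitSnpModel(d, y, modelCovariates(parts, model = 2))
  expect_lt(abs(f1$beta - f2$beta), 2 * f1$se)
  expect_error(modelCovariates(parts, model = 3), "metabolic")
})

test_that("homogeneous strata: meta agrees with a pooled fit", {
  set.seed(14)
  n <- 3000
  anc <- rep(c("EU", "AA", "LA"), each = n)
  d <- rbinom(3 * n, 2, 0.3)
  y <- rbinom(3 * n, 1, plogis(-0.8 + 0.3 * d))
  fits <- do.call(rbind, lapply(unique(anc), function(a)
    fitSnpModel(d[anc == a], y[anc == a], stratum = a)))
  m <- metaFixedEffects(fits)
  pooled <- fitSnpModel(d, y, data.frame(
    s1 = as.integer(anc == "AA"), s2 = as.integer(anc == "LA")))
  expect_lt(abs(m$beta - pooled$beta), 2 * m$se)
})

test_that("ancestry-stratified association table is complete and annotated", {
  sc <- simulateCohort(simConfig(n = 900, seed = 55))
  calls <- classifyCohort(participants(sc), labs(sc), codes(sc), meds(sc))
  outcome <- ifelse(calls$stratum == "case", 1L,
             ifelse(calls$stratum == "control", 0L, NA_integer_))
  res <- associateVariants(genotypes(sc), outcome, participants(sc),
                           model = 1)
  expect_equal(sort(unique(res$strata$stratum)), c("AA", "EU", "LA"))
  expect_equal(nrow(res$meta), nrow(nafldVariantPanel()))
  expect_true(all(c("rsid", "eaf", "or_", "p", "q", "het_p", "tier") %in%
                    names(res$meta)))
  est <- res$meta
  expect_true(all(est$ci_lo < est$or_ & est$or_ < est$ci_hi))
  # combined estimate lies within the per-stratum range (convexity)
  for (v in est$rsid[1:4]) {
    sub <- res$strata[res$strata$rsid == v & res$strata$estimable, ]
    if (nrow(sub) >= 2) {
      expect_gte(est$beta[est$rsid == v], min(sub$beta))
      expect_lte(est$beta[est$rsid == v], max(sub$beta))
    }
  }
})
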