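test_that("cohort parameters are validated", {
  expect_error(cohortParams(thresholds = c(0.5, 0.4, 0.9)), "increasing")
  expect_error(cohortParams(doseAlpha = 0), "positive")
  expect_error(cohortParams(selection = "nope"), "not in loci")
  expect_error(simulateCohort(list()), "cohortParams")
})

test_that("zero slope collapses every embryo onto the link intercept", {
  loci <- data.frame(locus = c("tyr", "nras"), intercept = c(0.5, -1),
                     slope = c(0, 0))
  coh <- simulateCohort(cohortParams(nEmbryos = 40, loci = loci,
                                     dispersion = Inf, seed = 5))
  f <- editFractions(coh)
  expect_true(all(abs(f[, "tyr"] - plogis(0.5)) < 1e-12))
  expect_true(all(abs(f[, "nras"] - plogis(-1)) < 1e-12))
  expect_identical(length(unique(as.character(cohortGroups(coh)))), 1L)
})

test_that("shared dose induces positive inter-locus correlation,
          independent mode breaks it", {
  p_shared <- cohortParams(nEmbryos = 500, mode = "shared-dose", seed = 9)
  coh <- simulateCohort(p_shared)
  f <- editFractions(coh)
  expect_gt(cor(f[, "tyr"], f[, "nras"], method = "spearman"), 0.3)

  p_ind <- cohortParams(nEmbryos = 500, mode = "independent", seed = 9)
  f2 <- editFractions(simulateCohort(p_ind))
  expect_lt(abs(cor(f2[, "tyr"], f2[, "nras"], method = "spearman")),
            3 / sqrt(500))
})

test_that("group summaries report occupied groups and an overall mean", {
  # worked fixture: mildly depigmented pool at 41%, albino pool at 95%
  obs <- data.frame(group = c("mild", "albino"), locus = "tyr",
                    edit_fraction = c(0.41, 0.95))
  s <- groupSummary(obs)
  expect_equal(s$mean_pct[s$group == "mild"], 41)
  expect_equal(s$mean_pct[s$group == "albino"], 95)
  expect_false("severe" %in% s$group[s$locus == "tyr" &
                                       s$group != "overall"])
  expect_equal(s$mean_pct[s$group == "overall"], 68)

  # uniform fractions give 50% everywhere
  u <- data.frame(group = rep(c("mild", "severe"), 5), locus = "x",
                  edit_fraction = 0.5)
  expect_true(all(groupSummary(u)$mean_pct == 50))
  expect_error(groupSummary(obs[0, ]), "empty")
})

test_that("a perfectly monotone cohort has trend statistic 1", {
  f <- matrix(rep(c(0.1, 0.3, 0.65, 0.95), each = 5), ncol = 1,
              dimnames = list(NULL, "tyr"))
  f <- cbind(f, nras = f[, 1])
  coh <- new("Cohort",
             embryos = data.frame(
               embryo_id = sprintf("e%02d", 1:20), dose = NA_real_,
               group = factor(rep(c("wt-like", "mild", "severe", "albino"),
                                  each = 5),
                              levels = c("wt-like", "mild", "severe",
                                         "albino"), ordered = TRUE)),
             fractions = f, selection = "tyr",
             thresholds = c(0.25, 0.6, 0.9))
  res <- trendTest(coh, "nras", n_perm = 199, seed = 1)
  expect_equal(res$statistic, 1.0)
  expect_lte(res$p_value, 0.01)
})

test_that("exact permutation p equals independent exhaustive enumeration", {
  set.seed(33)
  for (k in 1:3) {
    frac <- round(runif(8), 3)
    sel <- sort(runif(8))
    f <- cbind(tyr = sel, nras = frac)
    grp <- cut(sel, c(-Inf, 0.25, 0.6, 0.9, Inf),
               labels = c("wt-like", "mild", "severe", "albino"))
    coh <- new("Cohort",
               embryos = data.frame(embryo_id = sprintf("e%d", 1:8),
                                    dose = NA_real_,
                                    group = factor(as.character(grp),
                                                   levels = levels(grp),
                                                   ordered = TRUE)),
               fractions = f, selection = "tyr",
               thresholds = c(0.25, 0.6, 0.9))
    if (length(unique(as.integer(coh@embryos$group))) < 2) next
    res <- trendTest(coh, "nras", exact = TRUE)
    expect_equal(res$p_value,
                 oracle_exact_perm_p(as.integer(coh@embryos$group), frac))
  }
})

test_that("degenerate cohorts are rejected by the trend test", {
  f <- cbind(tyr = rep(0.5, 6), nras = rep(0.5, 6))
  coh <- new("Cohort",
             embryos = data.frame(embryo_id = sprintf("e%d", 1:6),
                                  dose = NA_real_,
                                  group = factor(rep("mild", 6),
                                                 levels = c("wt-like",
                                                            "mild",
                                                            "severe",
                                                            "albino"),
                                                 ordered = TRUE)),
             fractions = f, selection = "tyr",
             thresholds = c(0.05, 0.6, 0.9))
  expect_error(trendTest(coh, "nras"), "2 occupied groups|tied")
})

test_that("germline proportions print the founder-cross arithmetic", {
  g1 <- germlineProportion(28, 54)
  expect_equal(g1$percent, 51.9)
  g2 <- germlineProportion(47, 92)
  expect_equal(g2$percent, 51.1)
  g0 <- germlineProportion(0, 10)
  expect_equal(g0$percent, 0)
  expect_equal(g0$lower, 0)
  # Clopper-Pearson agrees with binom.test
  ci <- 100 * as.numeric(binom.test(28, 54)$conf.int)
  expect_equal(c(g1$lower, g1$upper), ci)
  expect_error(germlineProportion(5, 4), "exceed")
  expect_error(germlineProportion(1, 0), ">= 1")
  expect_output(print(g1), "51.9")
})

test_that("cohort TSV round-trips", {
  coh <- simulateCohort(cohortParams(nEmbryos = 30, seed = 21))
  f <- tempfile(fileext = ".tsv")
  writeCohortTsv(coh, f)
  back <- readCohortTsv(f, selection = "tyr")
  expect_equal(editFractions(back)[, "tyr"],
               unname(editFractions(coh)[, "tyr"]))
  expect_identical(as.character(cohortGroups(back)),
                   as.character(cohortGroups(coh)))
})
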