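test_that("robust effect size saturates at 1 on exact relations and flags degeneracy", {
  z <- seq(-2, 2, length.out = 30)
  expect_equal(robustEffectSize(z, 3 * z + 1)$es, 1)
  expect_equal(robustEffectSize(z, -2 * z)$es, -1)
  d <- robustEffectSize(rep(1, 30), rnorm(30))
  expect_true(d$degenerate)
  expect_true(is.na(d$es))
})

test_that("the MM effect size resists contamination that wrecks Pearson", {
  for (s in c(101, 202, 303)) {
    withr::with_seed(s, {
      n <- 200
      x <- rnorm(n)
      y <- 0.5 * x + sqrt(0.75) * rnorm(n)
      xc <- x; yc <- y
      bad <- sample(n, n / 10)
      flip <- sample(c(-1, 1), n / 10, replace = TRUE)
      xc[bad] <- 10 * flip; yc[bad] <- -10 * flip
    })
    es_clean <- robustEffectSize(x, y)$es
    es_cont <- robustEffectSize(xc, yc)$es
    expect_lt(abs(es_clean - es_cont), 0.15)
    expect_gt(abs(cor(x, y) - cor(xc, yc)), 0.3)
  }
})

test_that("the effect size is deterministic under the configured seed", {
  withr::with_seed(1, {
    x <- rnorm(80); y <- 0.4 * x + rnorm(80)
  })
  e1 <- robustEffectSize(x, y, mmConfig(seed = 3))
  e2 <- robustEffectSize(x, y, mmConfig(seed = 3))
  expect_identical(e1$es, e2$es)
})

test_that("contribution profiles surface the driving feature and stay flat under the null", {
  withr::with_seed(12, {
    n <- 200; p <- 12
    z <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("feat%02d", 1:p)))
    pad_driven <- 6 * z[, 5] + rnorm(n, 0, 2)
    prof <- contributionProfile(z, pad_driven, "driven")
    expect_equal(prof$feature[which.max(abs(prof$es))], "feat05")

    pad_null <- rnorm(n, 0, 7)
    prof0 <- contributionProfile(z, pad_null, "null")
    expect_true(all(abs(prof0$es) < 0.2))
  })
  one <- contributionProfile(matrix(rnorm(50), 50, 1,
                                    dimnames = list(NULL, "only")),
                             rnorm(50), "g")
  expect_equal(nrow(one), 1L)
  expect_error(contributionProfile(matrix(rnorm(20), 10, 2,
                                          dimnames = list(NULL, c("a", "b"))),
                                   rnorm(9), "g"), "aligned")
})

test_that("ranking orders by |ES| with lexicographic tie-breaks", {
  prof <- data.frame(feature = c("b", "a", "c", "d"),
                     es = c(0.5, -0.5, 0.9, 0.1))
  expect_equal(rankTop(prof, 2), c("c", "a"))  # tie 0.5: 'a' before 'b'
  expect_equal(rankTop(prof, 3), c("c", "a", "b"))
  expect_equal(rankTop(prof, 99), c("c", "a", "b", "d"))
})

test_that("delta-ES reproduces published worked examples and is antisymmetric", {
  mk <- function(es) data.frame(feature = names(es), es = unname(es))
  msa <- mk(c("Vol R Lat OrbFron Gy" = 0.527, "MD CC Parie" = 0.683,
              "CT R Inf Parie Gy" = 0.501, "GFA R UF" = 0.109))
  pd <- mk(c("Vol R Lat OrbFron Gy" = 0.106, "MD CC Parie" = 0.277,
             "CT R Inf Parie Gy" = 0.068, "GFA R UF" = 0.617))
  hc <- mk(c("Vol R Lat OrbFron Gy" = 0.496, "MD CC Parie" = 0.502,
             "CT R Inf Parie Gy" = 0.365, "GFA R UF" = 0.008))
  d <- deltaEffectSize(msa, pd, hc)
  expect_equal(d$delta_es[d$feature == "Vol R Lat OrbFron Gy"], 0.421)
  expect_equal(d$delta_es[d$feature == "MD CC Parie"], 0.406)
  expect_equal(d$delta_es[d$feature == "CT R Inf Parie Gy"], 0.433)
  expect_equal(d$delta_es[d$feature == "GFA R UF"], -0.507,
               tolerance = 0.002)
  expect_true(all(d$selected))

  flipped <- deltaEffectSize(pd, msa, hc)
  expect_equal(flipped$delta_es, -d$delta_es)
  expect_equal(flipped$selected, d$selected)

  same <- deltaEffectSize(mk(c(x = 0.5)), mk(c(x = 0.5)))
  expect_equal(same$delta_es, 0)
  expect_false(same$selected)
  expect_error(deltaEffectSize(msa, mk(c(other = 1))), "feature set")
})

test_that("regional aggregation yields percentages that sum to 100", {
  desc <- data.frame(
    name = sprintf("f%d", 1:8),
    modality = "GM_volume",
    region_group = rep(c("frontal", "parietal", "temporal", "occipital"),
                       each = 2),
    hemisphere = rep(c("left", "right"), 4))
  prof <- data.frame(feature = desc$name, es = rep(0.4, 8))
  agg <- aggregateByRegion(prof, desc)
  expect_equal(agg$percent, rep(25, 4))

  prof2 <- data.frame(feature = desc$name, es = c(0.7, rep(0, 7)))
  agg2 <- aggregateByRegion(prof2, desc)
  expect_equal(agg2$percent[agg2$region_group == "frontal"], 100)

  # hand-summed toy: |es| by lobe = (0.3, 0.5, 0.8, 0.4), total 2.0
  prof3 <- data.frame(feature = desc$name,
                      es = c(0.1, -0.2, 0.25, 0.25, -0.8, 0, 0.1, 0.3))
  agg3 <- aggregateByRegion(prof3, desc)
  expect_equal(agg3$percent[match(c("frontal", "parietal", "temporal",
                                    "occipital"), agg3$region_group)],
               c(15, 25, 40, 20))
  expect_equal(sum(agg3$percent), 100)

  expect_error(aggregateByRegion(data.frame(feature = desc$name, es = 0),
                                 desc), "zero")
})

test_that("features that truly drive the offset outrank the rest", {
  withr::with_seed(21, {
    n <- 200; p <- 40
    z <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%02d", 1:p)))
    S <- 1:8
    pad <- rowSums(z[, S]) + rnorm(n, 0, 2)
  })
  prof <- contributionProfile(z, pad, "sim")
  ranks <- rank(-abs(prof$es))
  wt <- wilcox.test(ranks[S], ranks[-S], alternative = "less")
  expect_lt(wt$p.value, 0.01)
})
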