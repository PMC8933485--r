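test_that("W matches exact rank arithmetic and the tie convention", {
  # disjoint samples: U = 0, mean 4.5, sd sqrt(5.25) -> 1.964 (3 decimals)
  r <- wilcoxon_W(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(r$W, 3), 1.964)
  expect_equal(r$n_a, 3); expect_equal(r$n_b, 3)
  # fully tied samples
  expect_equal(wilcoxon_W(c(5, 5, 5, 5), c(5, 5, 5, 5))$W, 0)
  expect_error(wilcoxon_W(1, c(1, 2)), ">= 2")
})

test_that("W is rank-based: monotone-transform and swap invariant", {
  set.seed(20)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(7, mean = runif(1, -1, 1))
    w <- wilcoxon_W(a, b)$W
    expect_equal(wilcoxon_W(b, a)$W, w, tolerance = 1e-12)
    expect_equal(wilcoxon_W(exp(a), exp(b))$W, w, tolerance = 1e-12)
    expect_equal(wilcoxon_W(a * 100 + 3, b * 100 + 3)$W, w,
                 tolerance = 1e-12)
  }
})

# Synthetic feature tables -------------------------------------------------

fake_table <- function(gen, n_groups = 8, n_reps = 10,
                       features = c("firstorder_Mean",
                                    "firstorder_Variance")) {
  rois <- data.frame(
    roi = c("liver_1", "liver_2", "cyst_1", "cyst_2", "hemangioma",
            "metastasis"),
    tissue_class = c("normal_liver", "normal_liver", "cyst", "cyst",
                     "hemangioma", "metastasis"))
  rows <- expand.grid(rep = seq_len(n_reps), group = seq_len(n_groups),
                      idx = seq_len(nrow(rois)))
  out <- data.frame(group = rows$group, roi = rois$roi[rows$idx],
                    tissue_class = rois$tissue_class[rows$idx])
  for (f in features) out[[f]] <- gen(out, f)
  out
}

test_that("identically distributed groups look stable, not discriminative", {
  # under the null, W = |z| exceeds 1 with probability ~ 0.32, so the
  # expected null rates are ~68% stable and ~32% discriminative
  set.seed(21)
  tab <- fake_table(function(df, f) rnorm(nrow(df)),
                    features = feature_names()[1:10])
  st <- stability_percentage(tab)
  di <- discriminative_percentage(tab)
  expect_equal(attr(st, "n_comparisons"), choose(8, 2) * 6)   # 168
  expect_equal(attr(di, "n_comparisons"), choose(4, 2) * 8)   # 48
  expect_gt(mean(st), 55)
  expect_lt(mean(di), 45)
  expect_gt(mean(st) - mean(di), 20)
})

test_that("separated group means give near-zero stability; separated classes 100% discrimination", {
  set.seed(22)
  # group means far apart relative to within-group spread
  tab <- fake_table(function(df, f) df$group * 100 + rnorm(nrow(df), sd = 0.1))
  st <- stability_percentage(tab)
  expect_lt(mean(st), 5)
  # classes with disjoint supports
  cls_lvl <- c(normal_liver = 0, cyst = 1000, hemangioma = 2000,
               metastasis = 3000)
  tab2 <- fake_table(function(df, f)
    cls_lvl[df$tissue_class] + runif(nrow(df)))
  di <- discriminative_percentage(tab2)
  expect_equal(unname(mean(di)), 100)
})

test_that("constant tables are 100% stable (W = 0 everywhere)", {
  tab <- fake_table(function(df, f) rep(1, nrow(df)))
  expect_equal(unname(mean(stability_percentage(tab))), 100)
  expect_equal(unname(mean(discriminative_percentage(tab))), 0)
})

test_that("rankings order by percentage with canonical tie-break", {
  tab <- data.frame(feature = c("glcm_Contrast", "firstorder_Mean",
                                "firstorder_Energy"),
                    stability = c(50, 50, 50),
                    discriminative = c(0, 100, 0))
  rep <- structure(list(table = tab), class = "stability_report")
  expect_equal(rank_features(rep, "stability"),
               c("firstorder_Energy", "firstorder_Mean", "glcm_Contrast"))
  expect_equal(rank_features(rep, "discriminative")[1], "firstorder_Mean")
})

test_that("top-k overlap uses round-half-up and the identity gives 100%", {
  u <- feature_names()
  ov <- topk_overlap(u, u, fractions = c(0.10, 0.5, 1))
  expect_equal(ov$k, c(9L, 43L, 86L))     # 10% of 86 -> top 9
  expect_true(all(ov$overlap_pct == 100))
  expect_equal(ov$baseline_pct, c(10, 50, 100))
  expect_error(topk_overlap(u, u[-1]), "universe")
})

test_that("independent random rankings overlap near the baseline", {
  set.seed(23)
  u <- feature_names()
  ovs <- replicate(400, topk_overlap(sample(u), sample(u),
                                     fractions = 0.5)$overlap_pct)
  expect_lt(abs(mean(ovs) - 50), 2)
})
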