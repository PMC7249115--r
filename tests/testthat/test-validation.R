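test_that("the one-way decomposition matches its forced cases", {
  # identical values everywhere: no between- or within-group variation
  a <- one_way_anova(list(rep(0.5, 4), rep(0.5, 5), rep(0.5, 3)))
  expect_equal(a$ss[1], 0)
  expect_equal(a$ss[2], 0)

  # {0,0} vs {1,1}: all variation is between groups;
  # SS_classes = 2*(0-1/2)^2 + 2*(1-1/2)^2 = 1
  b <- one_way_anova(list(c(0, 0), c(1, 1)))
  expect_equal(b$ss[1], 1)
  expect_equal(b$ss[2], 0)
  expect_equal(b$f[1], Inf)
  expect_equal(b$p[1], 0)
  expect_equal(b$df, c(1, 2, 3))

  expect_error(one_way_anova(list(c(1, 2))), class = "rarefynet_input_error")
  expect_error(one_way_anova(list(numeric(0), c(1, 2))),
               class = "rarefynet_input_error")
})

test_that("the decomposition agrees with the definitional oracle and aov", {
  set.seed(20)
  for (i in 1:10) {
    groups <- lapply(1:3, function(j) rnorm(sample(5:30, 1), mean = j / 10,
                                            sd = 0.2))
    a <- one_way_anova(groups)
    o <- anova_two_pass(groups)
    expect_equal(a$ss[1:2], o$ss, tolerance = 1e-10)
    expect_equal(a$ms[1:2], o$ms, tolerance = 1e-10)
    expect_equal(a$f[1], o$f, tolerance = 1e-10)
    # cross-check against the built-in linear-model ANOVA
    d <- data.frame(y = unlist(groups),
                    g = factor(rep(seq_along(groups), lengths(groups))))
    av <- anova(lm(y ~ g, data = d))
    expect_equal(a$ss[1:2], av$`Sum Sq`, tolerance = 1e-10)
    expect_equal(a$f[1], av$`F value`[1], tolerance = 1e-10)
    expect_equal(a$p[1], av$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("ANOVA invariances: shifts cancel, scales enter as squares", {
  set.seed(4)
  groups <- lapply(1:3, function(j) rnorm(12, j / 5, 0.1))
  a <- one_way_anova(groups)
  shifted <- one_way_anova(lapply(groups, `+`, 10))
  expect_equal(a$ss, shifted$ss, tolerance = 1e-8)
  expect_equal(a$f[1], shifted$f[1], tolerance = 1e-8)
  scaled <- one_way_anova(lapply(groups, `*`, 3))
  expect_equal(scaled$ss, 9 * a$ss, tolerance = 1e-10)
  expect_equal(scaled$f[1], a$f[1], tolerance = 1e-10)
})

test_that("F p-values hit the published validation table", {
  expect_equal(f_pvalue(3.4582, 2, 31), 0.0441, tolerance = 0.0005 / 0.0441)
  expect_equal(f_pvalue(22.9984, 2, 63), 3.2e-8, tolerance = 0.1)
  expect_equal(f_pvalue(0, 2, 31), 1)
  expect_equal(f_pvalue(Inf, 2, 31), 0)
  # strictly decreasing in F for fixed DFs
  fs <- seq(0, 40, by = 0.5)
  ps <- f_pvalue(fs, 2, 31)
  expect_true(all(diff(ps) < 0))
  expect_error(f_pvalue(-1, 2, 31), class = "rarefynet_input_error")
})

test_that("Pearson correlation follows its definition", {
  x <- runif(10)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 7)), 0.99339927, tolerance = 1e-7)
  expect_error(pearson(rep(1, 5), runif(5)), class = "rarefynet_input_error")
  expect_error(pearson(1:3, 1:4), class = "rarefynet_input_error")
})

test_that("the refinement report is consistent and deterministic", {
  sc <- generate_scene(tiny_scene_config(seed = 3))
  uav <- downsample_uav_reference(sc)
  raw <- downsample_satellite_raw(sc)
  vm <- vigor_truth_map(sc)
  rep1 <- evaluate_refinement(raw, uav, uav, vm)
  # a perfect refinement: zero error, perfect correlation, and its ANOVA
  # equals the reference's
  expect_equal(rep1$metrics$rmse[rep1$metrics$dataset == "refined"], 0)
  expect_equal(rep1$metrics$pearson[rep1$metrics$dataset == "refined"], 1)
  expect_equal(rep1$anova$refined, rep1$anova$reference)
  # raw == refined gives identical rows
  rep2 <- evaluate_refinement(raw, raw, uav, vm)
  expect_equal(rep2$metrics$rmse[1], rep2$metrics$rmse[2])
  # bit-for-bit reproducible
  rep3 <- evaluate_refinement(raw, raw, uav, vm)
  expect_identical(rep2, rep3)
  expect_error(evaluate_refinement(raw, uav, random_map(3, 3), vm),
               class = "rarefynet_input_error")

  d <- withr::local_tempdir()
  write_report(rep1, d)
  expect_true(file.exists(file.path(d, "metrics.csv")))
  expect_true(file.exists(file.path(d, "anova_refined.csv")))
})
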