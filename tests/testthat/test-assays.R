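test_that("Miller units follow the assay formula and its symmetries", {
  rec <- miller_record(0.9, 0.2, 0.5, 30, 0.1)
  expect_equal(miller_units(rec), 1000 * (0.9 - 1.75 * 0.2) / (30 * 0.1 * 0.5))
  expect_equal(miller_units(rec), 366.67, tolerance = 1e-4)
  # vanishing numerator
  expect_equal(miller_units(miller_record(1.75 * 0.2, 0.2, 0.5, 30, 0.1)), 0)
  # linearity in 1/v
  rec2 <- miller_record(0.9, 0.2, 0.5, 30, 0.2)
  expect_equal(miller_units(rec2), miller_units(rec) / 2)
  expect_error(miller_record(1, 0.2, 0, 30, 0.1), "od600")
  expect_error(miller_record(1, 0.2, 0.5, 0, 0.1), "t_reaction")
})

test_that("blank screening excludes outliers in a single pass", {
  blanks <- c(rep(15, 9), 40)
  bs <- blank_statistics(blanks)
  expect_equal(bs$n_used, 9L)
  expect_equal(bs$n_excluded, 1L)
  expect_equal(bs$mean_blank, 15)
  expect_equal(bs$sd_blank, 0)
})

test_that("unremarkable blank sets keep plain mean and SD", {
  blanks <- c(14, 15, 16, 17, 15.5)
  bs <- blank_statistics(blanks)
  expect_equal(bs$n_excluded, 0L)
  expect_equal(bs$mean_blank, mean(blanks))
  expect_equal(bs$sd_blank, sd(blanks))
  expect_true(bs$normality_p > 0 && bs$normality_p <= 1)
  # all-equal blanks: SD zero, nothing excluded
  bs0 <- blank_statistics(rep(12, 5))
  expect_equal(bs0$sd_blank, 0)
  expect_equal(bs0$n_excluded, 0L)
  expect_error(blank_statistics(c(1, 2)), "at least 3")
})

test_that("detection limits reproduce the published assay limits", {
  dl <- detection_limits(15.84, 2.686)         # shake flask
  expect_equal(dl$lod, 23.9, tolerance = 0.002)
  expect_equal(dl$loq, 42.7, tolerance = 0.002)
  dl2 <- detection_limits(19.543, 3.586)       # bioreactor
  expect_equal(dl2$lod, 30.3, tolerance = 0.002)
  expect_equal(dl2$loq, 55.4, tolerance = 0.002)
  # affine identity and degenerate SD
  expect_equal(dl$loq - dl$lod, 7 * 2.686)
  dl0 <- detection_limits(10, 0)
  expect_equal(dl0$lod, 10)
  expect_equal(dl0$loq, 10)
})

test_that("endopeptidase activity matches the azocasein definition", {
  expect_equal(endopeptidase_activity(0.3, 0.3), 0)
  expect_equal(endopeptidase_activity(0.55, 0.3, dilution = 2,
                                      t_incubation = 1,
                                      v_supernatant = 0.1), 5)
  expect_equal(endopeptidase_activity(0.55, 0.3, dilution = 4),
               2 * endopeptidase_activity(0.55, 0.3, dilution = 2))
  expect_error(endopeptidase_activity(1, 0, t_incubation = 0), "> 0")
})

test_that("degradation rate is the negated OLS slope", {
  expect_equal(degradation_rate(c(0, 4, 8), c(100, 100, 100)), 0)
  expect_equal(degradation_rate(c(0, 8), c(268.6, 251.1)), 2.1875)
  tt <- c(0, 1, 2, 3, 4, 6, 8)
  expect_equal(degradation_rate(tt, 300 - 10 * tt), 10)
  # invariance under constant shift
  expect_equal(degradation_rate(tt, 300 - 9.2 * tt + 50),
               degradation_rate(tt, 300 - 9.2 * tt))
  # endpoint mode
  expect_equal(degradation_rate(c(0, 8), c(268.6, 251.1), method = "endpoint"),
               (268.6 - 251.1) / 8)
  expect_error(degradation_rate(1, 5), "at least 2")
})

test_that("percent activity loss matches the autodegradation worked example", {
  expect_equal(percent_activity_loss(268.6, 251.1), 6.5, tolerance = 0.01)
  expect_equal(percent_activity_loss(100, 100), 0)
  expect_equal(percent_activity_loss(100, 0), 100)
  expect_error(percent_activity_loss(0, 1), "> 0")
})
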