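test_that("paired differences reproduce the published worked examples", {
  ref <- reference_compartment_means()
  rows <- c("Urea", "Glutamate", "Triacylglyceride")
  for (m in rows) {
    i <- match(m, ref$metabolite)
    expect_equal(ref$b0_um[i] - ref$p0_um[i], ref$b0_minus_p0_um[i],
                 tolerance = 0.005 / abs(ref$b0_minus_p0_um[i]))
  }
  # through the pipeline's own arithmetic: one patient carrying the means
  t <- as_concentration_table(data.frame(
    patient_id = "x", compartment = c("BM", "PB"), day = 0L,
    urea = c(5018.23, 4464.38), glutamate = c(459.979, 156.271),
    triacylglyceride = c(2299.07, 2051.74), check.names = FALSE))
  s <- paired_differences(t, 0)$summary
  expect_equal(s$mean_diff[match("urea", s$metabolite)], 553.85,
               tolerance = 1e-8)
  expect_equal(round(s$mean_diff[match("glutamate", s$metabolite)], 2), 303.71)
  expect_equal(round(s$mean_diff[match("triacylglyceride", s$metabolite)], 2),
               247.33)
})

test_that("paired differences handle missing sides and equal compartments", {
  t <- tiny_table()
  pd <- paired_differences(t, 0)
  expect_equal(unname(pd$differences[, "glutamate"]),
               c(400 - 150, 420 - 160, 450 - 155))
  expect_equal(pd$summary$mean_diff,
               pd$summary$mean_bm - pd$summary$mean_pb)

  same <- t
  same$glutamate <- rep(c(100, 100), 3)
  expect_equal(unname(paired_differences(same, 0)$differences[, "glutamate"]),
               rep(0, 3))

  t2 <- t
  t2$glutamate[2] <- NA  # PB side of patient a
  expect_true(is.na(paired_differences(t2, 0)$differences["a", "glutamate"]))
  expect_error(paired_differences(t, 29), "no patient")
})

test_that("exact rank-sum p-values equal the enumeration oracle", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$p, 1 / 3, tolerance = 1e-12)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 1)

  set.seed(10)
  for (rep in 1:30) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    v <- sample(100, n1 + n2)  # tie-free
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(rank_sum_test(x, y)$p, oracle_ranksum_p(x, y),
                 tolerance = 1e-12,
                 info = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
  }
  expect_error(rank_sum_test(numeric(0), 1), "empty")
  expect_error(rank_sum_test(c(NA_real_, NA_real_), 1), "empty")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (rep in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # single p: q = p
  expect_equal(bh_adjust(0.037), 0.037)
})

test_that("compartment comparison finds a strongly shifted metabolite", {
  panel <- data.frame(metabolite = sprintf("met%02d", 1:20),
                      class = "other", mean_um = 100, cv = 0.2,
                      shift_day0 = c(200, rep(0, 19)),  # met01 shifted ~10 SD
                      shift_day29 = 0)
  cfg <- cohort_config(n_patients = 10, panel = panel, blocks = list(),
                       missing_rate = 0, seed = 21)
  res <- compartment_comparison(generate_cohort(cfg), 0)
  expect_identical(res$tier[res$metabolite == "met01"], "pFDR<5%")
  expect_identical(res$metabolite[1], "met01")
})

test_that("metabolites with too few complete pairs are dropped with notice", {
  t <- tiny_table()
  t$glutamine[c(1, 3)] <- NA  # only 1 complete pair remains
  expect_message(res <- compartment_comparison(t, 0, min_pairs = 3),
                 "glutamine")
  expect_false("glutamine" %in% res$metabolite)
  # single tested metabolite: q equals p
  expect_equal(res$q, res$p)
})

test_that("ratio features are appended and never divide by zero", {
  panel <- default_panel()
  cfg <- cohort_config(n_patients = 5, panel = panel, blocks = list(),
                       missing_rate = 0, seed = 31)
  t <- generate_cohort(cfg)
  out <- ratio_features(t)
  new_cols <- setdiff(ct_metabolites(out), ct_metabolites(t))
  expect_setequal(new_cols,
                  c("glutamate/glutamine", "aspartate/asparagine",
                    "choline/creatine", "unsaturated/saturated fatty acids",
                    "glutamine+pyroglutamate"))
  expect_equal(out$`glutamate/glutamine`, t$glutamate / t$glutamine)
  expect_equal(out$`glutamine+pyroglutamate`, t$glutamine + t$pyroglutamate)

  z <- t
  z$glutamine[1] <- 0
  zr <- ratio_features(z)
  expect_true(is.na(zr$`glutamate/glutamine`[1]))
  expect_false(any(is.infinite(zr$`glutamate/glutamine`)))

  # absent constituents: feature skipped with a notice, no error
  small <- tiny_table()
  expect_message(sk <- ratio_features(small), "skipped")
  expect_true("glutamate/glutamine" %in% names(sk))
  expect_false("choline/creatine" %in% names(sk))
})
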