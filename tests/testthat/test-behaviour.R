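test_that("block choice rates are plain percentages", {
  data <- toy_subject(c(BHBL = 15, NHNL = 30, BHNL = 18, NHBL = 20,
                        BHNH = 10, BLNL = 12, BiHNH = 25, BiLNL = 5))
  rates <- block_choice_rates(data)
  expect_equal(rates$pct_a[rates$block_type == "BHBL"], 50)
  expect_equal(rates$pct_a[rates$block_type == "NHNL"], 100)
  expect_equal(rates$pct_a[rates$block_type == "BHNL"], 60)
  expect_equal(nrow(rates), 8)
})

test_that("pro-variance bias averages the four same-mean blocks", {
  expect_equal(provariance_bias(c(60, 40, 70, 30))[["overall"]], 50)
  expect_equal(provariance_bias(rep(50, 4))[["overall"]], 50)
  pv <- provariance_bias(c(BHNH = 80, BLNL = 60, BiHNH = 90, BiLNL = 70))
  expect_equal(pv[["overall"]], 75)
  expect_equal(pv[["unimodal"]], 70)
  expect_equal(pv[["bimodal"]], 80)
  # named input is reordered, so scrambled names give the same answer
  pv2 <- provariance_bias(c(BiLNL = 70, BHNH = 80, BiHNH = 90, BLNL = 60))
  expect_equal(pv, pv2)
  expect_error(provariance_bias(c(50, 50, 50)), "four")
  expect_error(provariance_bias(c(BHNH = 1, BLNL = 2, BiHNH = 3, XX = 4)),
               "missing same-mean")
})

test_that("subject summaries assemble rates, accuracy and bias per subject", {
  data <- rbind(
    toy_subject(c(BHBL = 20, NHNL = 25, BHNL = 22, NHBL = 21,
                  BHNH = 18, BLNL = 12, BiHNH = 20, BiLNL = 10), id = "S1"),
    toy_subject(c(BHBL = 30, NHNL = 30, BHNL = 30, NHBL = 30,
                  BHNH = 15, BLNL = 15, BiHNH = 15, BiLNL = 15), id = "S2"))
  ss <- subject_summaries(data)
  s1 <- ss[ss$subject_id == "S1", ]
  expect_equal(s1$mean_accuracy_diffmean, 100 * (20 + 25 + 22 + 21) / 120)
  expect_equal(s1$provariance_bias, 100 * (18 + 12 + 20 + 10) / 120)
  expect_true(all(ss$complete))
  s2 <- ss[ss$subject_id == "S2", ]
  expect_equal(s2$provariance_bias, 50)
})

test_that("exclusion rules fire at their boundaries and are idempotent", {
  low <- toy_subject(c(BHBL = 17, NHNL = 18, BHNL = 18, NHBL = 18,  # 59.2% accuracy
                       BHNH = 15, BLNL = 15, BiHNH = 15, BiLNL = 15), id = "LOW")
  edge <- toy_subject(c(BHBL = 18, NHNL = 18, BHNL = 18, NHBL = 18,  # exactly 60%
                        BHNH = 15, BLNL = 15, BiHNH = 15, BiLNL = 15), id = "EDGE")
  const <- toy_subject(c(BHBL = 25, NHNL = 25, BHNL = 25, NHBL = 25,
                         BHNH = 30, BLNL = 15, BiHNH = 15, BiLNL = 15), id = "CONST")
  incomplete <- toy_subject(c(BHBL = 25, NHNL = 25, BHNL = 25, NHBL = 25,
                              BHNH = 15, BLNL = 15, BiHNH = 15), id = "PART")
  ss <- subject_summaries(rbind(low, edge, const, incomplete))
  res <- apply_exclusions(ss)
  expect_setequal(res$retained$subject_id, "EDGE")
  expect_equal(res$log$rule[res$log$subject_id == "LOW"], "low_diffmean_accuracy")
  expect_equal(res$log$rule[res$log$subject_id == "CONST"], "constant_same_mean_block")
  expect_equal(res$log$rule[res$log$subject_id == "PART"], "incomplete")
  again <- apply_exclusions(res$retained)
  expect_equal(again$retained, res$retained)
  expect_equal(nrow(again$log), 0)
})

test_that("trait correlations match the exact Pearson t transform", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- 2 * x + 3
  expect_equal(correlate_with_trait(x, y)$r, 1)
  expect_equal(correlate_with_trait(x, -x)$r, -1)
  set.seed(8)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  res <- correlate_with_trait(a, b)
  ref <- cor.test(a, b)
  expect_equal(res$r, unname(ref$estimate))
  expect_equal(res$p, ref$p.value)
  expect_equal(res$n, 30)
  expect_error(correlate_with_trait(1:2, 2:3), "at least 3")
  expect_error(correlate_with_trait(rep(1, 5), 1:5), "zero variance")
  expect_error(correlate_with_trait(1:4, 1:5), "paired")
})

test_that("random agents show no pro-variance bias on average", {
  gen <- generate_cohort(cohort_spec(
    100, "rw1",
    param_sampler = function(n) data.frame(alpha = rep(0.3, n), beta = rep(0, n)),
    seed = 55))
  ss <- subject_summaries(gen$choices)
  expect_lt(abs(mean(ss$provariance_bias) - 50), 3)
})
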