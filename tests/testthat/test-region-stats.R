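test_that("ROI exclusions remove exactly the flagged voxels", {
  d <- c(6, 6, 4)
  ce <- array(FALSE, d); ce[1:3, 1:3, 1] <- TRUE          # 9 voxels
  ed <- array(FALSE, d); ed[4:6, 4:6, 2:3] <- TRUE        # 18 voxels
  swi <- array(FALSE, d); swi[1:2, 1:3, 1] <- TRUE        # 6 in CE
  nec <- array(FALSE, d); nec[4, 4:5, 2:3] <- TRUE        # 4 in edema
  rois <- roi_mask_set(ce, ed, swi, nec)
  clean <- apply_exclusions(rois)
  expect_equal(sum(clean$ce_t1_tumor), 9 - 6)
  expect_equal(sum(clean$t2_edema), 18 - 4)
  # empty exclusions leave the ROIs unchanged
  same <- apply_exclusions(roi_mask_set(ce, ed))
  expect_identical(same$ce_t1_tumor, ce)
  expect_identical(same$t2_edema, ed)
  # an exclusion covering a whole ROI empties it with a warning
  expect_warning(gone <- apply_exclusions(roi_mask_set(ce, ed, ce)),
                 "CE-T1")
  expect_equal(sum(gone$ce_t1_tumor), 0)
  # overlapping ROIs are rejected
  expect_error(roi_mask_set(ce, ce), "disjoint")
})

test_that("pair extraction enumerates finite ROI voxels", {
  d <- c(3, 3, 3)
  ce <- array(TRUE, d)
  ed <- array(FALSE, d)
  mtr <- array(as.numeric(1:27), d)
  adc <- array(as.numeric(101:127), d)
  rois <- roi_mask_set(ce, ed)
  tab <- extract_pairs(mtr, adc, rois)
  expect_equal(nrow(tab), 27)
  expect_equal(tab$mtr_asym_percent, as.numeric(1:27))
  expect_equal(tab$adc, as.numeric(101:127))
  # one NaN MTR voxel drops one row, and the drop is counted
  mtr[2, 2, 2] <- NaN
  tab2 <- extract_pairs(mtr, adc, rois)
  expect_equal(nrow(tab2), 26)
  expect_equal(unname(attr(tab2, "n_dropped")["ce_t1_tumor"]), 1L)
  # constant maps give identical rows over a 50-voxel ROI
  ce50 <- array(FALSE, c(5, 5, 2)); ce50[, , 1] <- TRUE
  t50 <- extract_pairs(array(-2, c(5, 5, 2)), array(900, c(5, 5, 2)),
                       roi_mask_set(ce50, array(FALSE, c(5, 5, 2))))
  expect_equal(nrow(t50), 25)
  expect_true(all(t50$mtr_asym_percent == -2 & t50$adc == 900))
})

test_that("Spearman matches the classical rank formula and its preconditions", {
  x <- c(1, 2, 3, 4, 5); y <- c(3, 1, 4, 2, 5)
  s <- spearman_rs(x, y)
  expect_equal(s$r, spearman_classical(x, y))  # = 0.5 for this pair
  expect_equal(s$r, 0.5)
  # monotone relations are exactly +/-1
  expect_equal(spearman_rs(1:10, exp(1:10))$r, 1)
  expect_equal(spearman_rs(1:10, -(1:10))$r, -1)
  expect_equal(spearman_rs(1:10, exp(1:10))$p, 0)
  # exhaustive agreement with the rank formula for untied n <= 8
  set.seed(71)
  for (n in 4:8) {
    for (rep in 1:20) {
      a <- sample(n); b <- sample(n)
      expect_equal(spearman_rs(a, b)$r, spearman_classical(a, b),
                   tolerance = 1e-12)
    }
  }
  expect_error(spearman_rs(1:3, 3:1), "at least 4")
  expect_error(spearman_rs(rep(1, 5), 1:5), "degenerate")
})

test_that("Spearman is invariant under strictly increasing transforms", {
  set.seed(5)
  x <- rnorm(60); y <- x + rnorm(60)
  r0 <- spearman_rs(x, y)$r
  expect_equal(spearman_rs(exp(x), y)$r, r0)
  expect_equal(spearman_rs(x, y^3)$r, r0)
  expect_equal(spearman_rs(exp(x), y^3)$r, r0)
})

test_that("tied data use mid-ranks, agreeing with cor.test", {
  x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6, 7)
  s <- spearman_rs(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  expect_equal(s$r, unname(ct$estimate))
  expect_equal(s$p, ct$p.value, tolerance = 1e-10)
})

test_that("Bonett-Wright interval matches its scalar formula", {
  ci <- bonett_wright_ci(0.5, 100)
  # independent hand evaluation: z +/- 1.959964 * sqrt(1.125 / 97)
  se <- sqrt((1 + 0.5^2 / 2) / 97)
  expect_equal(unname(ci),
               tanh(atanh(0.5) + c(-1, 1) * qnorm(0.975) * se),
               tolerance = 1e-12)
  # symmetric about 0 at r = 0
  ci0 <- bonett_wright_ci(0, 1000)
  expect_equal(ci0[["lo"]], -ci0[["hi"]])
  # higher confidence level widens the interval strictly
  ci99 <- bonett_wright_ci(0.5, 100, level = 0.99)
  expect_lt(ci99[["lo"]], ci[["lo"]])
  expect_gt(ci99[["hi"]], ci[["hi"]])
  expect_error(bonett_wright_ci(0.5, 4), "n >= 5")
})

test_that("association classification covers every case exactly once", {
  # published anchor cases
  expect_equal(classify_association(0.53, 1e-4), "positive-moderate")
  expect_equal(classify_association(0.12, 1e-4), "none-negligible")
  expect_equal(classify_association(-0.04, 0.5), "none-insignificant")
  expect_equal(classify_association(0.685, 0.014), "positive-strong")
  expect_equal(classify_association(-0.755, 0.005), "negative-strong")
  # band edges: 0.15 negligible, just above weak; 0.40 moderate; 0.65 strong
  expect_equal(classify_association(0.15, 0.01), "none-negligible")
  expect_equal(classify_association(0.1500001, 0.01), "positive-weak")
  expect_equal(classify_association(0.3999999, 0.01), "positive-weak")
  expect_equal(classify_association(0.40, 0.01), "positive-moderate")
  expect_equal(classify_association(0.65, 0.01), "positive-strong")
  expect_equal(classify_association(-0.65, 0.01), "negative-strong")
  # p exactly at alpha still counts as significant (rule is p > alpha)
  expect_equal(classify_association(0.3, 0.05), "positive-weak")
  expect_equal(classify_association(0.3, 0.0500001), "none-insignificant")
  # totality over a grid: exactly one class for every (r, p)
  grid <- expand.grid(r = seq(-1, 1, by = 0.05),
                      p = c(0.001, 0.04, 0.05, 0.06, 0.5))
  cls <- classify_association(grid$r, grid$p)
  expect_true(all(cls %in% c(
    "positive-weak", "positive-moderate", "positive-strong",
    "negative-weak", "negative-moderate", "negative-strong",
    "none-negligible", "none-insignificant")))
  expect_error(classify_association(1.2, 0.01), "\\[-1, 1\\]")
})

test_that("cohort summary reproduces per-ROI class tallies", {
  res <- data.frame(
    patient = rep(1:3, 2),
    roi = rep(c("a", "b"), each = 3),
    r_sp = c(0.3, -0.5, 0.05, 0.9, 0.2, 0.1),
    p = c(0.01, 0.001, 0.01, 0.001, 0.2, 0.01)
  )
  s <- summarize_cohort(res)
  ta <- s$tallies[s$tallies$roi == "a", ]
  expect_equal(ta$positive, 1)
  expect_equal(ta$negative, 1)
  expect_equal(ta$none, 1)
  expect_equal(sum(s$counts$n), 6)
  one <- summarize_cohort(res[1, , drop = FALSE])
  expect_equal(sum(one$counts$n), 1)
})

test_that("ROI correlation rows carry coefficient, CI and class", {
  set.seed(9)
  n <- 300
  pr <- rank_coupled_pairs(n, 0.5)
  pairs <- data.frame(voxel = seq_len(2 * n),
                      roi = rep(c("ce_t1_tumor", "t2_edema"), each = n),
                      mtr_asym_percent = c(pr$x, rnorm(n)),
                      adc = c(pr$y, rnorm(n)))
  out <- correlate_rois(pairs)
  expect_equal(nrow(out), 2)
  ce <- out[out$roi == "ce_t1_tumor", ]
  expect_true(ce$ci_lo <= ce$r_sp && ce$r_sp <= ce$ci_hi)
  expect_lt(abs(ce$r_sp - 0.5), 0.15)
  expect_match(ce$class, "^positive")
})
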