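# brute-force robust-Z reference, kept deliberately naive
brute_rz <- function(values, reference) {
  m <- sort(reference)[ceiling(length(reference) / 2)]
  if (length(reference) %% 2 == 0) {
    s <- sort(reference)
    m <- (s[length(s) / 2] + s[length(s) / 2 + 1]) / 2
  }
  dev <- sort(abs(reference - m))
  md <- dev[ceiling(length(dev) / 2)]
  if (length(dev) %% 2 == 0) md <- (dev[length(dev) / 2] +
                                      dev[length(dev) / 2 + 1]) / 2
  (values - m) / (1.4826 * md)
}

test_that("robust_z matches the hand-computed and brute-force references", {
  # reference [1,2,3,4,100]: median 3, MAD 1; value 100 -> 97/1.4826
  z <- robust_z(100, c(1, 2, 3, 4, 100))
  expect_equal(as.numeric(z), 97 / 1.4826, tolerance = 1e-12)
  expect_equal(attr(z, "median"), 3)
  expect_equal(attr(z, "mad"), 1)
  # value at the reference median scores 0
  expect_equal(as.numeric(robust_z(3, c(1, 2, 3, 4, 100))), 0)
  # brute-force agreement over 1,000 random vectors
  set.seed(11)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    ref <- rnorm(n, sd = runif(1, 0.1, 10))
    v <- rnorm(5)
    d <- max(abs(as.numeric(robust_z(v, ref)) - brute_rz(v, ref)))
    worst <- max(worst, d)
  }
  expect_lt(worst, 1e-12)
})

test_that("robust_z is a consistent normal-scale estimator and equivariant", {
  set.seed(21)
  ref <- rnorm(1e5)
  x <- c(-2, -1, 0.5, 1, 3)
  expect_equal(as.numeric(robust_z(x, ref)), x, tolerance = 0.02)
  # location/scale equivariance: rz(a x + b, a ref + b) = sign(a) rz(x, ref)
  set.seed(22)
  for (i in 1:20) {
    ref <- rnorm(50)
    x <- rnorm(4)
    a <- runif(1, -5, 5)
    if (abs(a) < 0.1) a <- 1
    b <- runif(1, -10, 10)
    expect_equal(as.numeric(robust_z(a * x + b, a * ref + b)),
                 sign(a) * as.numeric(robust_z(x, ref)), tolerance = 1e-9)
  }
})

test_that("robust_z flags degenerate references and rejects empty ones", {
  expect_error(robust_z(1, numeric(0)), "empty")
  expect_error(robust_z(1, c(1, 2)), ">= 3")
  z <- robust_z(c(1, 2), c(5, 5, 5, 5))
  expect_true(attr(z, "mad_zero"))
  expect_false(any(is.finite(z)))
})

test_that("median_polish handles constant, additive and hand-checked inputs", {
  # constant matrix: overall = c, effects and residuals 0
  mp <- median_polish(matrix(3.5, 6, 8))
  expect_equal(mp$overall, 3.5)
  expect_equal(mp$row_effects, rep(0, 6))
  expect_equal(mp$col_effects, rep(0, 8))
  expect_equal(max(abs(mp$residuals)), 0)
  # purely additive matrix: residuals vanish
  set.seed(31)
  r <- rnorm(10); c <- rnorm(14)
  m <- 2 + outer(r, c, "+")
  mp <- median_polish(m)
  expect_lt(max(abs(mp$residuals)), 1e-8)
  # 2x2 hand oracle: [[1,2],[3,4]] = 2.5 + (-1,1) + (-0.5,0.5), residuals 0
  mp <- median_polish(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(mp$overall, 2.5)
  expect_equal(mp$row_effects, c(-1, 1))
  expect_equal(mp$col_effects, c(-0.5, 0.5))
  expect_equal(max(abs(mp$residuals)), 0)
  # independent reference: stats::medpolish on screen-structured matrices
  # (additive effects plus sparse outliers; on heavily non-additive data
  # polish fixed points are not unique, so only such matrices admit an
  # exact cross-implementation check)
  set.seed(32)
  for (i in 1:5) {
    m <- 1 + outer(rnorm(8), rnorm(12), "+")
    k <- sample(96, 5)
    m[k] <- m[k] + rnorm(5, 0, 3)
    ref <- suppressWarnings(stats::medpolish(m, trace.iter = FALSE,
                                             maxiter = 200, eps = 1e-12))
    mp <- median_polish(m, max_iter = 200, tol = 1e-12)
    expect_equal(mp$overall, ref$overall, tolerance = 1e-10)
    expect_equal(mp$row_effects, ref$row, tolerance = 1e-10)
    expect_equal(mp$col_effects, ref$col, tolerance = 1e-10)
    expect_equal(mp$residuals, ref$residuals, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("median_polish reconstructs every entry and honors masks", {
  set.seed(33)
  for (i in 1:20) {
    m <- matrix(rnorm(6 * 9), 6, 9)
    use <- matrix(runif(54) > 0.2, 6, 9)
    use[, 1] <- TRUE  # keep enough support
    mp <- median_polish(m, use)
    fit <- mp$overall + outer(mp$row_effects, mp$col_effects, "+")
    expect_equal(m, fit + mp$residuals, tolerance = 1e-12)
  }
  # fully masked column: effect 0 and flagged; residuals still reported
  m <- matrix(rnorm(20), 4, 5)
  use <- matrix(TRUE, 4, 5); use[, 3] <- FALSE
  mp <- median_polish(m, use)
  expect_equal(mp$flagged_cols, 3L)
  expect_equal(mp$col_effects[3], 0)
  expect_true(all(is.finite(mp$residuals[, 3])))
})

test_that("score_plates flags MAD-zero plates and recovers spiked wells", {
  lay <- make_screen_layout(c(8L, 12L), replicates = 1L)
  sample_wells <- lay[lay$control_role == "sample", ]
  mk_summaries <- function(er_frac) {
    sm <- data.frame(plate = lay$plate, well = lay$well,
                     replicate = lay$replicate, n_cells = 300L)
    sm$frac_ER_retained <- er_frac
    sm$frac_ER_plus_Golgi <- 0
    sm$frac_Golgi <- 1 - er_frac
    sm$frac_Golgi_disrupted <- 0
    sm$low_count <- FALSE
    sm
  }
  # all wells identical: MAD 0, scores flagged non-finite
  sc <- score_plates(mk_summaries(rep(0.02, nrow(lay))), lay,
                     classes = "ER_retained")
  expect_true(all(sc$mad_zero))
  expect_false(any(is.finite(sc$rz[sc$control_role == "sample"])))
  # spiked well at median + 10 * (1.4826 * MAD) scores about 10
  set.seed(41)
  er <- 0.02 + rnorm(nrow(lay), 0, 0.004)
  sm <- mk_summaries(er)
  base <- sm$frac_ER_retained[sm$well %in% sample_wells$well]
  med <- median(base); madv <- median(abs(base - med))
  spike_well <- sample_wells$well[10]
  sm$frac_ER_retained[sm$well == spike_well] <- med + 10 * 1.4826 * madv
  sc <- score_plates(sm, lay, classes = "ER_retained", polish = FALSE)
  expect_equal(sc$rz[sc$well == spike_well], 10, tolerance = 0.2)
  # missing class column is rejected
  expect_error(score_plates(sm[, setdiff(names(sm), "frac_Golgi")], lay,
                            classes = "Golgi"))
})

test_that("hit calling is strict at the threshold and aggregates correctly", {
  mk_scores <- function(rz_by_rep) {
    do.call(rbind, lapply(seq_along(rz_by_rep), function(r)
      data.frame(plate = "P1", replicate = r, well = "B03", row = 2, col = 3,
                 compound_id = "CMP", control_role = "sample",
                 class = "ER_retained", value = 0, residual = 0,
                 rz = rz_by_rep[r], ref_median = 0, ref_mad = 1,
                 mad_zero = FALSE, low_count = FALSE)))
  }
  # RZ exactly 2.0 is NOT a hit (strict inequality)
  h <- call_hits(mk_scores(c(2, 2, 2)))
  expect_false(any(h$hit))
  h <- call_hits(mk_scores(c(2 + 1e-9, 2 + 1e-9, 2 + 1e-9)))
  expect_true(h$hit[h$class == "ER_retained"])
  # RZ -2.1 in all replicates is a hit, with negative sign
  h <- call_hits(mk_scores(c(-2.1, -2.1, -2.1)))
  er <- h[h$class == "ER_retained", ]
  expect_true(er$hit)
  expect_equal(er$sign, -1)
  # (2.5, 1.0, 2.5): majority yes, all no, any yes
  s <- mk_scores(c(2.5, 1.0, 2.5))
  expect_true(call_hits(s, aggregation = "majority")$hit[1])
  expect_false(call_hits(s, aggregation = "all")$hit[1])
  expect_true(call_hits(s, aggregation = "any")$hit[1])
  expect_error(call_hits(s, threshold = 0), "positive")
})

test_that("polish removes the positional gradient from a gradient-only plate", {
  p <- default_sim_params(positional_gradient_amplitude = 0.1,
                          nuisance_retention_sd = 0)
  lay <- make_screen_layout(c(16L, 24L), replicates = 3L)
  ids <- unique(lay$compound_id[lay$control_role == "sample"])
  fx <- assign_screen_effects(ids, active_fraction = 0, seed = 5)
  sim <- simulate_plate(lay, fx, p, seed = 5, render = FALSE)
  sm <- truth_well_summaries(sim)
  sc <- score_plates(sm, lay)
  samp <- sc[sc$control_role == "sample", ]
  # positional structure is gone from the residuals: per-row residual medians
  # are far smaller than the row gradient they replace
  g <- sim$gradient
  for (cl in c("Golgi", "ER_retained")) {
    x <- samp[samp$class == cl & samp$replicate == 1, ]
    row_med <- tapply(x$residual, x$row, median)
    expect_lt(max(abs(row_med)), 0.2 * max(g$row))
  }
  # per-replicate self-normalized coverage: below the 95.4% Gaussian value
  # because binomial well variance differs across the gradient (the MAD
  # tracks the typical well, not the noisiest), but the bulk of wells stays
  # inside the hit band
  expect_gt(mean(abs(samp$rz[samp$class == "Golgi"]) < 2), 0.85)
  expect_gt(mean(abs(samp$rz[samp$class == "ER_retained"]) < 2), 0.85)
  # after majority aggregation, the false-call rate stays small (small-count
  # Poisson skew keeps it above the pure-Gaussian ~0.7% floor)
  h <- call_hits(sc)
  for (cl in c("Golgi", "ER_retained")) {
    x <- h[h$class == cl, ]
    expect_lte(mean(ids %in% x$compound_id[x$hit]), 0.03)
  }
  # without polish, the raw values are strongly row-structured
  sc0 <- score_plates(sm, lay, polish = FALSE)
  x0 <- sc0[sc0$control_role == "sample" & sc0$class == "Golgi" &
              sc0$replicate == 1, ]
  row_med0 <- tapply(x0$residual - median(x0$residual), x0$row, median)
  expect_gt(max(abs(row_med0)), 0.3 * max(g$row))
})
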