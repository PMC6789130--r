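test_that("lipid correction applies strictly above C:N 3.15", {
  expect_equal(as.numeric(lipid_normalize(-18, 3.0)), -18)
  expect_equal(as.numeric(lipid_normalize(-18, 3.15)), -18)   # boundary: no correction
  out <- lipid_normalize(-18, 4.5)
  expect_equal(as.numeric(out), -18 - 3.32 + 0.99 * 4.5)
  expect_equal(attr(out, "equation"), "post2007")
  expect_error(lipid_normalize(-18, NA), "missing")
  expect_error(lipid_normalize(-18, -1), "positive")
  expect_error(lipid_normalize(-18, 4, equation = "nope"), "unknown")
})

test_that("discrimination shifts are exact arithmetic and invertible", {
  prey <- data.frame(d15N = 8.0, d13C = -19.0)
  out <- apply_discrimination(prey)
  expect_equal(out$d15N, 11.7)
  expect_equal(out$d13C, -17.1)
  zero <- apply_discrimination(prey, discrimination_factors(0, 0))
  expect_equal(zero, prey)
  expect_error(discrimination_factors(-3.7, -1.9), "positive")
  inv <- out; inv$d15N <- inv$d15N - 3.7; inv$d13C <- inv$d13C - 1.9
  expect_equal(inv, prey)
})

test_that("Ward clustering matches the Lance-Williams brute-force oracle", {
  x <- fixture_ward_12pt()[, c("d15N", "d13C")]
  lab <- ward_cluster(x, k = 2)
  tree <- attr(lab, "tree")
  oracle <- oracle_ward(as.matrix(x))
  expect_equal(tree$height, oracle$heights, tolerance = 1e-10)
  # the merged member set at each step is a single cluster when the tree is
  # cut just above that step's height
  for (s in seq_len(nrow(x) - 2)) {
    cl <- stats::cutree(tree, h = oracle$heights[s] + 1e-9)
    expect_equal(length(unique(cl[oracle$merges[[s]]])), 1)
  }
  # two tight clusters are recovered perfectly
  expect_equal(length(unique(lab[1:6])), 1)
  expect_equal(length(unique(lab[7:12])), 1)
  expect_true(lab[1] != lab[7])
  # k = n gives singletons
  expect_equal(sort(unique(ward_cluster(x, k = 12))), 1:12)
  expect_error(ward_cluster(x[1, , drop = FALSE], k = 2), "at least")
})

test_that("standard ellipse areas match direct computation", {
  e8 <- fixture_ellipse_8pt()
  out <- standard_ellipse(e8, group = "toy")
  expect_equal(out$SEA, oracle_sea(e8$d15N, e8$d13C), tolerance = 1e-12)
  expect_equal(out$SEAc, out$SEA * 7 / 6, tolerance = 1e-12)
  expect_gte(out$hull_area, out$SEA * 0.5)
  # n = 3: SEAc is exactly twice SEA
  s3 <- standard_ellipse(e8[1:3, ])
  expect_equal(s3$SEAc, 2 * s3$SEA)
  # large-n identity covariance: SEA -> pi
  set.seed(201)
  big <- data.frame(d15N = rnorm(20000), d13C = rnorm(20000))
  expect_equal(standard_ellipse(big)$SEA, pi, tolerance = 0.05)
  expect_error(standard_ellipse(e8[1:2, ]), "at least 3")
  degen <- data.frame(d15N = 1:5, d13C = 2 * (1:5))
  expect_error(standard_ellipse(degen), "degenerate")
})

test_that("the fitted discriminant agrees with MASS and manova", {
  tr <- simulate_isotopes(region_signatures("P6"), n = 25, seed = 301)
  m <- fit_lda(tr)
  ref <- MASS::lda(tr[, c("d15N", "d13C")], grouping = factor(tr$region))
  expect_equal(as.character(predict(ref)$class), classify(m, tr)$region)
  wl <- summary(stats::manova(as.matrix(tr[, c("d15N", "d13C")]) ~
                                factor(tr$region)), test = "Wilks")$stats[1, 2]
  expect_equal(m$wilks_lambda, unname(wl), tolerance = 1e-10)
  expect_gt(m$wilks_lambda, 0)
  expect_lte(m$wilks_lambda, 1)
})

test_that("equal group means give no discrimination (Wilks ~ 1)", {
  set.seed(302)
  tr <- data.frame(d15N = rnorm(60, 12), d13C = rnorm(60, -17),
                   region = rep(c("atlantic", "mediterranean"), 30))
  m <- fit_lda(tr)
  expect_gt(m$wilks_lambda, 0.9)
  expect_error(fit_lda(tr[tr$region == "atlantic", ]), "two groups")
  expect_error(fit_lda(tr[c(1, 3, 5, 2), ]), ">= 2")
})

test_that("Fisher argmax equals nearest-Mahalanobis-mean and the sign rule", {
  tr <- simulate_isotopes(region_signatures("P6"), n = 20, seed = 303)
  m <- fit_lda(tr)
  set.seed(304)
  probe <- data.frame(d15N = runif(100, 9, 17), d13C = runif(100, -19, -15))
  cls <- classify(m, probe)
  spinv <- solve(m$pooled_cov)
  maha <- apply(as.matrix(probe), 1, function(v) {
    d <- vapply(1:2, function(g) {
      dv <- v - m$means[g, ]; sqrt(sum(dv * (spinv %*% dv)))
    }, numeric(1))
    m$groups[which.min(d)]
  })
  expect_equal(cls$region, maha)
  # two-group identity: Fisher argmax == canonical sign rule
  expect_equal(cls$region == m$positive_group, cls$D > 0)
})

test_that("discriminant decisions are invariant to affine rescaling", {
  tr <- simulate_isotopes(region_signatures("P6"), n = 15, seed = 305)
  te <- simulate_isotopes(region_signatures("P6"), n = 30, seed = 306)
  m1 <- fit_lda(tr)
  scale2 <- function(d) { d$d15N <- 3 * d$d15N + 5; d$d13C <- 0.5 * d$d13C - 2; d }
  m2 <- fit_lda(scale2(tr))
  expect_equal(classify(m1, te)$region, classify(m2, scale2(te))$region)
  expect_equal(m1$wilks_lambda, m2$wilks_lambda, tolerance = 1e-10)
})

test_that("printed presets classify the published group means correctly", {
  p6 <- discriminant_preset("p6")
  means <- data.frame(d15N = c(11.8, 14.5), d13C = c(-17.4, -16.1))
  out <- classify(p6, means)
  expect_equal(out$region, c("mediterranean", "atlantic"))
  expect_equal(out$margin[1], 7.4, tolerance = 0.05)
  p1 <- discriminant_preset("p1")
  d <- classify(p1, data.frame(d15N = c(13.7, 11.8), d13C = c(-16.9, -17.2)))$D
  expect_equal(d, c(0.86, -0.57), tolerance = 0.01)
  expect_lt(d[1] * d[2], 0)
  # an exact Fisher tie is left unassigned
  tie_model <- p6
  tie_model$fisher[1, ] <- tie_model$fisher[2, ]
  tied <- classify(tie_model, means[1, ])
  expect_true(tied$tie)
  expect_true(is.na(tied$region))
})

test_that("leave-one-out cross-validation matches brute-force refits", {
  tr <- rbind(
    data.frame(d15N = c(14.2, 14.9, 13.8), d13C = c(-16.2, -15.8, -16.5),
               region = "atlantic"),
    data.frame(d15N = c(11.5, 11.1, 12.0), d13C = c(-17.6, -17.9, -17.2),
               region = "mediterranean"))
  cv <- loocv(tr)
  manual <- vapply(seq_len(6), function(i) {
    m <- fit_lda(tr[-i, ])
    classify(m, tr[i, , drop = FALSE])$region
  }, character(1))
  expect_equal(cv$predictions$predicted, manual)
  expect_equal(cv$accuracy, mean(manual == tr$region))
  # widely separated toy groups: perfect accuracy
  sep <- tr; sep$d15N[1:3] <- sep$d15N[1:3] + 20
  expect_equal(loocv(sep)$accuracy, 1)
})

test_that("LOOCV sits at chance for identical group distributions", {
  set.seed(307)
  tr <- data.frame(d15N = rnorm(120, 12, 1), d13C = rnorm(120, -17, 0.5),
                   region = rep(c("atlantic", "mediterranean"), 60))
  expect_lt(abs(loocv(tr)$accuracy - 0.5), 0.12)
})

test_that("LOOCV accuracy is high for colony-cell training groups", {
  # population-year cells as training groups (Atlantic = Mallorca P6,
  # Mediterranean = Menorca P6, 2011), averaged over replicate cohorts
  ref <- feather_isotope_reference()
  cells <- ref[ref$feather == "P6" & ref$year == 2011, ]
  cells$region <- ifelse(cells$population == "Mallorca", "atlantic",
                         "mediterranean")
  accs <- vapply(1:5, function(i) {
    tr <- simulate_isotopes(cells, n = 50, seed = 310 + i)
    loocv(tr)$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.85)
})

test_that("untracked assignment summarises cohorts and agrees with clusters", {
  empty <- assign_untracked(discriminant_preset("p6"),
                            data.frame(d15N = numeric(0), d13C = numeric(0)))
  expect_equal(nrow(empty$predictions), 0)
  expect_true(all(empty$summary$count == 0))
  # all samples at one group's mean: 100% that region
  m <- discriminant_preset("p6")
  at_mean <- data.frame(d15N = rep(11.8, 8), d13C = rep(-17.4, 8))
  res <- assign_untracked(m, at_mean)
  expect_equal(res$summary$proportion[res$summary$region == "mediterranean"], 1)
  # well-separated synthetic cohort: DFA and Ward clusters agree fully
  coh <- simulate_isotopes(region_signatures("P6"), n = 30, seed = 320)
  res2 <- assign_untracked(fit_lda(coh), coh)
  expect_equal(res2$ward_agreement, 1)
})

test_that("the fitted boundary converges to the generating-Gaussian optimum", {
  sig <- region_signatures("P6")
  tr <- simulate_isotopes(sig, n = 5000, seed = 330)
  m <- fit_lda(tr)
  # analytic optimal boundary for equal-covariance Gaussians: the canonical
  # direction is Sigma^-1 (mu_A - mu_M)
  sigma <- diag(c(1, 0.5)^2)
  dir_true <- solve(sigma, c(14.5 - 11.4, -16.1 + 17.5))
  dir_fit <- as.numeric(m$coef)
  cosang <- sum(dir_true * dir_fit) /
    sqrt(sum(dir_true^2) * sum(dir_fit^2))
  expect_gt(cosang, 0.999)
})
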