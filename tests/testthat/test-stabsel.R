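make_noise_design <- function(n = 400, p = 20, seed = 1) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(d) <- paste0("x", seq_len(p))
  list(d = d, y = rnorm(n))
}

test_that("a dominant predictor reaches frequency one; thresholds are closed", {
  set.seed(2)
  n <- 300
  d <- data.frame(strong = rnorm(n), weak = rnorm(n))
  y <- 3 * d$strong + rnorm(n, sd = 0.3)
  ln <- base_learners(d, c("strong", "weak"), types = "linear")
  st <- stabsel_boost(y, d, fam_gaussian(), ln, B = 10, q_sel = 1,
                      max_iter = 50, seed = 4)
  expect_equal(unname(st$freq["strong", "mu"]), 1)
  expect_true("strong" %in% st$stable)

  # 'at least 70%' is a closed threshold: 0.69 is excluded, 0.70 included
  fake <- st
  fake$freq["strong", "mu"] <- 0.69
  stable_of <- function(x) rownames(x$freq)[apply(
    x$freq[, intersect(c("mu", "nu"), colnames(x$freq)), drop = FALSE], 1, max) >= x$pi_thr]
  expect_false("strong" %in% stable_of(fake))
  fake$freq["strong", "mu"] <- 0.70
  expect_true("strong" %in% stable_of(fake))
})

test_that("stability selection is deterministic given the seed and validates inputs", {
  nd <- make_noise_design(n = 120, p = 5, seed = 3)
  ln <- base_learners(nd$d, names(nd$d), types = "linear")
  s1 <- stabsel_boost(nd$y, nd$d, fam_gaussian(), ln, B = 6, q_sel = 2,
                      max_iter = 60, seed = 9)
  s2 <- stabsel_boost(nd$y, nd$d, fam_gaussian(), ln, B = 6, q_sel = 2,
                      max_iter = 60, seed = 9)
  expect_identical(s1$freq, s2$freq)
  expect_error(stabsel_boost(nd$y, nd$d, fam_gaussian(), ln, B = 5),
               class = "divgrad_invalid_parameter")
  expect_error(stabsel_boost(nd$y, nd$d, fam_gaussian(), ln, B = 4, pi_thr = 0.4),
               class = "divgrad_invalid_parameter")
  expect_error(stabsel_boost(nd$y, nd$d, fam_gaussian(), ln, B = 4, q_sel = 99),
               class = "divgrad_invalid_parameter")
})

test_that("the null design stays below the expected-false-positive bound", {
  # smaller replicate of the acceptance-scale simulation
  sizes <- numeric(8)
  for (r in seq_len(8)) {
    nd <- make_noise_design(n = 200, p = 12, seed = 100 + r)
    ln <- base_learners(nd$d, names(nd$d), types = "linear")
    st <- stabsel_boost(nd$y, nd$d, fam_gaussian(), ln, B = 20, q_sel = 3,
                        max_iter = 120, seed = r)
    sizes[r] <- length(st$stable)
  }
  bound <- 3^2 / ((2 * 0.7 - 1) * 12)
  expect_lte(mean(sizes), bound)
})

test_that("consistency reports cross analyses and ignore the scale parameter", {
  nd <- make_noise_design(n = 150, p = 4, seed = 5)
  y <- 2.5 * nd$d$x1 + rnorm(150, sd = 0.4)
  ln <- base_learners(nd$d, names(nd$d), types = "linear")
  st <- stabsel_boost(y, nd$d, fam_gaussian(), ln, B = 8, q_sel = 2,
                      max_iter = 500, seed = 2)
  rep1 <- consistency_report(list(only = st))
  expect_setequal(rep1$learner[rep1$consistent], st$stable)

  # a learner stable on sigma alone never becomes consistent
  fake <- st
  fake$freq[, "mu"] <- 0
  fake$freq["x2", "sigma"] <- 1
  rep2 <- consistency_report(list(a = fake))
  expect_false(any(rep2$consistent))
  expect_equal(rep2$freq_sigma[rep2$learner == "x2"], 1)
})
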