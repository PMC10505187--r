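make_fits <- function(activity_by_rep, sgrna = NULL, promoter = "P1") {
  # activity_by_rep: named list replicate_id -> named numeric vector of
  # mean activities keyed by sgrna id
  rows <- lapply(names(activity_by_rep), function(r) {
    v <- activity_by_rep[[r]]
    data.frame(sgrna_id = names(v), promoter_id = promoter,
               replicate_id = r, mu = log(v), sigma = 0.5,
               mean_activity = unname(v), log_likelihood = -1, kl = 0.1,
               total_cells = 100, qc_flags = "", usable = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("rescaling a replicate identical to the reference is the identity", {
  act <- stats::setNames(exp(seq(4, 8, length.out = 30)), paste0("sg", 1:30))
  fits <- make_fits(list(rep1 = act, rep3 = act))
  maps <- fit_rescale(fits, "rep3")
  r1 <- maps[maps$replicate_id == "rep1", ]
  expect_equal(r1$slope, 1, tolerance = 1e-10)
  expect_equal(r1$intercept, 0, tolerance = 1e-9)
  ref <- maps[maps$replicate_id == "rep3", ]
  expect_identical(c(ref$slope, ref$intercept), c(1, 0))
})

test_that("an exact affine relation is recovered by least squares", {
  y <- seq(2, 6, length.out = 25)
  fits <- make_fits(list(rep1 = stats::setNames(exp(y), paste0("sg", 1:25)),
                         rep3 = stats::setNames(exp(2 * y + 1),
                                                paste0("sg", 1:25))))
  maps <- fit_rescale(fits, "rep3")
  r1 <- maps[maps$replicate_id == "rep1", ]
  expect_equal(r1$slope, 2, tolerance = 1e-10)
  expect_equal(r1$intercept, 1, tolerance = 1e-9)
  rescaled <- apply_rescale(fits, maps)
  r1rows <- rescaled[rescaled$replicate_id == "rep1", ]
  expect_equal(r1rows$log_activity_rescaled, 2 * y + 1, tolerance = 1e-9)
})

test_that("slope estimates are unbiased under symmetric noise", {
  set.seed(97)
  slopes <- replicate(200, {
    x <- runif(40, 3, 9)
    y <- 1.5 * x + 0.3 + rnorm(40, 0, 0.15)
    fits <- make_fits(list(
      repA = stats::setNames(exp(x), paste0("sg", 1:40)),
      repR = stats::setNames(exp(y), paste0("sg", 1:40))))
    fit_rescale(fits, "repR")$slope[1]
  })
  expect_lt(abs(mean(slopes) - 1.5) / 1.5, 0.01)
})

test_that("too few shared usable variants is a rescale error", {
  act <- stats::setNames(exp(seq(4, 8, length.out = 30)), paste0("sg", 1:30))
  fits <- make_fits(list(rep1 = act, rep3 = act))
  fits$usable[fits$replicate_id == "rep1"][1:25] <- FALSE
  expect_error(fit_rescale(fits, "rep3"), "rep1")
})

test_that("aggregation computes M, S, n and applies the consistency filter", {
  lib <- data.frame(sgrna_id = c("sgX", "sgY", "NC_01"),
                    target_tf = c("tfX", "tfY", ""),
                    is_control = c(FALSE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  fits <- make_fits(list(
    rep1 = c(sgX = exp(1.0), sgY = exp(1.0), NC_01 = exp(2)),
    rep2 = c(sgX = exp(1.1), sgY = exp(2.0), NC_01 = exp(2)),
    rep3 = c(sgX = exp(1.2), sgY = exp(3.0), NC_01 = exp(2))))
  maps <- data.frame(replicate_id = c("rep1", "rep2", "rep3"),
                     slope = 1, intercept = 0,
                     reference_replicate = "rep3", n_shared = 3,
                     stringsAsFactors = FALSE)
  agg <- aggregate_activity(apply_rescale(fits, maps), lib)
  x <- agg[agg$sgrna_id == "sgX", ]
  expect_equal(x$M, 1.1)
  expect_equal(x$S, 0.1, tolerance = 1e-12)
  expect_equal(x$n, 3)
  expect_false(x$excluded)
  # sgY spans a full log unit between replicates: S = 1 > 0.7
  y <- agg[agg$sgrna_id == "sgY", ]
  expect_true(y$excluded)
  expect_identical(y$exclude_reason, "high_S")
})

test_that("a variant usable in one replicate cannot enter the Z-test", {
  lib <- data.frame(sgrna_id = c("sgX", "NC_01", "NC_02"),
                    target_tf = c("tfX", "", ""),
                    is_control = c(FALSE, TRUE, TRUE),
                    stringsAsFactors = FALSE)
  acts <- c(sgX = exp(1), NC_01 = exp(2), NC_02 = exp(3))
  fits <- make_fits(list(rep1 = acts, rep2 = acts))
  fits$usable[fits$sgrna_id == "sgX" & fits$replicate_id == "rep2"] <- FALSE
  maps <- fit_rescale(fits, "rep1", min_shared = 2)
  agg <- aggregate_activity(apply_rescale(fits, maps), lib)
  x <- agg[agg$sgrna_id == "sgX", ]
  expect_equal(x$n, 1)
  expect_true(x$excluded)
  expect_identical(x$exclude_reason, "insufficient_n")
})

test_that("control pooling removes interquartile-range outliers", {
  lib <- data.frame(sgrna_id = c("sgX", paste0("NC_0", 1:5)),
                    target_tf = c("tfX", rep("", 5)),
                    is_control = c(FALSE, rep(TRUE, 5)),
                    stringsAsFactors = FALSE)
  # one replicate; controls pooled as independent samples (2,2,2,2,50):
  # Q1 = Q3 = 2, IQR = 0, so 50 is fenced out
  acts <- c(sgX = exp(2), NC_01 = exp(2), NC_02 = exp(2), NC_03 = exp(2),
            NC_04 = exp(2), NC_05 = exp(50))
  fits <- make_fits(list(rep1 = acts, rep2 = acts))
  maps <- fit_rescale(fits, "rep1", min_shared = 1)
  agg <- aggregate_activity(apply_rescale(fits, maps), lib)
  ctrl <- agg[agg$role == "control", ]
  expect_equal(ctrl$M, 2)
  expect_equal(ctrl$n, 8)  # 4 sgRNAs x 2 replicates survive
})

test_that("a named misbehaving control is dropped from the pools", {
  lib <- data.frame(sgrna_id = c("sgX", paste0("NC_0", 1:2)),
                    target_tf = c("tfX", "", ""),
                    is_control = c(FALSE, TRUE, TRUE),
                    stringsAsFactors = FALSE)
  acts <- c(sgX = exp(2), NC_01 = exp(2), NC_02 = exp(5))
  fits <- make_fits(list(rep1 = acts, rep2 = acts))
  maps <- fit_rescale(fits, "rep1", min_shared = 1)
  agg <- aggregate_activity(apply_rescale(fits, maps), lib,
                            controls_exclude = "NC_02")
  ctrl <- agg[agg$role == "control", ]
  expect_equal(ctrl$M, 2)
  expect_equal(ctrl$n, 2)
})

test_that("the fence rule never strips more than half of a clean pool", {
  set.seed(101)
  for (k in 1:50) {
    pool <- rnorm(12, 5, 0.2)
    expect_gte(sum(pptpseq:::iqr_keep(pool)), 6)
  }
})
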