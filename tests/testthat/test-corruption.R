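one_class <- function(m) {
  stats::setNames(rep("A", nrow(m)), rownames(m))
}

test_that("dropout injection hits the target sparsity exactly on a counting example", {
  m <- matrix(c(0, 0, rep(1:5, 2)), 3, 4,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  out <- add_dropouts(m, one_class(m), f = 0.5, seed = 1)
  expect_equal(sum(out == 0), 6)  # round(0.5 * 12)
  expect_true(all(out[m == 0] == 0))          # original zeros preserved
  expect_true(all(out[out != 0] == m[out != 0]))  # survivors unchanged
})

test_that("a class already sparser than the target is returned unchanged with a warning", {
  m <- matrix(c(rep(0, 8), 1:4), 3, 4,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  expect_gt(zero_fraction(m), 0.5)
  expect_warning(out <- add_dropouts(m, one_class(m), f = 0.5, seed = 1),
                 "unchanged")
  expect_identical(unname(out[, ]), unname(m[, ]))
})

test_that("dropout calibration is per class and matches f within rounding", {
  sim <- small_sim(n = 200, g = 300, seed = 13)
  lab <- true_labels(sim)
  out <- add_dropouts(sim$counts, sim$annotation, f = 0.8, seed = 2)
  for (cls in unique(lab)) {
    sub <- out[lab == cls, ]
    expect_equal(sum(sub == 0) / length(sub), 0.8,
                 tolerance = 1 / length(sub) + 1e-12)
  }
  expect_equal(zero_fraction(out), 0.8, tolerance = 1e-3)
  # zeros are a superset of the input zeros
  expect_true(all(out[sim$counts == 0] == 0))
})

test_that("low-expression entries drop preferentially", {
  sim <- simulate_baseline(simulation_params(
    500, 500, tree = cell_type_tree(data.frame(parent = "r", child = c("a", "b"),
                                               branch_weight = 1)),
    seed = 17))
  out <- add_dropouts(sim$counts, sim$annotation, f = 0.75, seed = 4)
  newly_zero <- sim$counts[sim$counts != 0 & out == 0]
  survived <- sim$counts[out != 0]
  expect_lt(mean(newly_zero), mean(survived))
  p <- wilcox.test(newly_zero, survived, alternative = "less")$p.value
  expect_lt(p, 0.01)
})

test_that("f = 1 zeroes everything and seeded dropout is deterministic", {
  sim <- small_sim(n = 60, g = 80, seed = 3)
  all0 <- add_dropouts(sim$counts, sim$annotation, f = 1, seed = 5)
  expect_equal(zero_fraction(all0), 1)
  a <- add_dropouts(sim$counts, sim$annotation, f = 0.7, seed = 5)
  b <- add_dropouts(sim$counts, sim$annotation, f = 0.7, seed = 5)
  expect_identical(a, b)
})

test_that("binomial thinning: identity at 1, zero stays zero, mean scales", {
  m <- matrix(c(0L, 4L, 10L, 2L), 2, 2,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  expect_identical(downsample_depth(m, 1, seed = 1), m)
  z <- matrix(0, 3, 3, dimnames = list(paste0("c", 1:3), paste0("g", 1:3)))
  expect_true(all(downsample_depth(z, 0.4, seed = 1) == 0))
  expect_error(downsample_depth(m / 3, 0.5), "integer")

  big <- matrix(10L, 100, 100,
                dimnames = list(sprintf("c%d", 1:100), sprintf("g%d", 1:100)))
  thin <- downsample_depth(big, 0.3, seed = 9)
  se <- sqrt(10 * 0.3 * 0.7 / length(big))
  expect_lt(abs(mean(thin) - 3), 3 * se)
  expect_true(all(thin <= big))
})

test_that("noise models: p = 0 identity, model 3 draws from the cell's own values", {
  sim <- small_sim(n = 40, g = 60, seed = 8)
  for (mod in 1:3) {
    out <- add_noise(sim$counts, mod, p = 0, seed = 2)
    expect_equal(unname(out[, ]), unname(sim$counts[, ]))
  }
  out3 <- add_noise(sim$counts, 3, p = 0.6, seed = 2)
  for (i in seq_len(nrow(out3))) {
    expect_true(all(out3[i, ] %in% sim$counts[i, ]))
  }
  expect_error(add_noise(sim$counts, 9, p = 0.1), "model")
})

test_that("noise model 1 at p = 1 perturbs with half-normal magnitude", {
  m <- matrix(5, 200, 200,
              dimnames = list(sprintf("c%d", 1:200), sprintf("g%d", 1:200)))
  sigma <- 0.5
  out <- add_noise(m, 1, p = 1, seed = 11, sigma1 = sigma)
  expect_gt(mean(out != m), 0.999)  # a Normal draw is almost never exactly 0
  pert <- abs(out - m)
  half_normal_mean <- sigma * sqrt(2 / pi)
  se <- sigma * sqrt((1 - 2 / pi) / length(m))
  expect_lt(abs(mean(pert) - half_normal_mean), 3 * se)
})

test_that("noise model 2 adds per-gene scaled noise and keeps nonnegativity", {
  sim <- small_sim(n = 80, g = 100, seed = 12)
  out <- add_noise(sim$counts, 2, p = 0.5, seed = 3)
  expect_true(min(out) >= 0)
  expect_equal(dim(out), dim(sim$counts))
  # high-mean genes receive bigger average shifts than near-silent genes
  mu_g <- colMeans(sim$counts)
  shift <- colMeans(abs(out - sim$counts))
  hi <- mu_g >= quantile(mu_g, 0.8); lo <- mu_g <= quantile(mu_g, 0.2)
  expect_gt(mean(shift[hi]), mean(shift[lo]))
})

test_that("all corruption operators preserve shape, ids and nonnegativity", {
  sim <- small_sim(n = 50, g = 70, seed = 14)
  lab <- sim$annotation
  outs <- list(
    add_dropouts(sim$counts, lab, 0.8, seed = 1),
    downsample_depth(sim$counts, 0.5, seed = 1),
    add_noise(sim$counts, 1, 0.4, seed = 1),
    add_noise(sim$counts, 2, 0.4, seed = 1),
    add_noise(sim$counts, 3, 0.4, seed = 1)
  )
  for (out in outs) {
    expect_equal(dimnames(out), dimnames(sim$counts))
    expect_true(min(out) >= 0)
  }
  # dispatch wrapper reaches every kind
  for (kind in c("dropout_expression", "dropout_depth", "noise1", "noise2", "noise3")) {
    expect_silent(suppressWarnings(
      apply_corruption(sim$counts, lab, kind, 0.5, seed = 2)))
  }
  expect_error(apply_corruption(sim$counts, lab, "nope", 0.5), "unknown")
})
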