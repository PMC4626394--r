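test_that("crude proportions are group counts over the total", {
  # the published sample: 277 lifetime users of 1115
  recs <- data.frame(pid = paste0("p", 1:1115),
                     `trait:any:lifetime` = rep(c(1, 0), c(277, 838)),
                     check.names = FALSE)
  part <- trait_partition(recs, "trait:any:lifetime")
  cp <- crude_proportion(recs, part)
  expect_equal(cp$proportion[cp$group == "user"], 277 / 1115)
  expect_equal(round(277 / 1115, 4), 0.2484)
  expect_equal(sum(cp$proportion), 1)

  one <- crude_proportion(recs[1:5, ], factor(rep("user", 5)))
  expect_equal(one$proportion, 1)
  even <- crude_proportion(recs[1:10, ], factor(rep(c("user", "non-user"), 5)))
  expect_equal(even$proportion, c(0.5, 0.5))
  expect_error(crude_proportion(recs[0, ], factor(character(0))),
               class = "rds_insufficient_data")
})

test_that("harmonic-mean degrees follow n / sum(1/d) with exclusions", {
  mk <- function(degs, grp = rep("g", length(degs))) {
    recs <- data.frame(pid = as.character(seq_along(degs)), degree = degs)
    part <- factor(grp); names(part) <- recs$pid
    harmonic_mean_degrees(recs, part)
  }
  expect_equal(mk(c(2, 2, 2))$D, 2)
  expect_equal(mk(c(1, 4))$D, 1.6)
  expect_message(mk(c(3, 0)), "excluded")
  res <- suppressMessages(mk(c(3, 0)))
  expect_equal(res$D, 3)
  expect_equal(res$n_excluded, 1L)
  expect_error(mk(c(0, 0)), class = "rds_insufficient_data")

  # arithmetic mean behind the sensitivity flag
  recs <- data.frame(pid = c("1", "2"), degree = c(1, 4))
  part <- factor(c("g", "g")); names(part) <- recs$pid
  expect_equal(harmonic_mean_degrees(recs, part, "arithmetic")$D, 2.5)
})

test_that("RDS adjustment reweights the equilibrium by inverse mean degree", {
  # equal degrees leave the equilibrium untouched
  S <- matrix(c(2/3, 1/3, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  tm <- structure(list(groups = c("A", "B"), S = S,
                       counts = S, zero_rows = character(0), smoothing = FALSE),
                  class = "rds_transition")
  degs <- data.frame(group = c("A", "B"), D = c(2, 2), n = c(5, 5), n_excluded = 0)
  expect_equal(rds_adjusted_proportion(tm, degs)$proportion, c(0.75, 0.25))

  # two-group closed form: S_AB = S_BA = 0.5, D_A = 4, D_B = 1 -> P_A = 0.2
  S5 <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tm5 <- structure(list(groups = c("A", "B"), S = S5, counts = S5,
                        zero_rows = character(0), smoothing = FALSE),
                   class = "rds_transition")
  degs5 <- data.frame(group = c("A", "B"), D = c(4, 1), n = c(5, 5), n_excluded = 0)
  expect_equal(rds_adjusted_proportion(tm5, degs5)$proportion[1], 0.2)
})

test_that("multi-group formula equals the two-group closed form (property)", {
  set.seed(41)
  for (i in 1:100) {
    S <- random_stochastic(2)
    D <- stats::runif(2, 0.5, 30)
    tm <- structure(list(groups = rownames(S), S = S, counts = S,
                         zero_rows = character(0), smoothing = FALSE),
                    class = "rds_transition")
    degs <- data.frame(group = rownames(S), D = D, n = 1, n_excluded = 0)
    got <- rds_adjusted_proportion(tm, degs)$proportion[1]
    closed <- S[2, 1] * D[2] / (S[1, 2] * D[1] + S[2, 1] * D[2])
    expect_equal(got, closed, tolerance = 1e-12)
  }
})

test_that("Wald z and p follow the normal contrast", {
  expect_equal(wald_test(0.3, 0.05, 0.3, 0.05)$z, 0)
  expect_equal(wald_test(0.3, 0.05, 0.3, 0.05)$p_value, 1)
  wt <- wald_test(0.3, 0.05, 0.1, 0.05)
  expect_equal(wt$z, 2.828, tolerance = 1e-3)
  expect_equal(wt$p_value, 2 * pnorm(-abs(wt$z)))
  expect_equal(wt$p_value, 0.0047, tolerance = 5e-3)
  flip <- wald_test(0.1, 0.05, 0.3, 0.05)
  expect_equal(flip$z, -wt$z)
  expect_equal(flip$p_value, wt$p_value)
  expect_error(wald_test(0.3, 0, 0.1, 0.05), class = "rds_undefined_test")
})

test_that("prevalence ratios round half away from zero like printed tables", {
  expect_equal(prevalence_ratio(16.3, 5.7), 2.9)
  expect_equal(prevalence_ratio(10.2, 2.7), 3.8)
  expect_equal(prevalence_ratio(5, 5), 1.0)
  # half-away cases where round-half-even would differ
  expect_equal(prevalence_ratio(6.1, 2.0), 3.1)
  expect_equal(prevalence_ratio(4.9, 2.0), 2.5)
  expect_error(prevalence_ratio(1, 0), class = "rds_undefined_ratio")
})
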