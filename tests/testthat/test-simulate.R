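test_that("the default scenario encodes the emulated study design", {
  cfg <- scenario_default()
  expect_equal(cfg$seeds_community + cfg$seeds_hospital, 47)
  expect_equal(cfg$seeds_community, 35)
  expect_equal(cfg$seeds_hospital, 12)
  expect_equal(sum(cfg$target_n), 1115)
  expect_equal(cfg$target_n, c(144, 328, 350, 293))
  expect_equal(cfg$max_waves, 8)
  expect_true(all(cfg$coupon_probs[2:4] >= cfg$coupon_probs[c(1, 5, 6)]))
})

test_that("population generation is reproducible and matches its marginals", {
  cfg <- sim_config(population_size = 5000, homophily_user_odds = 1,
                    homophily_stratum_odds = 1, p_user = c(early = 0.2, late = 0.2))
  p1 <- generate_population(cfg, seed = 4)
  p2 <- generate_population(cfg, seed = 4)
  expect_identical(p1$members, p2$members)
  expect_identical(p1$adjacency, p2$adjacency)

  # user frequency 0.2 within ~3 binomial SDs
  f <- mean(p1$members$user)
  expect_lt(abs(f - 0.2), 3 * sqrt(0.2 * 0.8 / 5000) + 0.005)
  # stratum marginal
  expect_lt(abs(mean(p1$members$stratum == "early") - cfg$p_early), 0.03)
  # past-year implies lifetime for every drug
  for (d in c("ketamine", "heroin")) {
    expect_true(all(p1$members[[sprintf("trait:%s:past_year", d)]] <=
                      p1$members[[sprintf("trait:%s:lifetime", d)]]))
  }
})

test_that("homophily odds of 1 give equal within/between tie rates", {
  cfg <- sim_config(population_size = 4000, homophily_user_odds = 1,
                    homophily_stratum_odds = 1, p_user = c(early = 0.3, late = 0.3),
                    degree_user_multiplier = 1)
  pop <- generate_population(cfg, seed = 8)
  u <- pop$members$user
  # count edges by type
  within <- 0; between <- 0
  for (i in seq_along(pop$adjacency)) {
    nb <- pop$adjacency[[i]]
    nb <- nb[nb > i]
    within <- within + sum(u[nb] == u[i])
    between <- between + sum(u[nb] != u[i])
  }
  # expected between fraction 2 p (1-p) with p the user mass share
  p <- mean(u)
  exp_between <- 2 * p * (1 - p)
  got_between <- between / (within + between)
  expect_lt(abs(got_between - exp_between), 0.03)
})

test_that("strong homophily raises the within-group tie share", {
  base <- sim_config(population_size = 4000, homophily_user_odds = 1,
                     homophily_stratum_odds = 1)
  homo <- sim_config(population_size = 4000, homophily_user_odds = 6,
                     homophily_stratum_odds = 1)
  share <- function(cfg, seed) {
    pop <- generate_population(cfg, seed = seed)
    u <- pop$members$user
    w <- 0; b <- 0
    for (i in seq_along(pop$adjacency)) {
      nb <- pop$adjacency[[i]]; nb <- nb[nb > i]
      w <- w + sum(u[nb] == u[i]); b <- b + sum(u[nb] != u[i])
    }
    w / (w + b)
  }
  expect_gt(share(homo, 3), share(base, 3) + 0.05)
})

test_that("recruitment respects coupons, waves and the no-duplicate contract", {
  cfg <- test_scenario()
  sim <- simulate_study(cfg, seed = 14)
  f <- sim$forest
  expect_lte(max(table(f$edges$recruiter)), 5)
  expect_lte(max(f$nodes$wave), cfg$max_waves)
  # no member recruited twice within any round (rounds are independent draws)
  for (r in sim$rounds)
    expect_equal(anyDuplicated(r$records$member), 0L)
})

test_that("coupon count of zero leaves only isolated seeds", {
  cfg <- test_scenario(coupon_probs = c(1, 0, 0, 0, 0, 0))
  pop <- generate_population(cfg, seed = 5)
  expect_warning(out <- simulate_rds(pop, cfg, target_n = 100, seed = 6),
                 "exhausted")
  expect_equal(nrow(out$forest$edges), 0L)
  expect_equal(length(out$forest$roots), nrow(out$records))
})

test_that("a line-graph population with one seed yields a single chain", {
  # hand-built population: path 1-2-3-...-12
  cfg <- sim_config(population_size = 12, seeds_community = 1,
                    seeds_hospital = 0,
                    coupon_probs = c(0, 1, 0, 0, 0, 0), max_waves = 20,
                    target_n = 12)
  pop <- generate_population(cfg, seed = 1)
  n <- 12
  pop$adjacency <- c(list(2L), lapply(2:(n - 1), function(i) c(i - 1L, i + 1L)),
                     list(n - 1L))
  pop$members$degree <- lengths(pop$adjacency)
  out <- suppressWarnings(simulate_rds(pop, cfg, target_n = n, seed = 2))
  f <- out$forest
  # one coupon each: every recruiter has exactly one recruit (a chain)
  expect_lte(max(table(f$edges$recruiter)), 1)
  member_by_pid <- out$records$member[match(f$nodes$pid, out$records$pid)]
  seed_member <- member_by_pid[f$nodes$wave == 0]
  expect_equal(f$nodes$wave, abs(member_by_pid - seed_member))
})

test_that("wave numbers in emitted codes equal graph distance from the seed", {
  cfg <- test_scenario()
  sim <- simulate_study(cfg, seed = 21)
  f <- sim$forest
  # BFS over the referral edges is the independent distance oracle
  dist <- stats::setNames(rep(NA_integer_, nrow(f$nodes)), f$nodes$pid)
  dist[f$roots] <- 0L
  frontier <- f$roots
  while (length(frontier)) {
    nxt <- f$edges$recruit[f$edges$recruiter %in% frontier]
    dist[nxt] <- dist[f$edges$recruiter[match(nxt, f$edges$recruit)]] + 1L
    frontier <- nxt
  }
  expect_equal(unname(dist[f$nodes$pid]), f$nodes$wave)
})

test_that("most recruiters hand on one to three recruits in the default design", {
  set.seed(71)
  shares <- numeric(20)
  cfg <- test_scenario()
  for (i in 1:20) {
    sim <- simulate_study(cfg)
    kids <- table(sim$forest$edges$recruiter)
    shares[i] <- mean(kids >= 1 & kids <= 3)
  }
  expect_gt(mean(shares), 0.85)
  # and the mean number of recruits per recruiter sits in [1, 3]
  sim <- simulate_study(cfg, seed = 77)
  kids <- table(sim$forest$edges$recruiter)
  expect_gte(mean(kids), 1)
  expect_lte(mean(kids), 3)
})

test_that("hospital seeds are enriched for hard-drug users", {
  cfg <- test_scenario(seeds_community = 20, seeds_hospital = 20)
  set.seed(81)
  pop <- generate_population(cfg)
  hard_rate <- numeric(0)
  for (i in 1:10) {
    out <- simulate_rds(pop, cfg, target_n = 45)
    seeds <- out$records[grepl("-0+$", out$records$code), ]
    hosp <- seeds[seeds$seed_source == "hospital", ]
    comm <- seeds[seeds$seed_source == "community", ]
    hard <- function(df) mean(df[["trait:methamphetamine:lifetime"]] |
                                df[["trait:heroin:lifetime"]])
    hard_rate <- rbind(hard_rate, c(hard(hosp), hard(comm)))
  }
  expect_gt(mean(hard_rate[, 1]), mean(hard_rate[, 2]))
})
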