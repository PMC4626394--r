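#' Simulation configuration for synthetic chain-referral studies
#'
#' Bundles every knob of the synthetic generator: population size, the
#' two-stratum trait model (tobacco-onset stratum probability, per-drug
#' lifetime prevalence conditional on stratum and being a drug user,
#' past-year probability conditional on lifetime use), the degree model, the
#' block homophily odds, seed counts and sources, the coupon (referral count)
#' distribution, wave cap and per-round target sample sizes.
#'
#' @param population_size number of members of the hidden population network.
#' @param p_early probability of the early-onset (< 18 y) smoking stratum.
#' @param p_user named vector: probability of any lifetime illegal-drug use
#'   by stratum (`early`, `late`).
#' @param drug_given_user matrix (drugs x strata) of per-drug lifetime use
#'   probability conditional on being a user; drugs in rows.
#' @param pastyear_given_lifetime named vector per drug.
#' @param degree_meanlog,degree_sdlog log-normal reported-degree model.
#' @param degree_user_multiplier multiplicative degree factor for drug users
#'   (differential visibility in the substance-using network).
#' @param degree_noise_sdlog sd of multiplicative log-normal reporting noise
#'   on degrees (0 = report true degree).
#' @param homophily_user_odds within- vs between-group tie odds for the
#'   user/non-user split (1 = no homophily).
#' @param homophily_stratum_odds same for the onset stratum.
#' @param seeds_community,seeds_hospital seed counts by source.
#' @param hospital_enrichment sampling-weight multiplier for hard-drug users
#'   when drawing hospital (drug-rehabilitation) seeds.
#' @param coupon_probs probability of handing out 0..5 successful referrals.
#' @param recruit_preference relative odds that a user recruits a non-user
#'   neighbor over a user neighbor (1 = uniform random recruitment; > 1
#'   models masking).
#' @param max_waves recruitment depth cap.
#' @param target_n total recruits wanted, either a single number or a vector
#'   of per-round (yearly) targets.
#' @param years labels for the rounds (recycled to `length(target_n)`).
#' @return a `sim_config` list.
#' @seealso [scenario_default()], [generate_population()], [simulate_study()]
#' @export
sim_config <- function(population_size = 5000,
                       p_early = 0.58,
                       p_user = c(early = 0.318, late = 0.152),
                       drug_given_user = default_drug_given_user(),
                       pastyear_given_lifetime = c(ketamine = 0.41,
                                                   ecstasy = 0.36,
                                                   marijuana = 0.37,
                                                   methamphetamine = 0.37,
                                                   heroin = 0.51),
                       degree_meanlog = log(10) - 0.32,
                       degree_sdlog = 0.8,
                       degree_user_multiplier = 1.3,
                       degree_noise_sdlog = 0,
                       homophily_user_odds = 2,
                       homophily_stratum_odds = 1.3,
                       seeds_community = 35, seeds_hospital = 12,
                       hospital_enrichment = 20,
                       coupon_probs = c(0.10, 0.35, 0.30, 0.20, 0.03, 0.02),
                       recruit_preference = 1,
                       max_waves = 8,
                       target_n = c(144, 328, 350, 293),
                       years = 2007:2010) {
  stopifnot(length(coupon_probs) == 6L, all(coupon_probs >= 0),
            abs(sum(coupon_probs) - 1) < 1e-8,
            p_early >= 0, p_early <= 1, all(p_user >= 0 & p_user <= 1),
            seeds_community + seeds_hospital <= population_size,
            homophily_user_odds > 0, homophily_stratum_odds > 0)
  cfg <- list(population_size = population_size, p_early = p_early,
              p_user = p_user, drug_given_user = drug_given_user,
              pastyear_given_lifetime = pastyear_given_lifetime,
              degree_meanlog = degree_meanlog, degree_sdlog = degree_sdlog,
              degree_user_multiplier = degree_user_multiplier,
              degree_noise_sdlog = degree_noise_sdlog,
              homophily_user_odds = homophily_user_odds,
              homophily_stratum_odds = homophily_stratum_odds,
              seeds_community = seeds_community,
              seeds_hospital = seeds_hospital,
              hospital_enrichment = hospital_enrichment,
              coupon_probs = coupon_probs,
              recruit_preference = recruit_preference,
              max_waves = max_waves,
              target_n = target_n,
              years = rep_len(years, length(target_n)))
  class(cfg) <- "sim_config"
  cfg
}

## per-drug lifetime use probability conditional on stratum and on being a
## lifetime user of anything; magnitudes follow the stratified composition
## of the Taipei regular tobacco/alcohol-user survey this design emulates
default_drug_given_user <- function() {
  m <- cbind(early = c(0.61, 0.51, 0.50, 0.31, 0.17),
             late  = c(0.52, 0.58, 0.68, 0.21, 0.13))
  rownames(m) <- c("ketamine", "ecstasy", "marijuana", "methamphetamine", "heroin")
  m
}

#' Default study scenario
#'
#' The study design this package emulates: 47 seeds (35 community, 12 from
#' hospital drug-rehabilitation programs), up to five referral coupons with
#' most respondents referring one to three, a cap of 8 recruitment waves,
#' and four yearly rounds targeting 144, 328, 350 and 293 recruits (1115 in
#' total) on the same population. Any field can be overridden.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @examples
#' cfg <- scenario_default()
#' sum(cfg$target_n)  # 1115
#' @export
scenario_default <- function(...) {
  over <- list(...)
  ## alias: a scalar target_n overrides the yearly split with a single round
  do.call(sim_config, utils::modifyList(list(population_size = 20000), over))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Chain-referral simulation config: population %d, ",
                     "%d+%d seeds (community+hospital), %d round(s) targeting %s, ",
                     "max %d waves\n"),
              x$population_size, x$seeds_community, x$seeds_hospital,
              length(x$target_n), paste(x$target_n, collapse = "/"),
              x$max_waves))
  invisible(x)
}

#' Generate a synthetic hidden-population network
#'
#' Members carry an onset stratum, per-drug lifetime and past-year traits
#' (drawn hierarchically: stratum, then any-use, then drugs conditional on
#' use with at least one drug forced, then past-year conditional on
#' lifetime), and a target degree. Ties are sampled by a fast weighted
#' Chung-Lu scheme inside a block homophily model over
#' user/non-user x stratum blocks: the expected number of ties between two
#' blocks is proportional to the product of their degree masses times the
#' homophily odds, and tie endpoints are drawn proportional to member degree
#' weights. Duplicate ties and self-loops are discarded.
#'
#' @param config a `sim_config`.
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @return a `population_network`: list with `members` (data frame) and
#'   `adjacency` (list of integer neighbor vectors).
#' @export
generate_population <- function(config, seed = NULL) {
  with_seed(seed, generate_population_impl(config))
}

generate_population_impl <- function(cfg) {
  n <- cfg$population_size
  stratum <- ifelse(stats::runif(n) < cfg$p_early, "early", "late")
  user <- stats::runif(n) < cfg$p_user[stratum]
  drugs <- rownames(cfg$drug_given_user)
  traits_l <- matrix(0L, n, length(drugs), dimnames = list(NULL, drugs))
  idx_user <- which(user)
  if (length(idx_user)) {
    pm <- t(cfg$drug_given_user[, ifelse(stratum[idx_user] == "early", 1L, 2L)])
    draw <- matrix(stats::runif(length(idx_user) * length(drugs)),
                   ncol = length(drugs)) < pm
    none <- rowSums(draw) == 0L
    while (any(none)) {   # a "user" uses at least one drug: redraw
      draw[none, ] <- matrix(stats::runif(sum(none) * length(drugs)),
                             ncol = length(drugs)) < pm[none, , drop = FALSE]
      none <- rowSums(draw) == 0L
    }
    traits_l[idx_user, ] <- draw * 1L
  }
  traits_p <- traits_l
  for (d in drugs) {
    traits_p[, d] <- traits_l[, d] *
      (stats::runif(n) < cfg$pastyear_given_lifetime[d])
  }
  w <- stats::rlnorm(n, cfg$degree_meanlog, cfg$degree_sdlog)
  w <- pmax(w, 1) * ifelse(user, cfg$degree_user_multiplier, 1)

  block <- paste0(ifelse(user, "u", "n"), ".", stratum)
  blocks <- sort(unique(block))
  bu <- substr(blocks, 1L, 1L)
  bs <- substr(blocks, 3L, 7L)
  theta <- outer(seq_along(blocks), seq_along(blocks), function(i, j) {
    ifelse(bu[i] == bu[j], cfg$homophily_user_odds, 1) *
      ifelse(bs[i] == bs[j], cfg$homophily_stratum_odds, 1)
  })
  Wg <- vapply(blocks, function(b) sum(w[block == b]), 0)
  Stot <- sum(w)
  Z <- sum(outer(Wg, Wg) * theta) / Stot^2   # keeps overall mean degree on target
  by_block <- split(seq_len(n), block)
  edges_a <- integer(0); edges_b <- integer(0)
  for (i in seq_along(blocks)) for (j in i:length(blocks)) {
    lam <- theta[i, j] * Wg[i] * Wg[j] / (Stot * Z)
    if (i == j) lam <- lam / 2
    m <- stats::rpois(1L, lam)
    if (m == 0L) next
    ia <- by_block[[i]]; ib <- by_block[[j]]
    ea <- ia[sample.int(length(ia), m, replace = TRUE, prob = w[ia])]
    eb <- ib[sample.int(length(ib), m, replace = TRUE, prob = w[ib])]
    keep <- ea != eb
    edges_a <- c(edges_a, ea[keep]); edges_b <- c(edges_b, eb[keep])
  }
  lo <- pmin(edges_a, edges_b); hi <- pmax(edges_a, edges_b)
  dup <- duplicated(lo * (n + 1) + hi)
  lo <- lo[!dup]; hi <- hi[!dup]
  adjacency <- split(c(hi, lo), factor(c(lo, hi), levels = seq_len(n)))
  names(adjacency) <- NULL
  members <- data.frame(
    member = seq_len(n), stratum = stratum, user = user * 1L,
    degree = lengths(adjacency),
    age = sample(18:50, n, replace = TRUE),
    sex = ifelse(stats::runif(n) < 0.57, "M", "F"),
    stringsAsFactors = FALSE)
  for (d in drugs) {
    members[[trait_col(d, "lifetime")]] <- traits_l[, d]
    members[[trait_col(d, "past_year")]] <- traits_p[, d]
  }
  structure(list(members = members, adjacency = adjacency, config = cfg),
            class = "population_network")
}

#' @export
print.population_network <- function(x, ...) {
  cat(sprintf("Synthetic population network: %d members, %d ties, mean degree %.1f\n",
              nrow(x$members), sum(x$members$degree) / 2,
              mean(x$members$degree)))
  invisible(x)
}

#' Simulate one chain-referral (RDS) round on a population
#'
#' Implements the field procedure: seeds are drawn by source (hospital seeds
#' oversample hard-drug users by `hospital_enrichment`), every respondent
#' draws a referral count from the coupon distribution and recruits that
#' many uniformly-chosen eligible, not-yet-recruited neighbors; recruitment
#' proceeds wave by wave until the target sample size or the wave cap is
#' reached. Referral codes in the `F001-...` dialect are emitted, waves equal
#' tree distance from the seed, and the reported degree is the true network
#' degree (optionally noised).
#'
#' @param population a `population_network`.
#' @param config a `sim_config` (defaults to the population's).
#' @param target_n recruits wanted for this round (default: first element of
#'   the config's target).
#' @param year round label stamped on the records.
#' @param seed optional RNG seed.
#' @param seed_labels optional character vector of seed labels to use (one
#'   per seed); generated from the source mix when omitted.
#' @param exclude member ids that may not be recruited (used when pooling
#'   rounds without replacement across the whole study).
#' @return list with `records` (participant data frame) and `forest`.
#' @export
simulate_rds <- function(population, config = population$config,
                         target_n = config$target_n[1L],
                         year = config$years[1L], seed = NULL,
                         seed_labels = NULL, exclude = integer(0)) {
  with_seed(seed, simulate_rds_impl(population, config, target_n, year,
                                    seed_labels, exclude))
}

simulate_rds_impl <- function(pop, cfg, target_n, year, seed_labels, exclude) {
  mem <- pop$members
  adj <- pop$adjacency
  n_pop <- nrow(mem)
  hard <- (mem[[trait_col("methamphetamine", "lifetime")]] |
             mem[[trait_col("heroin", "lifetime")]]) * 1L
  connected <- mem$degree >= 1
  avail <- connected
  avail[exclude] <- FALSE

  n_seeds <- cfg$seeds_community + cfg$seeds_hospital
  src <- c(rep("community", cfg$seeds_community),
           rep("hospital", cfg$seeds_hospital))
  w_comm <- as.numeric(avail)
  w_hosp <- w_comm * ifelse(hard == 1L, cfg$hospital_enrichment, 1)
  seeds <- integer(0)
  for (s in src) {
    wgt <- if (s == "hospital") w_hosp else w_comm
    wgt[seeds] <- 0
    if (sum(wgt > 0) == 0L)
      rds_stop("rds_config_error", "not enough eligible members to seed")
    seeds <- c(seeds, sample.int(n_pop, 1L, prob = wgt))
  }
  if (is.null(seed_labels)) {
    seed_labels <- sprintf("%s%03d", ifelse(src == "hospital", "H", "F"),
                           seq_len(n_seeds))
  }
  stopifnot(length(seed_labels) == n_seeds)

  width <- max(10L, cfg$max_waves)
  recruited <- logical(n_pop)
  recruited[seeds] <- TRUE
  member_id <- seeds
  codes <- paste0(seed_labels, "-", strrep("0", width))
  waves <- rep(0L, n_seeds)
  sources <- src
  queue <- seq_len(n_seeds)          # indices into the sample being built
  total <- n_seeds
  exhausted <- FALSE
  qi <- 1L
  ## target_n counts participants in the round, seeds included
  while (qi <= length(queue)) {
    cur <- queue[qi]; qi <- qi + 1L
    if (total >= target_n) break
    if (waves[cur] >= cfg$max_waves) next
    m <- member_id[cur]
    coup <- sample.int(6L, 1L, prob = cfg$coupon_probs) - 1L
    if (coup == 0L) next
    nb <- adj[[m]]
    nb <- nb[avail[nb] & !recruited[nb]]
    if (length(nb) == 0L) next
    k_take <- min(coup, length(nb), 5L, target_n - total)
    if (k_take <= 0L) break
    if (cfg$recruit_preference != 1 && mem$user[m] == 1L) {
      pref <- ifelse(mem$user[nb] == 1L, 1, cfg$recruit_preference)
      take <- nb[sample.int(length(nb), k_take, prob = pref)]
    } else {
      take <- nb[sample.int(length(nb), k_take)]
    }
    parent_path <- substr(codes[cur], 6L, 5L + width)
    for (j in seq_along(take)) {
      child_path <- parent_path
      substr(child_path, waves[cur] + 1L, waves[cur] + 1L) <- as.character(j)
      total <- total + 1L
      recruited[take[j]] <- TRUE
      member_id[total] <- take[j]
      codes[total] <- paste0(substr(codes[cur], 1L, 4L), "-", child_path)
      waves[total] <- waves[cur] + 1L
      sources[total] <- sources[cur]
      queue[length(queue) + 1L] <- total
    }
  }
  if (total < target_n)
    warning(sprintf("network exhausted: achieved %d of %d target participants",
                    total, target_n), call. = FALSE)
  deg_rep <- mem$degree[member_id]
  if (cfg$degree_noise_sdlog > 0)
    deg_rep <- pmax(1, round(deg_rep *
      stats::rlnorm(total, -cfg$degree_noise_sdlog^2 / 2, cfg$degree_noise_sdlog)))
  records <- data.frame(
    pid = sprintf("Y%s-%05d", year, member_id),
    code = codes, year = year, seed_source = sources,
    age = mem$age[member_id], sex = mem$sex[member_id],
    onset_stratum = mem$stratum[member_id],
    degree = deg_rep, member = member_id,
    stringsAsFactors = FALSE)
  for (tc in grep("^trait:", names(mem), value = TRUE))
    records[[tc]] <- mem[[tc]][member_id]
  list(records = records,
       forest = build_recruitment_forest(records))
}

#' Simulate a full multi-round study
#'
#' Runs one chain-referral round per entry of the config's `target_n` on the
#' same population (independent forests, pooled afterwards — the repeated
#' yearly implementation of the emulated design). Seeds are apportioned to
#' rounds by largest remainder in proportion to the round targets, and seed
#' labels stay unique across rounds.
#'
#' @param config a `sim_config`.
#' @param population optional pre-generated `population_network`.
#' @param seed RNG seed for the whole study (population + all rounds).
#' @return list with `records` (pooled), `forest` (pooled), `rounds`
#'   (per-round results), `population`, `config`.
#' @export
simulate_study <- function(config, population = NULL, seed = NULL) {
  with_seed(seed, {
    if (is.null(population)) population <- generate_population(config)
    rounds <- vector("list", length(config$target_n))
    alloc_c <- apportion(config$seeds_community, config$target_n)
    alloc_h <- apportion(config$seeds_hospital, config$target_n)
    next_c <- 1L; next_h <- 1L
    for (r in seq_along(config$target_n)) {
      rc <- sim_config_round(config, alloc_c[r], alloc_h[r])
      labels <- c(sprintf("F%03d", seq.int(next_c, length.out = alloc_c[r])),
                  sprintf("H%03d", seq.int(next_h, length.out = alloc_h[r])))
      next_c <- next_c + alloc_c[r]; next_h <- next_h + alloc_h[r]
      rounds[[r]] <- simulate_rds(population, rc,
                                  target_n = config$target_n[r],
                                  year = config$years[r],
                                  seed_labels = labels)
    }
    records <- do.call(rbind, lapply(rounds, `[[`, "records"))
    list(records = records, forest = build_recruitment_forest(records),
         rounds = rounds, population = population, config = config)
  })
}

sim_config_round <- function(cfg, n_comm, n_hosp) {
  rc <- cfg
  rc$seeds_community <- n_comm
  rc$seeds_hospital <- n_hosp
  rc
}

## largest-remainder apportionment of `total` seats by weights
apportion <- function(total, weights) {
  q <- total * weights / sum(weights)
  base <- floor(q)
  extra <- total - sum(base)
  if (extra > 0) {
    add <- order(q - base, decreasing = TRUE)[seq_len(extra)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}
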