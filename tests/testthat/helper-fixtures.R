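# Fixtures built in code, shared across test files.

# a single referral chain of given length under one seed, first-recruit codes
chain_records <- function(len, seed_label = "F001", traits = NULL) {
  path <- strrep("0", 10L)
  codes <- character(len)
  for (i in seq_len(len)) {
    codes[i] <- paste0(seed_label, "-", path)
    if (i <= 10L) substr(path, i, i) <- "1"
  }
  df <- data.frame(pid = paste0(seed_label, "_", seq_len(len) - 1L),
                   code = codes, degree = 2L, stringsAsFactors = FALSE)
  if (!is.null(traits)) df[["trait:x:lifetime"]] <- traits
  df
}

# forest with explicit recruiter->recruit group pattern: seed in group g0,
# then one chain following `groups` (character vector per wave)
grouped_chain <- function(groups, degrees = NULL) {
  df <- chain_records(length(groups))
  if (!is.null(degrees)) df$degree <- degrees
  f <- build_recruitment_forest(df)
  part <- factor(groups, levels = sort(unique(groups)))
  names(part) <- f$nodes$pid
  list(forest = f, partition = part)
}

# forest realizing an exact multiset of group-to-group referral pairs:
# one seed per 'from' group, each recruiting its listed recruits (<=5 per
# recruiter enforced by chunking through intermediate waves is avoided by
# using several seeds)
grouped_edges <- function(pairs, degree_by_group = NULL) {
  # pairs: data.frame(from, to); realized as stars: one seed per row-chunk
  stopifnot(nrow(pairs) >= 1L)
  froms <- unique(pairs$from)
  recs <- list(); part <- character(0); pid_i <- 0L
  seed_i <- 0L
  for (g in froms) {
    kids <- pairs$to[pairs$from == g]
    for (chunk in split(kids, ceiling(seq_along(kids) / 5))) {
      seed_i <- seed_i + 1L
      lbl <- sprintf("F%03d", seed_i)
      pid_i <- pid_i + 1L
      seed_pid <- paste0("p", pid_i)
      recs[[length(recs) + 1L]] <- data.frame(
        pid = seed_pid, code = paste0(lbl, "-", strrep("0", 10)),
        degree = 2L, stringsAsFactors = FALSE)
      part[seed_pid] <- g
      for (j in seq_along(chunk)) {
        pid_i <- pid_i + 1L
        kid_pid <- paste0("p", pid_i)
        path <- strrep("0", 10); substr(path, 1, 1) <- as.character(j)
        recs[[length(recs) + 1L]] <- data.frame(
          pid = kid_pid, code = paste0(lbl, "-", path),
          degree = 2L, stringsAsFactors = FALSE)
        part[kid_pid] <- chunk[j]
      }
    }
  }
  df <- do.call(rbind, recs)
  if (!is.null(degree_by_group)) df$degree <- unname(degree_by_group[part[df$pid]])
  f <- build_recruitment_forest(df)
  p <- factor(part[f$nodes$pid], levels = sort(unique(part)))
  names(p) <- f$nodes$pid
  list(forest = f, partition = p)
}

# random row-stochastic matrix with strictly positive entries
random_stochastic <- function(k) {
  S <- matrix(stats::rgamma(k * k, shape = 1) + 1e-3, k, k)
  S <- S / rowSums(S)
  dimnames(S) <- list(letters[1:k], letters[1:k])
  S
}

# independent oracle: stationary distribution by brute-force matrix powering
power_stationary <- function(S, t = 1e4) {
  v <- rep(1 / nrow(S), nrow(S))
  # repeated squaring is NOT used: plain powering is the independent check
  for (i in seq_len(t)) v <- as.numeric(v %*% S)
  names(v) <- rownames(S)
  v
}

# small fast scenario for simulation-heavy tests
test_scenario <- function(...) {
  scenario_default(population_size = 3000, seeds_community = 8,
                   seeds_hospital = 3, target_n = 300, ...)
}
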