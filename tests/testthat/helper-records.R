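# Builders for respondent records used across the test files.

DIMS <- c("AC", "CO", "PD", "IN", "SE", "ME", "AX")

# one respondent row in the CSV schema; defaults give the "uniform"
# respondent: equal weights, symmetric level ratings, anchor 0.3
make_record <- function(id = "r1", sample = "GP", state = "1111111",
                        vas_l2 = rep(200 / 3, 7), vas_l3 = rep(100 / 3, 7),
                        weights = rep(100, 7), anchor_branch = "worst",
                        anchor_vas = 30, gender = "Female",
                        age_band = "30-39") {
  df <- data.frame(id = id, sample = sample, state = state,
                   stringsAsFactors = FALSE)
  for (d in seq_along(DIMS)) {
    df[[sprintf("vas_%s_l2", DIMS[d])]] <- vas_l2[d]
    df[[sprintf("vas_%s_l3", DIMS[d])]] <- vas_l3[d]
  }
  for (d in seq_along(DIMS))
    df[[sprintf("weight_%s", DIMS[d])]] <- weights[d]
  df$anchor_branch <- anchor_branch
  df$anchor_vas <- anchor_vas
  df$gender <- gender
  df$age_band <- age_band
  df$employment <- NA_character_
  df$ethnicity <- NA_character_
  df
}

# a random valid record (monotone ratings optional)
random_record <- function(seed, monotone = FALSE) {
  set.seed(seed)
  l2 <- runif(7, 0, 100)
  l3 <- runif(7, 0, 100)
  if (monotone) {
    hi <- pmax(l2, l3)
    lo <- pmin(l2, l3)
    l2 <- hi
    l3 <- lo
  }
  w <- runif(7, 0, 100)
  w[sample.int(7, 1)] <- 100
  branch <- sample(c("worst", "dead"), 1)
  make_record(id = paste0("rnd", seed), vas_l2 = l2, vas_l3 = l3,
              weights = w, anchor_branch = branch,
              anchor_vas = runif(1, 0, 100))
}

# independent brute-force PUF evaluator: recompute 1 - sum w*s*(1-a)
# per state with scalar loops, from the raw record (not via build_puf)
brute_force_utilities <- function(record, states) {
  l2 <- as.numeric(record[sprintf("vas_%s_l2", DIMS)])
  l3 <- as.numeric(record[sprintf("vas_%s_l3", DIMS)])
  w <- as.numeric(record[sprintf("weight_%s", DIMS)])
  w <- w / sum(w)
  av <- as.numeric(record$anchor_vas)
  a <- if (record$anchor_branch == "worst") av / 100 else
    max(-1, -av / (100 - av))
  sev <- function(d, l) switch(l, 0, 1 - l2[d] / 100, 1 - l3[d] / 100, 1)
  vapply(states, function(s) {
    lev <- as.integer(strsplit(s, "")[[1]])
    u <- 1
    for (d in 1:7) u <- u - w[d] * sev(d, lev[d]) * (1 - a)
    u
  }, numeric(1), USE.NAMES = FALSE)
}
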