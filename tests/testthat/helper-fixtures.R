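# shared fixtures, all built in code at test time

anchor_pair <- function() choice_pairs(17, 0, 38, 30)

small_menu <- function() {
  cfg <- cohort_config()
  generate_choice_menu(cfg)
}

# simulate one participant's trials from known parameters
sim_participant <- function(params, n_trials = 200, seed = 1, dt = 0.001) {
  set.seed(seed)
  menu <- small_menu()
  rows <- rep(seq_len(nrow(menu)), length.out = n_trials)
  simulate_trials(params, menu[rows, ], dt = dt)
}

# construct a ddm_fit object directly from known parameters (for testing
# downstream consumers without paying for an optimisation)
fake_fit <- function(params, nll = 0, converged = TRUE, n_trials = 80) {
  structure(list(params = params, nll = nll, converged = converged,
                 n_trials = n_trials, mode = "mle", samples = NULL, seed = 1L),
            class = "ddm_fit")
}

# brute-force one-way F from explicit sums of squares (independent oracle)
brute_force_f <- function(x1, x2) {
  all_x <- c(x1, x2)
  gm <- mean(all_x)
  ss_between <- length(x1) * (mean(x1) - gm)^2 + length(x2) * (mean(x2) - gm)^2
  ss_within <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
  df2 <- length(all_x) - 2
  f <- (ss_between / 1) / (ss_within / df2)
  list(f = f, p = pf(f, 1, df2, lower.tail = FALSE),
       eta_sq = ss_between / (ss_between + ss_within))
}
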