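# Shared fixtures, all generated in code.

# small item bank with varied slopes/locations for fast IRT tests
tiny_items <- function(m = 8L) {
  data.frame(
    item = sprintf("it%02d", seq_len(m)),
    a = rep(c(1.4, 0.8, 2.0, 0.6), length.out = m),
    b = seq(-1.5, 1.5, length.out = m),
    low = 10 * seq_len(m), high = 10 * seq_len(m) + 5,
    units = "synthetic", stringsAsFactors = FALSE
  )
}

# simulate a response matrix with known truth under a fixed seed
tiny_responses <- function(n = 600L, items = tiny_items(), seed = 101L) {
  withr::local_seed(seed)
  theta <- rnorm(n)
  U <- cdistrat:::sim_responses(items$a, items$b, theta,
                                item_names = items$item)
  U
}

# a small coded cohort with learnable outcome for bench tests
tiny_coded <- function(n = 200L, seed = 11L, link = 1.5) {
  gen <- generate_cohort(
    generator_config(n_cases = n, link_slope = link), seed = seed)
  code_cohort(gen$cohort, gen$specs, seed = seed + 1L)
}

# raw cohort data.frame with controllable missingness
tiny_cohort_df <- function(n = 40L, seed = 21L) {
  withr::local_seed(seed)
  data.frame(
    case_id = paste0("c", seq_len(n)),
    lab1 = rnorm(n, 10, 2),
    lab2 = rnorm(n, 50, 5),
    flag = rbinom(n, 1, 0.4),
    outcome = rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE
  )
}
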