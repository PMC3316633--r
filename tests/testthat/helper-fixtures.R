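# Shared fixtures and independent scalar oracles. The oracles are direct,
# unvectorised transcriptions of the model formulas, kept separate from the
# package implementation on purpose.

oracle_sv <- function(R, D, k) R / (1 + k * D)

oracle_sv_star <- function(R, D, k, a, apple) R / (1 + (k + a * as.numeric(apple)) * D)

oracle_p_later <- function(sv, omega, imm = 20) 1 / (1 + exp(-omega * (sv - imm)))

oracle_gamma <- function(delta, omega) {
  p <- oracle_p_later(delta + 20, omega)
  1 - abs(2 * p - 1)
}

oracle_nll <- function(k, a, omega, trials, imm = 20) {
  total <- 0
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (tr$trial_type != "TD" || !(tr$choice %in% c("now", "later"))) next
    sv <- oracle_sv_star(tr$amount, tr$delay, k, a, tr$prime == "apple")
    p <- oracle_p_later(sv, omega, imm)
    p <- min(max(p, 1e-12), 1 - 1e-12)
    y <- as.numeric(tr$choice == "later")
    total <- total - (y * log(p) + (1 - y) * log(1 - p))
  }
  total
}

# deterministic 20-trial choice fixture (built in code, frozen choices)
tiny_trials <- function() {
  data.frame(
    trial_type = "TD",
    prime = rep(c("apple", "cup"), 10),
    amount = rep(c(21, 25, 40, 80, 120), 4),
    delay = rep(c(1, 10, 55, 90, 180), 4),
    choice = rep(c("later", "now", "later", "later", "now",
                   "now", "later", "now", "later", "later"), 2),
    stringsAsFactors = FALSE)
}

default_params <- function() discount_params(0.024, 0.06, 0.3)

quick_dataset <- function(seed = 1, k = 0.024, a = 0.06, omega = 0.3,
                          design_seed = seed) {
  sch <- build_design(design_config(seed = design_seed))
  simulate_choices(discount_params(k, a, omega), sch, seed = seed)
}

# small BOLD spec for unit tests (full spec used in acceptance tests)
tiny_bold_spec <- function(...) {
  bold_spec(grid = c(10, 10, 8), ...)
}
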