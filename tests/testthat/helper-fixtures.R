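# shared builders for synthetic fixtures used across test files

# noiseless dose-response series from explicit 4PL parameters
make_series <- function(params, concentrations, n_rep = 1L,
                        id = "fix", pair = "polyq") {
  conc <- rep(concentrations, each = n_rep)
  dose_response_series(id, pair, conc, evaluate_four_pl(params, conc),
                       replicate = rep(seq_len(n_rep), length(concentrations)))
}

# minimal converged-fit stub for operations that only need params + flag
fit_stub <- function(params) {
  structure(list(params = params, converged = TRUE), class = "fourpl_fit")
}

# random peak cluster around a centre
random_trace <- function(centre, n_peaks, seed) {
  set.seed(seed)
  rl <- sort(sample(seq(centre - 8, centre + 8), n_peaks))
  peak_trace(paste0("t", seed), rl, stats::runif(n_peaks, 10, 1000))
}

table3_recipes <- list(
  q = c(25, 38, 48, 55, 72),
  avgQ38 = c(0.45, 0.21, 0.16, 0.11, 0.07),
  avgQ43 = c(0.38, 0.14, 0.11, 0.22, 0.15)
)
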