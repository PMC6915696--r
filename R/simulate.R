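#' Configuration for the synthetic assay-data generator
#'
#' Encodes the generative structure the simulator emulates: per-polyQ-length
#' 4PL dose-response curves whose `Top` and `EC50` depend on polyQ length in
#' the polyQ-antibody channel but not in the total-antibody channel, constant
#' `Bottom` and `HillSlope`, multiplicative log-normal measurement noise, and
#' duplicate wells per concentration.
#'
#' `Top(Q)` and `EC50(Q)` rules are linear, given as `c(intercept, slope)`
#' per channel. Defaults: polyQ channel `Top = 500*Q`, total channel
#' `Top = 20000` (constant), `EC50 = 500` pM in both channels, `Bottom = 100`
#' counts, `HillSlope = 1` — yielding a linear-range slope-ratio that is an
#' affine function of Q, matching the strong linear ratio-vs-Q correlation
#' the assay exhibits.
#'
#' @param seed integer seed; required for any stochastic output.
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   signal noise (default 0.05).
#' @param q_standards polyQ lengths of the standard panel.
#' @param bottom,hillslope shared 4PL background plateau and steepness.
#' @param top_per_q,ec50_per_q named lists with `polyq` and `total`
#'   `c(intercept, slope)` coefficient pairs.
#' @param concentrations standard-curve concentration ladder in pM.
#' @param n_replicates wells per concentration (default duplicates).
#' @return object of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              noise_cv = 0.05,
                              q_standards = c(19, 25, 32, 38, 44, 48, 55, 72),
                              bottom = 100,
                              hillslope = 1,
                              top_per_q = list(polyq = c(0, 500),
                                               total = c(20000, 0)),
                              ec50_per_q = list(polyq = c(500, 0),
                                                total = c(500, 0)),
                              concentrations = c(6.25, 12.5, 25, 50, 100,
                                                 200, 400, 800, 1600),
                              n_replicates = 2L) {
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  if (length(concentrations) == 0L) {
    stop("`concentrations` must be non-empty", call. = FALSE)
  }
  tq <- top_per_q$polyq
  if (tq[2] <= 0) {
    stop("polyQ-channel Top(Q) must be strictly increasing in Q", call. = FALSE)
  }
  if (top_per_q$total[2] != 0) {
    stop("total-channel Top must be constant in Q", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), noise_cv = noise_cv,
                 q_standards = q_standards, bottom = bottom,
                 hillslope = hillslope, top_per_q = top_per_q,
                 ec50_per_q = ec50_per_q, concentrations = concentrations,
                 n_replicates = as.integer(n_replicates)),
            class = "simulation_config")
}

channel_top <- function(config, channel, q) {
  co <- config$top_per_q[[channel]]
  co[1] + co[2] * q
}

channel_ec50 <- function(config, channel, q) {
  co <- config$ec50_per_q[[channel]]
  co[1] + co[2] * q
}

#' Per-species linear-range slope implied by the generator
#'
#' For `HillSlope = 1` the 4PL response is proportional at `x << EC50` with
#' slope `(Top - Bottom)/EC50`; this is the per-species signal-per-pM used by
#' the additive mixture generator.
#'
#' @param config a [simulation_config()].
#' @param channel `"polyq"` or `"total"`.
#' @param q polyQ length(s).
#' @return slope(s) in counts per pM.
#' @export
species_slope <- function(config, channel, q) {
  channel <- match.arg(channel, c("polyq", "total"))
  (channel_top(config, channel, q) - config$bottom) / channel_ec50(config, channel, q)
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))  # mean exactly 1
}

#' Simulate a panel of standard dose-response curves
#'
#' One [dose_response_series()] per polyQ standard, with replicate wells at
#' each ladder concentration: the noiseless signal is the 4PL curve for that
#' standard's channel-specific `Top(Q)`/`EC50(Q)`, then multiplied by
#' log-normal noise of coefficient `noise_cv`. Deterministic for a given
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param antibody_channel `"polyq"` or `"total"`.
#' @return named list of [dose_response_series()], one per standard.
#' @export
simulate_standard_curves <- function(config,
                                     antibody_channel = c("polyq", "total")) {
  antibody_channel <- match.arg(antibody_channel)
  # channel offset keeps the two channels' noise streams distinct but
  # reproducible from the one seed
  set.seed(config$seed + if (antibody_channel == "polyq") 0L else 1L)
  out <- lapply(config$q_standards, function(q) {
    params <- four_pl_params(bottom = config$bottom,
                             top = channel_top(config, antibody_channel, q),
                             ec50 = channel_ec50(config, antibody_channel, q),
                             hillslope = config$hillslope)
    conc <- rep(config$concentrations, each = config$n_replicates)
    mu <- evaluate_four_pl(params, conc)
    sig <- mu * lognormal_noise(length(mu), config$noise_cv)
    dose_response_series(sample_id = sprintf("Q%g", q),
                         antibody_pair = antibody_channel,
                         concentration = conc, signal = sig,
                         replicate = rep(seq_len(config$n_replicates),
                                         times = length(config$concentrations)))
  })
  names(out) <- sprintf("Q%g", config$q_standards)
  out
}

#' Simulate immunoassay signals for a protein mixture
#'
#' Under linear-range additivity each species contributes independently:
#' `signal = Bottom + sum_i fraction_i * concentration * slope(Q_i)`, where
#' `slope(Q_i)` is the species' linear-range slope ([species_slope()]);
#' multiplicative log-normal noise is applied per well. Requires
#' `HillSlope = 1` (the proportional regime the additivity assumption
#' describes). Component concentrations beyond the linear range
#' (`> 0.25 * EC50`, where the 4PL deviates > 20% from proportionality)
#' are recorded as an `out_of_range` attribute on the returned series.
#'
#' @param mix a [mixture_spec()].
#' @param config a [simulation_config()].
#' @param antibody_channel `"polyq"` or `"total"`.
#' @param dilutions optional vector of total concentrations (pM) to simulate;
#'   defaults to the mixture's `total_concentration`.
#' @return a [dose_response_series()] (with attribute `out_of_range` naming
#'   any component beyond the linear range).
#' @export
simulate_mixture_signals <- function(mix, config,
                                     antibody_channel = c("polyq", "total"),
                                     dilutions = NULL) {
  antibody_channel <- match.arg(antibody_channel)
  if (config$hillslope != 1) {
    stop("additive mixture simulation assumes HillSlope = 1", call. = FALSE)
  }
  conc_tot <- if (is.null(dilutions)) mix$total_concentration else dilutions
  if (any(!is.finite(conc_tot)) || any(conc_tot <= 0)) {
    stop("mixture total concentration must be finite and > 0", call. = FALSE)
  }
  set.seed(config$seed + 2L + if (antibody_channel == "polyq") 0L else 1L)
  slopes <- species_slope(config, antibody_channel, mix$q_lengths)
  ec50s <- channel_ec50(config, antibody_channel, mix$q_lengths)
  oor <- character(0)
  for (ct in conc_tot) {
    beyond <- mix$fractions * ct > 0.25 * ec50s
    if (any(beyond)) {
      oor <- union(oor, sprintf("Q%g@%gpM", mix$q_lengths[beyond], ct))
    }
  }
  conc <- rep(conc_tot, each = config$n_replicates)
  mu <- config$bottom + conc * sum(mix$fractions * slopes)
  sig <- mu * lognormal_noise(length(mu), config$noise_cv)
  out <- dose_response_series(sample_id = mix$label,
                              antibody_pair = antibody_channel,
                              concentration = conc, signal = sig,
                              replicate = rep(seq_len(config$n_replicates),
                                              times = length(conc_tot)))
  attr(out, "out_of_range") <- oor
  out
}

#' Simulate a fragment-analysis peak trace
#'
#' Draws `n_molecules` repeat lengths from a discretised normal kernel
#' centred at `modal_cag + expansion_bias` with dispersion `spread`
#' (truncated at repeat >= 1) and returns the resulting peak cluster, with
#' heights proportional to molecule counts. An optional one-sided geometric
#' expansion tail (`tail_weight > 0`, mean tail length `tail_mean`) skews
#' the distribution toward longer repeats, as somatic expansion does.
#'
#' @param modal_cag modal repeat length (integer >= 1).
#' @param expansion_bias mean shift toward longer repeats (>= 0).
#' @param spread kernel SD in repeat units (> 0; values below 1e-9 give a
#'   single peak at the rounded centre).
#' @param n_molecules number of molecules sampled (> 0).
#' @param seed integer seed.
#' @param tail_weight mixture weight of the geometric expansion tail in
#'   `[0, 1)` (default 0 = symmetric kernel).
#' @param tail_mean mean extra repeats in the tail component.
#' @param sample_id trace label.
#' @return a [peak_trace()].
#' @export
simulate_peak_trace <- function(modal_cag, expansion_bias = 0, spread = 2,
                                n_molecules = 10000L, seed = 1L,
                                tail_weight = 0, tail_mean = 5,
                                sample_id = sprintf("sim_cag%d", modal_cag)) {
  if (modal_cag < 1 || modal_cag != round(modal_cag)) {
    stop("`modal_cag` must be a positive integer", call. = FALSE)
  }
  if (expansion_bias < 0) stop("`expansion_bias` must be >= 0", call. = FALSE)
  if (spread < 0) stop("`spread` must be >= 0", call. = FALSE)
  if (n_molecules <= 0) stop("`n_molecules` must be > 0", call. = FALSE)
  set.seed(seed)
  mu <- modal_cag + expansion_bias
  if (spread < 1e-9) {
    k <- max(1L, as.integer(round(mu)))
    return(peak_trace(sample_id, k, n_molecules))
  }
  lo <- max(1L, floor(mu - 8 * spread))
  hi <- ceiling(mu + 8 * spread + if (tail_weight > 0) 8 * tail_mean else 0)
  k <- lo:hi
  p <- stats::pnorm(k + 0.5, mu, spread) - stats::pnorm(k - 0.5, mu, spread)
  if (tail_weight > 0) {
    tail_p <- ifelse(k >= mu, stats::dgeom(pmax(k - floor(mu), 0),
                                           prob = 1 / (1 + tail_mean)), 0)
    p <- (1 - tail_weight) * p + tail_weight * tail_p / sum(tail_p)
  }
  p <- p / sum(p)
  counts <- as.vector(stats::rmultinom(1, n_molecules, p))
  keep <- counts > 0
  peak_trace(sample_id, k[keep], counts[keep])
}

#' Simulate a paired protein/DNA cohort
#'
#' Each sample draws an integer true average CAG repeat length uniformly
#' across `instability_range`, builds a fragment-analysis trace around it,
#' and generates duplicate-well immunoassay signals in both antibody
#' channels at a fixed linear-range protein load through the forward
#' calibration (species slope at polyQ length = CAG length), with
#' multiplicative noise. The protein ratio and its propagated SD are
#' computed from background-subtracted well means.
#'
#' @param n_samples number of samples (>= 3).
#' @param instability_range length-2 integer range of true average CAG.
#' @param config a [simulation_config()].
#' @param seed integer seed (overrides `config$seed`).
#' @param protein_load_pM matched protein load for all samples (must sit in
#'   the linear range).
#' @param trace_spread,trace_n_molecules peak-trace kernel parameters.
#' @return object of class `"synthetic_cohort"`: list of per-sample lists
#'   (`sample_id`, `true_avg_cag`, `dna_trace`, `ratio`, `ratio_sd`,
#'   `signals`), with the generating parameters attached as attributes
#'   (`generating_slope`: d ratio / d CAG; `config`; `seed`).
#' @export
simulate_cohort <- function(n_samples, instability_range = c(105, 135),
                            config = simulation_config(), seed = config$seed,
                            protein_load_pM = 100,
                            trace_spread = 2, trace_n_molecules = 10000L) {
  if (n_samples < 3L) stop("`n_samples` must be >= 3", call. = FALSE)
  if (diff(range(instability_range)) <= 0) {
    warning("degenerate instability range: downstream correlation undefined")
  }
  set.seed(seed)
  true_cag <- sample(seq(instability_range[1], instability_range[2]),
                     n_samples, replace = TRUE)
  trace_seeds <- sample.int(.Machine$integer.max, n_samples)
  noise <- matrix(lognormal_noise(4L * n_samples, config$noise_cv),
                  nrow = n_samples)
  samples <- lapply(seq_len(n_samples), function(i) {
    q <- true_cag[i]
    net_p <- protein_load_pM * species_slope(config, "polyq", q) * noise[i, 1:2]
    net_t <- protein_load_pM * species_slope(config, "total", q) * noise[i, 3:4]
    s_p <- config$bottom + net_p
    s_t <- config$bottom + net_t
    sd_p <- stats::sd(net_p) / sqrt(2)   # SD of the duplicate mean
    sd_t <- stats::sd(net_t) / sqrt(2)
    r <- propagate_ratio_sd(mean(net_p), sd_p, mean(net_t), sd_t)
    trace <- simulate_peak_trace(q, 0, trace_spread, trace_n_molecules,
                                 seed = trace_seeds[i],
                                 sample_id = sprintf("S%02d", i))
    list(sample_id = sprintf("S%02d", i), true_avg_cag = q,
         dna_trace = trace, ratio = r$ratio, ratio_sd = r$sd,
         signals = list(polyq = s_p, total = s_t))
  })
  gen_slope <- (species_slope(config, "polyq", 1) - species_slope(config, "polyq", 0)) /
    species_slope(config, "total", 50)
  structure(samples, class = "synthetic_cohort",
            generating_slope = gen_slope, config = config, seed = seed,
            protein_load_pM = protein_load_pM)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cags <- vapply(x, function(s) s$true_avg_cag, numeric(1))
  cat(sprintf("Synthetic cohort: %d samples, true average CAG %d-%d (seed %d)\n",
              length(x), min(cags), max(cags), attr(x, "seed")))
  invisible(x)
}

#' Write a dose-response series (or panel) to delimited text
#'
#' Emits the plate-reader exchange format consumed by
#' [read_dose_response()]: columns `sample_id`, `antibody_pair`,
#' `concentration`, `units`, `replicate`, `signal`.
#'
#' @param series a [dose_response_series()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(series, path) {
  if (inherits(series, "dose_response_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(sample_id = attr(s, "sample_id"),
               antibody_pair = attr(s, "antibody_pair"),
               concentration = s$concentration,
               units = attr(s, "units"),
               replicate = s$replicate,
               signal = s$signal)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read dose-response series from delimited text
#'
#' Reads the plate-reader exchange format (see [write_dose_response()]) and
#' splits it into one [dose_response_series()] per
#' sample/antibody-pair combination.
#'
#' @param path CSV path.
#' @return named list of [dose_response_series()]
#'   (names `sample_id:antibody_pair`).
#' @export
read_dose_response <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "antibody_pair", "concentration", "units",
            "replicate", "signal")
  if (!all(need %in% names(df))) {
    stop("dose-response file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$sample_id, df$antibody_pair, sep = ":")
  out <- lapply(split(df, key), function(sub) {
    dose_response_series(sub$sample_id[1], sub$antibody_pair[1],
                         sub$concentration, sub$signal, sub$replicate,
                         units = sub$units[1])
  })
  out
}
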