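# Seeded simulators generating every input the pipeline consumes:
# treated-molecule populations, noisy peak lists, calibration series and
# hydrazine concentration series.
#
# Each simulator takes an explicit seed and seeds R's generator locally
# (restoring the caller's RNG state on exit), so every stage is
# independently reproducible.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Flag RNA-degrading treatment conditions
#'
#' Hydrazine itself leaves the phosphodiester backbone intact; degradation
#' is driven by temperature. The flag encodes the observed stability map:
#' intact at <= 10 degC for up to 24 h; caution (no pronounced degradation)
#' at 10-30 degC for short incubations but degraded from 6 h; degraded at
#' >= 30 degC at any time; severe at >= 50 degC.
#'
#' @param condition A [treatment_condition()].
#' @return A list: `degraded` (logical), `severity` (`"none"`, `"caution"`,
#'   `"moderate"`, `"severe"`).
#' @examples
#' degradation_flag(treatment_condition(30, temperature_c = 0, time_h = 24))
#' @export
degradation_flag <- function(condition) {
  stopifnot(inherits(condition, "treatment_condition"))
  T <- condition$temperature_c
  t <- condition$time_h
  if (T >= 50) return(list(degraded = TRUE, severity = "severe"))
  if (T >= 30) return(list(degraded = TRUE, severity = "moderate"))
  if (T > 10) {
    if (t >= 6) return(list(degraded = TRUE, severity = "moderate"))
    return(list(degraded = FALSE, severity = "caution"))
  }
  list(degraded = FALSE, severity = "none")
}

#' Simulate hydrazine treatment of an oligonucleotide population
#'
#' Each of `n` molecules converts every reactive position independently with
#' probability `p = reactivity(code, condition)` (per-molecule Bernoulli
#' trials), so per-molecule conversion counts are Binomial when all sites
#' share one probability. Species are aggregated by total composition delta,
#' matching the states of [conversion_ladder()]. Conditions flagged as
#' degrading are refused unless `allow_degradation = TRUE`.
#'
#' @param oligo An `rna_oligo`.
#' @param condition A [treatment_condition()].
#' @param n Number of molecules (>= 1).
#' @param seed Integer seed (local to this call).
#' @param registry A `nucleoside_registry`.
#' @param allow_degradation Simulate anyway under degrading conditions.
#' @return A list: `species` (data.frame `k`, `delta_mono`, `mass_mono`,
#'   `mass_avg`, `count`), `conversions` (integer per-molecule conversion
#'   counts, length `n`), `p` (named per-code conversion probabilities).
#' @export
simulate_treatment <- function(oligo, condition, n, seed = NULL,
                               registry = default_registry(),
                               allow_degradation = FALSE) {
  stopifnot(inherits(oligo, "rna_oligo"), n >= 1)
  deg <- degradation_flag(condition)
  if (deg$degraded && !allow_degradation) {
    stop("condition degrades RNA (severity: ", deg$severity,
         "); quantitative simulation refused. ",
         "Set allow_degradation = TRUE to override.")
  }
  lad <- suppressWarnings(conversion_ladder(oligo, registry, condition))
  tokens <- oligo$tokens
  reactive_pos <- attr(lad, "reactive_positions")
  .with_seed(seed, {
    if (length(reactive_pos)) {
      codes <- tokens[reactive_pos]
      p_code <- vapply(unique(codes), function(cd)
        reactivity(cd, condition, registry), numeric(1))
      deltas <- vapply(unique(codes), function(cd)
        mono_mass(reaction_rules(cd, registry)[[1]]$delta), numeric(1))
      # per molecule x position Bernoulli draws
      conv <- matrix(stats::rbinom(n * length(reactive_pos), 1L,
                                   rep(p_code[codes], each = n)),
                     nrow = n)
      conversions <- as.integer(rowSums(conv))
      delta_per_mol <- as.numeric(conv %*% deltas[codes])
    } else {
      p_code <- numeric(0)
      conversions <- integer(n)
      delta_per_mol <- numeric(n)
    }
    keyv <- round(delta_per_mol, 6)
    counts <- table(keyv)
    species <- data.frame(delta_mono = as.numeric(names(counts)),
                          count = as.integer(counts))
    m <- match(round(species$delta_mono, 6), round(lad$delta_mono, 6))
    species$k <- lad$k[m]
    species$mass_mono <- lad$mass_mono[m]
    species$mass_avg <- lad$mass_avg[m]
    species <- species[order(species$k), c("k", "delta_mono", "mass_mono",
                                           "mass_avg", "count")]
    rownames(species) <- NULL
    list(species = species, conversions = conversions, p = p_code)
  })
}

#' Simulate a noisy peak list from species counts
#'
#' Peaks are placed at the theoretical m/z of each species/charge with
#' additive Gaussian jitter (in ppm, or in Da for MALDI-style spectra);
#' intensities are proportional to species counts times a multiplicative
#' log-normal factor (MS intensities are scale-noisy); spurious noise peaks
#' are added as a Poisson count uniform over the scan range.
#'
#' @param species A data.frame with columns `mass_mono` (and `mass_avg` for
#'   `kind = "average"`), `count` and `k`, e.g. from [simulate_treatment()].
#' @param charges Integer vector of charge states to emit.
#' @param kind Mass kind for peak positions.
#' @param ppm_sigma Gaussian m/z jitter, ppm standard deviation.
#' @param da_sigma Alternative absolute jitter in Da (used when non-zero,
#'   e.g. 0.5 for reflector MALDI-TOF of 2-7 kDa oligos).
#' @param intensity_sdlog Log-normal sdlog of the intensity factor.
#' @param noise_peaks Expected number of spurious peaks (Poisson mean).
#' @param scan_range m/z range for noise peaks (default: data range +/- 5%).
#' @param seed Integer seed (local to this call).
#' @return A data.frame with columns `mz`, `intensity`, `charge` (NA for
#'   noise peaks), sorted by m/z.
#' @export
simulate_peaklist <- function(species, charges = 1L,
                              kind = c("monoisotopic", "average"),
                              ppm_sigma = 5, da_sigma = 0,
                              intensity_sdlog = 0.3, noise_peaks = 0,
                              scan_range = NULL, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(nrow(species) >= 1)
  masses <- if (kind == "monoisotopic") species$mass_mono else species$mass_avg
  .with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(species))) {
      for (z in charges) {
        mz0 <- mz_from_mass(masses[i], ion_descriptor(z))
        jitter <- if (da_sigma > 0) stats::rnorm(1, 0, da_sigma)
                  else mz0 * stats::rnorm(1, 0, ppm_sigma) * 1e-6
        rows[[length(rows) + 1L]] <- data.frame(
          mz = mz0 + jitter,
          intensity = species$count[i] *
            stats::rlnorm(1, meanlog = 0, sdlog = intensity_sdlog),
          charge = as.integer(z))
      }
    }
    out <- do.call(rbind, rows)
    n_noise <- stats::rpois(1, noise_peaks)
    if (n_noise > 0) {
      if (is.null(scan_range)) {
        span <- range(out$mz)
        pad <- 0.05 * diff(span)
        scan_range <- c(span[1] - pad, span[2] + pad)
      }
      noise <- data.frame(
        mz = stats::runif(n_noise, scan_range[1], scan_range[2]),
        intensity = stats::rlnorm(n_noise, meanlog = log(max(out$intensity) / 50),
                                  sdlog = 1),
        charge = NA_integer_)
      out <- rbind(out, noise)
    }
    out <- out[order(out$mz), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

.CALIBRATION_MAXIMA <- list(
  canonical = 100, Psi = 20, D = 20, modified = 5
)

#' Default maximum calibration amount for a nucleoside
#'
#' The serial-dilution design starts canonical nucleosides at 100 pmol,
#' pseudouridine and dihydrouridine at 20 pmol, and all other modified
#' nucleosides at 5 pmol.
#'
#' @param code Nucleoside code.
#' @return Maximum amount in pmol.
#' @export
calibration_max_pmol <- function(code) {
  code <- .normalize_code(code)
  if (code %in% c("A", "C", "G", "U")) return(.CALIBRATION_MAXIMA$canonical)
  if (code %in% c("Psi", "D")) return(.CALIBRATION_MAXIMA$Psi)
  .CALIBRATION_MAXIMA$modified
}

#' Simulate a serial-dilution calibration series
#'
#' A 1:1 serial dilution of `points` steps from `max_pmol` down, with
#' responses `slope * amount * (1 + eps)`, `eps ~ N(0, noise^2)`
#' (multiplicative noise, as response ratios scale with amount).
#'
#' @param code Nucleoside code (sets the default maximum via
#'   [calibration_max_pmol()]).
#' @param max_pmol Maximum (first) amount in pmol.
#' @param points Number of calibration points (default 12).
#' @param noise Relative noise standard deviation.
#' @param slope True response slope per pmol.
#' @param seed Integer seed (local to this call).
#' @return A [calibration_series()] with attribute `true_slope`.
#' @export
simulate_calibration <- function(code, max_pmol = calibration_max_pmol(code),
                                 points = 12, noise = 0.05, slope = 0.02,
                                 seed = NULL) {
  stopifnot(max_pmol > 0, points >= 3)
  amount <- max_pmol / 2^(0:(points - 1))
  .with_seed(seed, {
    eps <- stats::rnorm(points, 0, noise)
    series <- calibration_series(code, amount, slope * amount * (1 + eps))
    attr(series, "true_slope") <- slope
    series
  })
}

#' Simulate a hydrazine concentration series
#'
#' For each code and concentration, the remaining fraction is
#' `(1 - reactivity(code, c)) * (1 + eps)`, `eps ~ N(0, noise^2)`, at the
#' registry's reference temperature/time (0 degC, 1 h).
#'
#' @param codes Character vector of nucleoside codes.
#' @param concentrations Hydrazine concentrations (% v/v), must include 0.
#' @param noise Relative noise standard deviation.
#' @param seed Integer seed (local to this call).
#' @param registry A `nucleoside_registry`.
#' @return A data.frame with columns `code`, `concentration`, `remaining`.
#' @export
simulate_concentration_series <- function(codes, concentrations,
                                          noise = 0.03, seed = NULL,
                                          registry = default_registry()) {
  if (!any(concentrations == 0)) stop("concentrations must include 0")
  .with_seed(seed, {
    rows <- list()
    for (cd in codes) {
      for (conc in concentrations) {
        p <- reactivity(cd, treatment_condition(conc), registry)
        rem <- (1 - p) * (1 + stats::rnorm(1, 0, noise))
        rows[[length(rows) + 1L]] <- data.frame(
          code = cd, concentration = conc, remaining = max(rem, 0),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
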