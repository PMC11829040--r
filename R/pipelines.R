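# File formats, run configuration and the two headline pipelines:
# MALDI/HRMS fingerprint Ψ-calling and nucleoside quantification.
# The package's functions (plus these pipeline drivers) are the command
# surface; reports are plain lists serializable to JSON/CSV.

#' Read a peak list from TSV
#'
#' Expects two or three tab-separated numeric columns: m/z, intensity and
#' optionally charge. A header line is auto-detected. Decimal separator is
#' always the dot, independent of locale.
#'
#' @param path File path.
#' @return A data.frame with columns `mz`, `intensity` and (if present)
#'   `charge`. An empty file yields an empty peak list with a warning.
#' @export
read_peaklist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (!length(lines)) {
    warning("empty peak list: '", path, "'")
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  }
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = "\t",
                          header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 1 || ncol(df) > 3) {
    stop("peak list must have 1-3 columns (m/z, intensity[, charge]); got ",
         ncol(df))
  }
  names(df) <- c("mz", "intensity", "charge")[seq_len(ncol(df))]
  if (!is.numeric(df$mz)) stop("m/z column is not numeric in '", path, "'")
  df
}

#' @rdname read_peaklist
#' @param peaks A peak data.frame (`mz`, optional `intensity`, `charge`).
#' @export
write_peaklist <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a table as CSV/TSV
#'
#' @param rows A data.frame.
#' @param path Output path; extension `.tsv` selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write peak assignments to CSV or JSON
#'
#' @param assignments A `peak_assignments` from [match_peaks()].
#' @param path Output path; `.json` selects JSON (assignments plus
#'   unassigned peaks), anything else CSV of the assignment rows.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  stopifnot(inherits(assignments, "peak_assignments"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(assignments = assignments$assignments,
                              unassigned = assignments$unassigned,
                              tolerance = assignments$tolerance,
                              unit = assignments$unit),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(assignments$assignments, path, sep = ",",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Assemble a run configuration
#'
#' Bundles the knobs shared by the pipelines; all defaults are documented
#' here. The resolved configuration is embedded in every report for
#' reproducibility.
#'
#' @param tolerance Match tolerance (default 10 ppm for HRMS; use 0.5 Da for
#'   reflector MALDI spectra of 2-7 kDa oligonucleotides).
#' @param tolerance_unit `"ppm"` or `"da"`.
#' @param charges Charge states searched.
#' @param adducts Cations allowed to replace one proton.
#' @param mass_kind `"monoisotopic"` or `"average"`.
#' @param condition Optional [treatment_condition()].
#' @param registry A `nucleoside_registry`.
#' @param try_cyclic Also offer the 2',3'-cyclic-phosphate variant of each
#'   T1 fragment to the matcher.
#' @param seed Integer seed for any simulation steps.
#' @return A `run_config` list.
#' @export
run_config <- function(tolerance = 10, tolerance_unit = c("ppm", "da"),
                       charges = 1:4, adducts = c("Na", "K", "NH4"),
                       mass_kind = c("monoisotopic", "average"),
                       condition = NULL, registry = default_registry(),
                       try_cyclic = TRUE, seed = NULL) {
  structure(list(tolerance = tolerance,
                 tolerance_unit = match.arg(tolerance_unit),
                 charges = charges, adducts = adducts,
                 mass_kind = match.arg(mass_kind),
                 condition = condition, registry = registry,
                 try_cyclic = try_cyclic, seed = seed),
            class = "run_config")
}

.config_header <- function(config) {
  list(registry_version = config$registry$version,
       registry_profile = config$registry$profile,
       tolerance = config$tolerance, tolerance_unit = config$tolerance_unit,
       charges = config$charges, adducts = config$adducts,
       mass_kind = config$mass_kind,
       condition = if (!is.null(config$condition))
         unclass(config$condition) else NULL,
       seed = config$seed)
}

#' Fingerprint pipeline: digest, ladder, match, infer
#'
#' Runs the MALDI/HRMS fingerprint analysis: RNase T1 digestion of each
#' input oligo, hydrazine conversion-ladder enumeration per fragment (both
#' linear and cyclic 3'-phosphate variants when configured), theoretical
#' peak prediction, matching against the observed peak list and
#' non-reactive-site (Ψ candidate) inference per fragment.
#'
#' @param oligos A list of `rna_oligo`s, a single oligo, or a path to an
#'   extended-FASTA file.
#' @param peaks A peak data.frame or a path to a peak-list TSV.
#' @param config A [run_config()].
#' @return A `fingerprint_report`: list with `config`, `fragments` (table),
#'   `assignments` (per fragment), `inference` (data.frame with u, kmax,
#'   inferred non-reactive count, confidence per fragment) and `unassigned`.
#' @export
pipeline_fingerprint <- function(oligos, peaks, config = run_config()) {
  if (is.character(oligos)) oligos <- read_extended_fasta(oligos, config$registry)
  if (inherits(oligos, "rna_oligo")) oligos <- list(oligos)
  if (is.character(peaks)) peaks <- read_peaklist(peaks)
  registry <- config$registry

  fragments <- list()
  for (o in oligos) fragments <- c(fragments, t1_digest(o, registry = registry))

  per_fragment <- list()
  inference_rows <- list()
  all_assigned <- list()
  matched_mz <- numeric(0)
  for (f in fragments) {
    variants <- list(linear = f)
    if (isTRUE(config$try_cyclic) && f$three_prime == "phosphate") {
      fc <- f
      fc$three_prime <- "cyclic_phosphate"
      variants$cyclic <- fc
    }
    theo <- do.call(rbind, lapply(names(variants), function(v) {
      lad <- suppressWarnings(
        conversion_ladder(variants[[v]], registry, config$condition))
      tp <- theoretical_peaks(lad, charges = config$charges,
                              adducts = config$adducts,
                              kind = config$mass_kind)
      tp$variant <- v
      tp
    }))
    asg <- if (nrow(peaks)) {
      match_peaks(peaks, theo, tolerance = config$tolerance,
                  unit = config$tolerance_unit)
    } else {
      structure(list(assignments = theo[0, c("mz", "k", "z", "adduct")],
                     unassigned = peaks, tolerance = config$tolerance,
                     unit = config$tolerance_unit),
                class = "peak_assignments")
    }
    inf <- infer_nonreactive_sites(asg, f, config$condition, registry)
    per_fragment[[f$name]] <- asg
    matched_mz <- c(matched_mz, asg$assignments$mz)
    inference_rows[[length(inference_rows) + 1L]] <- data.frame(
      fragment = f$name, sequence = format_oligo(f),
      start = f$start, end = f$end,
      u = inf$u, kmax = inf$kmax, n_nonreactive = inf$n_nonreactive,
      localized = inf$localized, confidence = inf$confidence,
      stringsAsFactors = FALSE)
  }
  unassigned <- peaks[!peaks$mz %in% matched_mz, , drop = FALSE]
  structure(list(
    config = .config_header(config),
    fragments = fragments_table(fragments, registry),
    assignments = per_fragment,
    inference = do.call(rbind, inference_rows),
    unassigned = unassigned
  ), class = "fingerprint_report")
}

#' @export
print.fingerprint_report <- function(x, ...) {
  cat("<fingerprint report> ", nrow(x$fragments), " fragments, ",
      nrow(x$unassigned), " unassigned peaks\n", sep = "")
  print(x$inference)
  invisible(x)
}

#' Quantification pipeline: calibrate, quantify, normalize, yield
#'
#' Fits one calibration curve per nucleoside, inverse-predicts amounts for
#' control and treated samples, converts them to per-molecule counts via the
#' guanosine reference, and computes hydrazine conversion yields. An
#' optional concentration series is fitted per code with the log-logistic
#' dose-response model.
#'
#' @param calibrations Named list of [calibration_series()] (one per code).
#' @param control,treated Named numeric vectors of response ratios per code.
#' @param reference Reference nucleoside code for normalization (default
#'   `"G"`).
#' @param reference_count Per-molecule count of the reference in the RNA.
#' @param concentration_series Optional data.frame (`code`, `concentration`,
#'   `remaining`) as from [simulate_concentration_series()].
#' @param config A [run_config()].
#' @return A `quant_report`: list with `config`, `curves`, `amounts`
#'   (data.frame of control/treated pmol), `counts` (per-molecule),
#'   `yields` (data.frame code, yield, raw), and `dose_response` (per-code
#'   fits or NULL).
#' @export
pipeline_quant <- function(calibrations, control, treated,
                           reference = "G", reference_count,
                           concentration_series = NULL,
                           config = run_config()) {
  codes <- names(control)
  if (is.null(codes) || !all(codes %in% names(calibrations))) {
    stop("every quantified code needs a calibration series")
  }
  if (!reference %in% codes) {
    stop("reference nucleoside '", reference, "' missing from samples")
  }
  curves <- lapply(calibrations[codes], fit_calibration)
  amt <- function(samples) {
    vapply(codes, function(cd) as.numeric(quantify(samples[[cd]],
                                                   curves[[cd]])),
           numeric(1))
  }
  control_pmol <- amt(control)
  treated_pmol <- amt(treated)
  control_counts <- per_molecule_counts(control_pmol, reference,
                                        reference_count)
  treated_counts <- per_molecule_counts(treated_pmol, reference,
                                        reference_count)
  yields <- conversion_yield(control_counts, treated_counts)
  dr <- NULL
  if (!is.null(concentration_series)) {
    dr <- lapply(split(concentration_series, concentration_series$code),
                 function(d) fit_dose_response(d$concentration, d$remaining))
  }
  structure(list(
    config = .config_header(config),
    curves = curves,
    amounts = data.frame(code = codes, control_pmol = unname(control_pmol),
                         treated_pmol = unname(treated_pmol),
                         stringsAsFactors = FALSE),
    counts = data.frame(code = codes,
                        control = unname(control_counts),
                        treated = unname(treated_counts),
                        stringsAsFactors = FALSE),
    yields = data.frame(code = codes, yield = unname(yields),
                        raw = unname(attr(yields, "raw")),
                        stringsAsFactors = FALSE),
    dose_response = dr
  ), class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat("<quantification report>\n")
  print(merge(x$counts, x$yields, by = "code"))
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report A `fingerprint_report` or `quant_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "peak_assignments")) {
      return(list(assignments = x$assignments, unassigned = x$unassigned))
    }
    if (inherits(x, "calibration_curve")) return(x[c("slope", "intercept",
                                                     "r_squared", "range",
                                                     "code")])
    if (inherits(x, "dose_response_fit")) return(x[c("ec50", "slope",
                                                     "ceiling", "flags",
                                                     "converged")])
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
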