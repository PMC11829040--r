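# Hydrazine conversion ladders, theoretical peak prediction, peak-list
# matching and pseudouridine inference.

#' Enumerate the hydrazine conversion ladder of a fragment
#'
#' Every reactive position (a residue whose registry rule carries a mass
#' delta) may or may not have reacted; the ladder enumerates all resulting
#' species, collapsing those with identical total composition delta. The
#' unreacted species (k = 0) is always included. Positions whose rule has an
#' unknown product mass (e.g. mcm5s2U) are flagged and excluded from the
#' mass states. When a [treatment_condition()] is supplied, each species
#' receives its Bernoulli-product probability; probabilities over the ladder
#' sum to 1.
#'
#' @param fragment An `rna_oligo` (typically a `t1_fragment`).
#' @param registry A `nucleoside_registry`.
#' @param condition Optional [treatment_condition()].
#' @return A `conversion_ladder`: a data.frame with columns `k` (conversion
#'   count), `delta_mono`, `delta_avg`, `delta_nominal`, `mass_mono`,
#'   `mass_avg` and (with a condition) `probability`, sorted by `k` then
#'   mass; attributes `fragment`, `reactive_positions`, `flagged_positions`.
#' @examples
#' conversion_ladder(tokenize("[m1A]UCCACAG"))
#' @export
conversion_ladder <- function(fragment, registry = default_registry(),
                              condition = NULL) {
  stopifnot(inherits(fragment, "rna_oligo"))
  tokens <- fragment$tokens
  reactive <- list()   # per class: code, positions, delta, p
  flagged <- integer(0)
  for (i in seq_along(tokens)) {
    rules <- reaction_rules(tokens[i], registry)
    if (!length(rules)) next
    rule <- rules[[1]]
    if (is.null(rule$delta)) {
      flagged <- c(flagged, i)
      next
    }
    key <- tokens[i]
    if (is.null(reactive[[key]])) {
      p <- if (!is.null(condition)) reactivity(tokens[i], condition, registry) else NA_real_
      reactive[[key]] <- list(code = key, positions = i, rule = rule, p = p)
    } else {
      reactive[[key]]$positions <- c(reactive[[key]]$positions, i)
    }
  }
  if (length(flagged)) {
    warning("position(s) ", paste(flagged, collapse = ", "),
            " carry rules with unknown product mass; ",
            "ladder emitted without their mass states")
  }
  base_mono <- oligo_mass(fragment, "monoisotopic", registry)
  base_avg <- oligo_mass(fragment, "average", registry)

  # combinations of per-class conversion counts
  if (length(reactive)) {
    grids <- lapply(reactive, function(cl) 0:length(cl$positions))
    combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  } else {
    combos <- data.frame(row.names = 1)
  }
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    ks <- if (ncol(combos)) as.numeric(combos[r, ]) else numeric(0)
    d_mono <- 0; d_avg <- 0; d_nom <- 0; prob <- 1
    for (ci in seq_along(reactive)) {
      cl <- reactive[[ci]]
      k <- ks[ci]
      nj <- length(cl$positions)
      d_mono <- d_mono + k * mono_mass(cl$rule$delta)
      d_avg <- d_avg + k * avg_mass(cl$rule$delta)
      d_nom <- d_nom + k * nominal_mass(cl$rule$delta)
      if (!is.na(cl$p)) {
        prob <- prob * choose(nj, k) * cl$p^k * (1 - cl$p)^(nj - k)
      }
    }
    data.frame(k = sum(ks), delta_mono = d_mono, delta_avg = d_avg,
               delta_nominal = d_nom, probability = prob)
  })
  lad <- do.call(rbind, rows)
  # collapse species with identical total delta (they are indistinguishable
  # by mass); the representative keeps the smallest conversion count k
  lad <- lad[order(lad$k), , drop = FALSE]
  keyv <- as.character(round(lad$delta_mono, 6))
  agg <- stats::aggregate(lad["probability"], by = list(key = keyv), FUN = sum)
  first <- lad[!duplicated(keyv), , drop = FALSE]
  first$probability <- agg$probability[match(as.character(round(first$delta_mono, 6)),
                                             agg$key)]
  lad <- first[order(first$k, -first$delta_mono), , drop = FALSE]
  lad$mass_mono <- base_mono + lad$delta_mono
  lad$mass_avg <- base_avg + lad$delta_avg
  if (is.null(condition)) lad$probability <- NULL
  rownames(lad) <- NULL
  structure(lad,
            class = c("conversion_ladder", "data.frame"),
            fragment = fragment,
            reactive_positions = unlist(lapply(reactive, `[[`, "positions"),
                                        use.names = FALSE),
            flagged_positions = flagged)
}

.adduct_profiles <- function(z, adducts) {
  profiles <- list(c(H = z))
  if (z >= 1) {
    for (a in adducts) {
      prof <- c(H = z - 1L)
      prof[a] <- (if (a %in% names(prof)) prof[[a]] else 0L) + 1L
      profiles[[length(profiles) + 1L]] <- prof
    }
  }
  names(profiles) <- vapply(profiles, function(p) {
    paste(vapply(names(p)[p > 0], function(nm) {
      paste0(if (p[[nm]] != 1) p[[nm]] else "", nm)
    }, character(1)), collapse = "+")
  }, character(1))
  profiles
}

#' Predict theoretical peaks for a conversion ladder
#'
#' One peak per (species, charge, adduct profile). Adduct profiles follow
#' the targeted-search convention: all protons, plus variants in which one
#' proton is replaced by a listed cation (Na+, K+, NH4+).
#'
#' @param ladder A `conversion_ladder` (or any data.frame with `k` and
#'   `mass_mono`/`mass_avg` columns).
#' @param charges Integer vector of positive charge states.
#' @param adducts Character vector of cations allowed to replace one proton
#'   (subset of `"Na"`, `"K"`, `"NH4"`); empty for protons only.
#' @param kind Mass kind used for the neutral species, `"monoisotopic"` or
#'   `"average"`.
#' @return A data.frame with columns `mz`, `z`, `adduct`, `k`, `mass`,
#'   `kind` (class `theoretical_peaks`).
#' @export
theoretical_peaks <- function(ladder, charges = 1L, adducts = character(0),
                              kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  stopifnot(length(charges) >= 1L, all(charges >= 1))
  bad <- setdiff(adducts, c("Na", "K", "NH4"))
  if (length(bad)) stop("unsupported adduct(s): ", paste(bad, collapse = ", "))
  masses <- if (kind == "monoisotopic") ladder$mass_mono else ladder$mass_avg
  rows <- list()
  for (i in seq_len(nrow(ladder))) {
    for (z in charges) {
      for (prof_name in names(profiles <- .adduct_profiles(as.integer(z), adducts))) {
        ion <- ion_descriptor(z, profiles[[prof_name]])
        rows[[length(rows) + 1L]] <- data.frame(
          mz = mz_from_mass(masses[i], ion), z = as.integer(z),
          adduct = prof_name, k = ladder$k[i], mass = masses[i],
          kind = kind, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("mz", "z", "k")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("theoretical_peaks", "data.frame")
  out
}

#' Match observed peaks against theoretical peaks
#'
#' Each observed peak is assigned to the nearest theoretical peak within the
#' tolerance; ties are broken by smaller absolute ppm error, then lower
#' conversion count k, then lower charge z. When two theoretical peaks fit
#' equally well the assignment is flagged ambiguous. Matching is independent
#' of the order of the input peak list.
#'
#' @param observed A data.frame with column `mz` and optional `intensity`,
#'   `charge` (an observed charge restricts candidates to that z), e.g. from
#'   [read_peaklist()] or [simulate_peaklist()].
#' @param theoretical A data.frame from [theoretical_peaks()].
#' @param tolerance Match tolerance, in ppm (HRMS) or Da (MALDI).
#' @param unit `"ppm"` or `"da"`.
#' @return A `peak_assignments` object: list with `assignments` (one row per
#'   matched observed peak: mz, intensity, theoretical mz, k, z, adduct, ppm,
#'   rank, ambiguous) and `unassigned` (rows of `observed` without a match).
#' @export
match_peaks <- function(observed, theoretical, tolerance = 10,
                        unit = c("ppm", "da")) {
  unit <- match.arg(unit)
  if (tolerance <= 0) stop("tolerance must be positive")
  if (is.null(theoretical) || !nrow(theoretical)) {
    stop("theoretical peak list is empty")
  }
  observed <- as.data.frame(observed)
  if (!"mz" %in% names(observed)) stop("observed peaks need an 'mz' column")
  assigned <- list()
  unassigned <- list()
  for (i in seq_len(nrow(observed))) {
    mz <- observed$mz[i]
    cand <- theoretical
    if ("charge" %in% names(observed) && !is.na(observed$charge[i])) {
      cand <- cand[cand$z == observed$charge[i], , drop = FALSE]
    }
    if (nrow(cand)) {
      dev <- mz - cand$mz
      within <- if (unit == "ppm") abs(dev) / cand$mz * 1e6 <= tolerance
                else abs(dev) <= tolerance
      cand <- cand[within, , drop = FALSE]
    }
    if (!nrow(cand)) {
      unassigned[[length(unassigned) + 1L]] <- observed[i, , drop = FALSE]
      next
    }
    ppm <- ppm_error(mz, cand$mz)
    ord <- order(abs(ppm), cand$k, cand$z)
    cand <- cand[ord, , drop = FALSE]
    ppm <- ppm[ord]
    best <- cand[1L, ]
    ambiguous <- nrow(cand) > 1L && abs(abs(ppm[2L]) - abs(ppm[1L])) < 1e-9
    assigned[[length(assigned) + 1L]] <- data.frame(
      mz = mz,
      intensity = if ("intensity" %in% names(observed)) observed$intensity[i] else NA_real_,
      theoretical_mz = best$mz, k = best$k, z = best$z, adduct = best$adduct,
      ppm = ppm[1L], rank = 1L, ambiguous = ambiguous,
      stringsAsFactors = FALSE)
  }
  structure(list(
    assignments = if (length(assigned)) do.call(rbind, assigned) else
      data.frame(mz = numeric(0), intensity = numeric(0),
                 theoretical_mz = numeric(0), k = integer(0), z = integer(0),
                 adduct = character(0), ppm = numeric(0), rank = integer(0),
                 ambiguous = logical(0)),
    unassigned = if (length(unassigned)) do.call(rbind, unassigned) else
      observed[0, , drop = FALSE],
    tolerance = tolerance, unit = unit
  ), class = "peak_assignments")
}

#' @export
print.peak_assignments <- function(x, ...) {
  cat("<peak assignments> ", nrow(x$assignments), " assigned, ",
      nrow(x$unassigned), " unassigned (tolerance ", x$tolerance, " ",
      x$unit, ")\n", sep = "")
  if (nrow(x$assignments)) print(x$assignments)
  invisible(x)
}

#' Infer non-reactive (pseudouridine-candidate) sites from a ladder
#'
#' With u uridine-or-pseudouridine positions in a fragment and a maximum
#' assigned conversion count kmax, u - kmax positions are inferred
#' non-reactive (Ψ candidates). MS1 ladders count sites but cannot localize
#' them unless all or none of the positions are implicated. When a
#' treatment condition is given and the per-site conversion probability is
#' below 0.9, unconverted uridines cannot be ruled out and confidence is
#' flagged low.
#'
#' @param assignments A `peak_assignments` from [match_peaks()] referring to
#'   one fragment's ladder.
#' @param fragment The `rna_oligo` the ladder was built from.
#' @param condition Optional [treatment_condition()] used for the confidence
#'   flag.
#' @param registry A `nucleoside_registry`.
#' @return A list: `u` (ambiguous U/Ψ positions), `kmax`, `n_nonreactive`
#'   (inferred Ψ-candidate count), `localized` (TRUE when the inference
#'   pins down every position), `confidence` (`"high"`/`"low"`), `positions`
#'   (parent coordinates of the U/Ψ sites).
#' @export
infer_nonreactive_sites <- function(assignments, fragment, condition = NULL,
                                    registry = default_registry()) {
  stopifnot(inherits(assignments, "peak_assignments"),
            inherits(fragment, "rna_oligo"))
  amb <- which(fragment$tokens %in% c("U", "Psi"))
  u <- length(amb)
  kmax <- if (nrow(assignments$assignments)) max(assignments$assignments$k) else 0L
  n_nonreactive <- max(u - kmax, 0L)
  confidence <- "high"
  if (!is.null(condition)) {
    p <- reactivity("U", condition, registry)
    if (p < 0.9 && n_nonreactive > 0) confidence <- "low"
  }
  list(u = u, kmax = as.integer(kmax),
       n_nonreactive = as.integer(n_nonreactive),
       localized = n_nonreactive == 0L || n_nonreactive == u,
       confidence = confidence,
       positions = fragment$offset + amb - 1L)
}

.NEUTRAL_LOSS_TABLE <- c(
  NH3 = 17.026549, H2O = 18.010565, N2H4 = 32.037448, H2S = 33.987721,
  HNCO = 43.005814, ribose = 132.042260
)

#' Annotate MS2/MS3 neutral-loss series
#'
#' Matches mass differences between fragment ions against the classic
#' neutral losses seen in nucleoside fragmentation (ammonia, water,
#' hydrazine, hydrogen sulfide, HNCO, the ribose equivalent C5H8O4).
#'
#' @param deltas Numeric vector of mass differences (Da, magnitudes).
#' @param tolerance Matching tolerance in Da.
#' @return A data.frame with columns `delta`, `label` (`"unknown"` if
#'   unmatched), `theoretical`, `error_da`.
#' @examples
#' annotate_neutral_losses(c(17.03, 43.01, 99.9))
#' @export
annotate_neutral_losses <- function(deltas, tolerance = 0.02) {
  out <- lapply(deltas, function(d) {
    err <- abs(abs(d) - .NEUTRAL_LOSS_TABLE)
    i <- which.min(err)
    if (err[i] <= tolerance) {
      data.frame(delta = d, label = names(.NEUTRAL_LOSS_TABLE)[i],
                 theoretical = unname(.NEUTRAL_LOSS_TABLE[i]),
                 error_da = unname(abs(d) - .NEUTRAL_LOSS_TABLE[[i]]),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(delta = d, label = "unknown", theoretical = NA_real_,
                 error_da = NA_real_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
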