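# Registry of ribonucleosides and their hydrazine reaction rules.
# The registry is a plain value (modifying a copy never touches the default),
# loaded from a versioned YAML data file so users can refit or extend it.

.hydramass_env <- new.env(parent = emptyenv())

.CODE_ALIASES <- c("Ψ" = "Psi", "psi" = "Psi", "PSI" = "Psi")

.normalize_code <- function(code) {
  if (code %in% names(.CODE_ALIASES)) .CODE_ALIASES[[code]] else code
}

.parse_rule <- function(r) {
  delta <- NULL
  if (!is.null(r$delta)) delta <- elemental_composition(unlist(r$delta))
  list(
    product = r$product %||% "unknown",
    mechanism = r$mechanism %||% "unknown-loss",
    leaving_group = r$leaving_group,
    delta = delta,
    dose_response = r$dose_response
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a nucleoside registry from YAML
#'
#' @param path Path to a registry YAML file (see the packaged
#'   `inst/extdata/registry.yaml` for the schema).
#' @param profile Organism profile, `"human"` or `"ecoli"`. Some entries
#'   (t6A) carry profile-specific rules because the underlying reactivity
#'   difference is attributed to a cofactor in the tRNA preparation, not to
#'   the chemistry of the base.
#' @return A `nucleoside_registry` object.
#' @export
load_registry <- function(path, profile = c("human", "ecoli")) {
  profile <- match.arg(profile)
  raw <- yaml::read_yaml(path)
  specs <- list()
  for (entry in raw$nucleosides) {
    comp <- parse_formula(entry$formula)
    rules <- lapply(entry$rules %||% list(), .parse_rule)
    if (!is.null(entry$profile_rules) && profile %in% names(entry$profile_rules)) {
      rules <- c(rules, lapply(entry$profile_rules[[profile]], .parse_rule))
    }
    specs[[entry$code]] <- list(
      code = entry$code,
      name = entry$name %||% entry$code,
      composition = comp,
      residue = comp + parse_formula("HPO3") - parse_formula("H2O"),
      rules = rules
    )
  }
  structure(list(
    version = raw$version %||% "unversioned",
    profile = profile,
    reference_condition = raw$reference_condition %||%
      list(temperature_c = 0, time_h = 1),
    specs = specs
  ), class = "nucleoside_registry")
}

#' The packaged default registry
#'
#' Loads (and caches) the registry shipped with the package: canonical and
#' modified ribonucleosides with formulas, hydrazine reaction rules
#' (composition deltas, mechanisms, leaving groups) and log-logistic
#' dose-response defaults referenced to 0 degC / 1 h.
#'
#' @inheritParams load_registry
#' @return A `nucleoside_registry`.
#' @export
default_registry <- function(profile = c("human", "ecoli")) {
  profile <- match.arg(profile)
  key <- paste0("registry_", profile)
  if (is.null(.hydramass_env[[key]])) {
    path <- system.file("extdata", "registry.yaml", package = "hydramass",
                        mustWork = TRUE)
    .hydramass_env[[key]] <- load_registry(path, profile)
  }
  .hydramass_env[[key]]
}

#' @export
print.nucleoside_registry <- function(x, ...) {
  n_rules <- sum(vapply(x$specs, function(s) length(s$rules), integer(1)))
  cat("<nucleoside registry> v", x$version, " (", x$profile, " profile): ",
      length(x$specs), " nucleosides, ", n_rules, " reaction rules\n", sep = "")
  invisible(x)
}

#' Look up a nucleoside
#'
#' @param code Short nucleoside code (MODOMICS style, e.g. `"U"`, `"m5C"`,
#'   `"Psi"`; the literal `"Ψ"` is accepted as an alias for `"Psi"`).
#' @param registry A `nucleoside_registry`; defaults to the packaged one.
#' @return The spec: code, display name, nucleoside composition, residue
#'   composition (nucleoside - H2O + HPO3) and reaction rules.
#' @export
lookup_nucleoside <- function(code, registry = default_registry()) {
  stopifnot(is.character(code), length(code) == 1L)
  code <- .normalize_code(code)
  spec <- registry$specs[[code]]
  if (is.null(spec)) {
    near <- if (nzchar(code))
      agrep(code, names(registry$specs), max.distance = 1, value = TRUE)
    else character(0)
    stop("unknown nucleoside code '", code, "'",
         if (length(near)) paste0("; did you mean: ",
                                  paste(near, collapse = ", "), "?") else "")
  }
  spec
}

#' Hydrazine reaction rules for a nucleoside
#'
#' Returns the (possibly empty) list of reaction rules registered for a
#' code. Each rule holds the product name, a mechanism tag, the optional
#' leaving group, the signed composition delta (`NULL` for products of
#' unknown mass) and log-logistic dose-response parameters.
#'
#' @inheritParams lookup_nucleoside
#' @return A list of rules (possibly empty).
#' @export
reaction_rules <- function(code, registry = default_registry()) {
  lookup_nucleoside(code, registry)$rules
}

#' Describe a hydrazine treatment condition
#'
#' @param hydrazine_pct Hydrazine concentration, % v/v (0-50; a warning is
#'   issued above 50).
#' @param temperature_c Incubation temperature, degC. The reactivity model is
#'   referenced to 0 degC; above 10 degC RNA degradation sets in (see
#'   [degradation_flag()]).
#' @param time_h Incubation time in hours, > 0.
#' @return A `treatment_condition` object.
#' @export
treatment_condition <- function(hydrazine_pct, temperature_c = 0, time_h = 1) {
  stopifnot(is.numeric(hydrazine_pct), length(hydrazine_pct) == 1L)
  if (hydrazine_pct < 0) stop("hydrazine concentration must be non-negative")
  if (hydrazine_pct > 50) warning("hydrazine concentration above 50% v/v is ",
                                  "outside the calibrated range")
  if (time_h <= 0) stop("incubation time must be positive")
  structure(list(hydrazine_pct = hydrazine_pct,
                 temperature_c = temperature_c, time_h = time_h),
            class = "treatment_condition")
}

#' @export
print.treatment_condition <- function(x, ...) {
  cat(sprintf("<treatment> %g%% hydrazine, %g degC, %g h\n",
              x$hydrazine_pct, x$temperature_c, x$time_h))
  invisible(x)
}

#' Log-logistic conversion model
#'
#' Converted fraction as a function of hydrazine concentration:
#' `p(c) = ceiling / (1 + (ec50 / c)^slope)` with `p(0) = 0`. Monotone
#' non-decreasing in `c` and bounded in `[0, ceiling]`.
#'
#' @param conc Hydrazine concentration(s), % v/v.
#' @param ec50 Concentration of half-maximal conversion, % v/v.
#' @param slope Hill-type slope (dimensionless, > 0).
#' @param ceiling Maximal converted fraction in `[0, 1]`.
#' @return Converted fraction(s) in `[0, ceiling]`.
#' @export
dose_response_fraction <- function(conc, ec50, slope, ceiling = 1) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  ifelse(conc == 0, 0, ceiling / (1 + (ec50 / conc)^slope))
}

#' Converted fraction of a nucleoside under a treatment condition
#'
#' Evaluates the registry's dose-response defaults for `code` at a
#' condition. Time scales the response by a multiplicative factor linear in
#' hours (capped at 6 h, referenced to 1 h) and the result is clipped at the
#' rule's ceiling; temperatures above 10 degC are outside the calibrated
#' range and trigger a warning.
#'
#' @inheritParams lookup_nucleoside
#' @param condition A [treatment_condition()].
#' @return Converted fraction p in `[0, 1]` (0 for codes with no rule).
#' @export
reactivity <- function(code, condition, registry = default_registry()) {
  stopifnot(inherits(condition, "treatment_condition"))
  rules <- reaction_rules(code, registry)
  if (!length(rules)) return(0)
  dr <- rules[[1]]$dose_response
  if (is.null(dr)) return(0)
  if (condition$temperature_c > 10) {
    warning("reactivity model is calibrated at 0 degC; extrapolating to ",
            condition$temperature_c, " degC")
  }
  p <- dose_response_fraction(condition$hydrazine_pct, dr$ec50, dr$slope,
                              dr$ceiling %||% 1)
  tf <- min(max(condition$time_h, 0), 6)
  min(p * tf, dr$ceiling %||% 1)
}

#' Register or replace a nucleoside
#'
#' Returns a modified copy of the registry (value semantics); the packaged
#' default registry is never altered.
#'
#' @inheritParams lookup_nucleoside
#' @param formula Molecular formula of the nucleoside (string or
#'   `elem_comp`).
#' @param rules List of reaction rules; each rule is a list with elements
#'   `product`, `mechanism`, optional `leaving_group`, `delta` (named signed
#'   counts, `elem_comp`, or `NULL`) and `dose_response`
#'   (`list(ec50=, slope=, ceiling=)`).
#' @param name Display name.
#' @param overwrite Allow replacing an existing code.
#' @return The updated `nucleoside_registry`.
#' @export
register_nucleoside <- function(registry, code, formula, rules = list(),
                                name = code, overwrite = FALSE) {
  stopifnot(inherits(registry, "nucleoside_registry"))
  code <- .normalize_code(code)
  if (!is.null(registry$specs[[code]]) && !overwrite) {
    stop("code '", code, "' already registered; use overwrite = TRUE")
  }
  comp <- .as_comp(formula)
  rules <- lapply(rules, function(r) {
    if (!is.null(r$delta) && !inherits(r$delta, "elem_comp")) {
      r$delta <- elemental_composition(unlist(r$delta))
    }
    .parse_rule(r)
  })
  registry$specs[[code]] <- list(
    code = code, name = name, composition = comp,
    residue = comp + parse_formula("HPO3") - parse_formula("H2O"),
    rules = rules
  )
  registry
}

#' Serialize a registry to YAML
#'
#' @inheritParams lookup_nucleoside
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "nucleoside_registry"))
  nucs <- lapply(registry$specs, function(s) {
    out <- list(code = s$code, name = s$name,
                formula = format_formula(s$composition))
    if (length(s$rules)) {
      out$rules <- lapply(s$rules, function(r) {
        rl <- list(product = r$product, mechanism = r$mechanism)
        if (!is.null(r$leaving_group)) rl$leaving_group <- r$leaving_group
        if (!is.null(r$delta)) {
          d <- unclass(r$delta)
          rl$delta <- as.list(d[d != 0])
        }
        if (!is.null(r$dose_response)) rl$dose_response <- r$dose_response
        rl
      })
    }
    out
  })
  yaml::write_yaml(list(version = registry$version,
                        reference_condition = registry$reference_condition,
                        nucleosides = unname(nucs)), path)
  invisible(path)
}
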