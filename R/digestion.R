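# Bracket-notation RNA sequences, terminus bookkeeping and in-silico
# RNase T1 digestion.
#
# Terminus bookkeeping convention (one formula, heavily unit-tested):
#   residue  = nucleoside 5'-monophosphate - H2O
#   oligo    = sum(residues) + H2O            (a 5'-phosphate / 3'-OH chain)
#   5'-OH    : subtract HPO3
#   3'-phosphate : add HPO3
#   3'-cyclic phosphate : add HPO3, subtract H2O
# This prevents the classic +/-80 and +/-18 bookkeeping bugs: a single
# 5'-OH/3'-OH residue comes out exactly as the free nucleoside.

.H2O <- c(H = 2, O = 1)
.HPO3 <- c(H = 1, P = 1, O = 3)

#' Construct an RNA oligonucleotide
#'
#' @param tokens Character vector of residue codes (must be registered in the
#'   registry when masses are computed).
#' @param five_prime 5' terminus: `"OH"` or `"phosphate"`.
#' @param three_prime 3' terminus: `"OH"`, `"phosphate"` or
#'   `"cyclic_phosphate"`.
#' @param name Optional name.
#' @param offset 1-based position of the first residue in a parent sequence
#'   (used by digestion fragments).
#' @return An `rna_oligo` object.
#' @export
rna_oligo <- function(tokens, five_prime = c("OH", "phosphate"),
                      three_prime = c("OH", "phosphate", "cyclic_phosphate"),
                      name = NULL, offset = 1L) {
  stopifnot(is.character(tokens), length(tokens) >= 1L)
  structure(list(tokens = tokens,
                 five_prime = match.arg(five_prime),
                 three_prime = match.arg(three_prime),
                 name = name, offset = as.integer(offset)),
            class = "rna_oligo")
}

#' Tokenize an extended RNA sequence string
#'
#' Canonical residues are single letters (`A`, `C`, `G`, `U`); modified
#' residues are written in square brackets, e.g. `"[m1A]UCCACAG"`. The
#' literal `Ψ` character and the bracket token `[Psi]` both denote
#' pseudouridine.
#'
#' @param text Sequence string.
#' @param registry Registry used to validate tokens.
#' @inheritParams rna_oligo
#' @return An `rna_oligo`.
#' @examples
#' tokenize("A[Cm]U[Gm]AA[Y]A[Psi][m5C]UG")
#' @export
tokenize <- function(text, five_prime = "OH", three_prime = "OH",
                     name = NULL, registry = default_registry()) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  tokens <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("unbalanced bracket at position ", i,
                                  " in '", text, "'")
      tok <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (tok == "") stop("empty bracket token at position ", i)
      tokens <- c(tokens, .normalize_code(tok))
      i <- j + 1L
    } else if (ch == "]") {
      stop("unbalanced closing bracket at position ", i, " in '", text, "'")
    } else if (ch %in% c("A", "C", "G", "U")) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else if (ch == "Ψ") {  # literal Psi
      tokens <- c(tokens, "Psi")
      i <- i + 1L
    } else if (ch %in% c(" ", "\t")) {
      i <- i + 1L
    } else {
      stop("unknown residue character '", ch, "' at position ", i,
           " (modified residues must be bracketed)")
    }
  }
  if (!length(tokens)) stop("empty sequence")
  for (tok in tokens) lookup_nucleoside(tok, registry)  # validates
  rna_oligo(tokens, five_prime = five_prime, three_prime = three_prime,
            name = name)
}

#' Format an oligo back to bracket notation
#'
#' Inverse of [tokenize()]: canonical residues print bare, everything else
#' in brackets. `tokenize(format_oligo(x))` reproduces the token list.
#'
#' @param oligo An `rna_oligo`.
#' @return A single sequence string.
#' @export
format_oligo <- function(oligo) {
  stopifnot(inherits(oligo, "rna_oligo"))
  paste(vapply(oligo$tokens, function(t) {
    if (t %in% c("A", "C", "G", "U")) t else paste0("[", t, "]")
  }, character(1)), collapse = "")
}

#' @export
print.rna_oligo <- function(x, ...) {
  cat("<rna_oligo", if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
      "> ", format_oligo(x), "  (", length(x$tokens), " nt, 5'-",
      x$five_prime, "/3'-", x$three_prime, ")\n", sep = "")
  invisible(x)
}

#' Neutral elemental composition of an oligo
#'
#' Applies the residue/terminus bookkeeping documented in this module.
#'
#' @inheritParams format_oligo
#' @param registry Registry supplying residue compositions.
#' @return An `elem_comp`.
#' @export
oligo_composition <- function(oligo, registry = default_registry()) {
  stopifnot(inherits(oligo, "rna_oligo"))
  total <- elemental_composition(.H2O)  # sum(residues) + H2O
  for (tok in oligo$tokens) {
    total <- total + lookup_nucleoside(tok, registry)$residue
  }
  if (oligo$five_prime == "OH") total <- total - elemental_composition(.HPO3)
  if (oligo$three_prime %in% c("phosphate", "cyclic_phosphate")) {
    total <- total + elemental_composition(.HPO3)
  }
  if (oligo$three_prime == "cyclic_phosphate") {
    total <- total - elemental_composition(.H2O)
  }
  total
}

#' Neutral mass of an oligo or digestion fragment
#'
#' @inheritParams oligo_composition
#' @param kind `"monoisotopic"`, `"average"` or `"nominal"`.
#' @return Neutral mass in Da.
#' @examples
#' oligo_mass(tokenize("GUAGUCGUGGCCGAGUGGUU"))  # 6452.8519
#' @export
oligo_mass <- function(oligo, kind = c("monoisotopic", "average", "nominal"),
                       registry = default_registry()) {
  .mass_by_kind(oligo_composition(oligo, registry), match.arg(kind))
}

#' In-silico RNase T1 digestion
#'
#' Cleaves the phosphodiester 3' of every cleavable guanosine. By default
#' only unmodified `G` is cleavable: 2'-O-methylation blocks the T1
#' 2'-OH-dependent chemistry and base-methylated guanosines are treated as
#' resistant. Each cut leaves a 3'-phosphate (or 2',3'-cyclic phosphate) on
#' the upstream fragment and a 5'-OH on the downstream fragment; the parent's
#' own termini are preserved on the first and last fragment.
#'
#' @param parent An `rna_oligo`.
#' @param resistant Codes never cleaved after (default: all modified Gs).
#' @param missed_cleavages Maximum number of missed cleavages k; the result
#'   contains all contiguous unions of at most k+1 zero-missed fragments.
#' @param product_terminus 3' terminus of internal products: `"phosphate"`
#'   (linear, default — a 30-min digestion ring-opens the cyclic
#'   intermediate) or `"cyclic_phosphate"`.
#' @param registry Registry for token validation.
#' @return List of `t1_fragment` objects (an `rna_oligo` plus `start`,
#'   `end` 1-based inclusive parent coordinates, `parent_name` and `missed`).
#' @examples
#' t1_digest(tokenize("GUAG"))  # fragments G and UAG
#' @export
t1_digest <- function(parent,
                      resistant = c("Gm", "m1G", "m2G", "m22G", "m7G"),
                      missed_cleavages = 0,
                      product_terminus = c("phosphate", "cyclic_phosphate"),
                      registry = default_registry()) {
  stopifnot(inherits(parent, "rna_oligo"))
  product_terminus <- match.arg(product_terminus)
  n <- length(parent$tokens)
  cut_after <- which(parent$tokens == "G" & !(parent$tokens %in% resistant))
  cut_after <- cut_after[cut_after < n]  # a 3'-terminal G yields no new cut
  bounds <- c(0L, cut_after, n)          # fragment i spans bounds[i]+1..bounds[i+1]
  base <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i] + 1L
    e <- bounds[i + 1L]
    base[[i]] <- c(s, e)
  }
  nfrag <- length(base)
  out <- list()
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + missed_cleavages)) {
      s <- base[[i]][1]
      e <- base[[j]][2]
      frag <- rna_oligo(
        parent$tokens[s:e],
        five_prime = if (s == 1L) parent$five_prime else "OH",
        three_prime = if (e == n) parent$three_prime else product_terminus,
        name = paste0(parent$name %||% "oligo", "_", s, "-", e),
        offset = parent$offset + s - 1L
      )
      frag$start <- parent$offset + s - 1L
      frag$end <- parent$offset + e - 1L
      frag$parent_name <- parent$name
      frag$missed <- j - i
      class(frag) <- c("t1_fragment", "rna_oligo")
      out[[length(out) + 1L]] <- frag
    }
  }
  out
}

#' Tabulate digestion fragments
#'
#' @param fragments List of `t1_fragment`s from [t1_digest()].
#' @param registry Registry for mass computation.
#' @return A data.frame with name, coordinates, sequence, termini, missed
#'   cleavages and monoisotopic/average neutral masses, suitable for TSV
#'   export via [write_table()].
#' @export
fragments_table <- function(fragments, registry = default_registry()) {
  do.call(rbind, lapply(fragments, function(f) {
    data.frame(
      name = f$name %||% NA_character_,
      start = f$start, end = f$end,
      sequence = format_oligo(f),
      five_prime = f$five_prime, three_prime = f$three_prime,
      missed = f$missed,
      mono_mass = oligo_mass(f, "monoisotopic", registry),
      avg_mass = oligo_mass(f, "average", registry),
      stringsAsFactors = FALSE
    )
  }))
}

#' Read / write extended FASTA
#'
#' A plain FASTA layout whose sequence lines use the package's bracket
#' notation for modified residues. `read_extended_fasta()` reports parse
#' errors with the offending line number.
#'
#' @param path File path.
#' @param registry Registry for token validation.
#' @return A list of `rna_oligo`s.
#' @export
read_extended_fasta <- function(path, registry = default_registry()) {
  lines <- readLines(path, warn = FALSE)
  oligos <- list()
  name <- NULL
  seq_parts <- character(0)
  first_line <- NA_integer_
  flush <- function() {
    if (is.null(name)) return()
    txt <- paste(seq_parts, collapse = "")
    oligo <- tryCatch(
      tokenize(txt, name = name, registry = registry),
      error = function(e) stop("entry '", name, "' (line ", first_line, "): ",
                               conditionMessage(e), call. = FALSE)
    )
    oligos[[length(oligos) + 1L]] <<- oligo
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, ">")) {
      flush()
      name <- sub("^>\\s*", "", ln)
      seq_parts <- character(0)
      first_line <- i
    } else {
      if (is.null(name)) stop("line ", i, ": sequence before first header")
      seq_parts <- c(seq_parts, ln)
    }
  }
  flush()
  if (!length(oligos)) warning("no sequences found in '", path, "'")
  oligos
}

#' @rdname read_extended_fasta
#' @param oligos A list of `rna_oligo`s (or a single one).
#' @export
write_extended_fasta <- function(oligos, path) {
  if (inherits(oligos, "rna_oligo")) oligos <- list(oligos)
  lines <- unlist(lapply(seq_along(oligos), function(i) {
    o <- oligos[[i]]
    c(paste0(">", o$name %||% paste0("oligo_", i)), format_oligo(o))
  }))
  writeLines(lines, path)
  invisible(path)
}
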