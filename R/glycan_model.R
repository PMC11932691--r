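#' Construct a monosaccharide composition
#'
#' An N-glycan species is represented by its generic monosaccharide
#' composition: hexose (mannose + galactose), N-acetylhexosamine,
#' deoxyhexose (fucose) and N-acetylneuraminic acid counts. Structural
#' detail beyond the composition (linkage, antenna arrangement) is not
#' modeled.
#'
#' @param hex,hexnac,dhex,neuac non-negative integer residue counts.
#' @return An object of class `glycan_composition`.
#' @examples
#' glycan_composition(hex = 3, hexnac = 2, dhex = 1)
#' @export
glycan_composition <- function(hex = 0, hexnac = 0, dhex = 0, neuac = 0) {
  counts <- c(hex = hex, hexnac = hexnac, dhex = dhex, neuac = neuac)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("residue counts must be non-negative integers", call. = FALSE)
  if (hex + hexnac < 1)
    stop("invalid composition: needs at least one Hex or HexNAc residue",
         call. = FALSE)
  counts <- as.integer(counts)
  structure(list(hex = counts[1], hexnac = counts[2],
                 dhex = counts[3], neuac = counts[4]),
            class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(format_composition(x), "\n")
  invisible(x)
}

#' Format a composition as a canonical string
#'
#' @param c a `glycan_composition`.
#' @return A string such as `"Hex3HexNAc2dHex1"`.
#' @export
format_composition <- function(c) {
  parts <- c(
    if (c$hex > 0) paste0("Hex", c$hex),
    if (c$hexnac > 0) paste0("HexNAc", c$hexnac),
    if (c$dhex > 0) paste0("dHex", c$dhex),
    if (c$neuac > 0) paste0("NeuAc", c$neuac)
  )
  paste0(parts, collapse = "")
}

# token -> canonical residue slot; matched case-insensitively, longest first
.residue_tokens <- c(
  hexnac = "hexnac", neu5ac = "neuac", neuac = "neuac",
  dhex = "dhex", fuc = "dhex", hex = "hex"
)

#' Parse a composition string
#'
#' Accepts strings built from the tokens `Hex`, `HexNAc`, `dHex` (alias
#' `Fuc`) and `NeuAc` (alias `Neu5Ac`), each followed by a count, in any
#' order and case. An absent token means a count of zero.
#'
#' @param text a single composition string, e.g. `"Hex3HexNAc2dHex1"`.
#' @return A `glycan_composition`.
#' @examples
#' parse_composition("HexNAc1Fuc1")
#' @export
parse_composition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  pat <- "(HexNAc|Neu5Ac|NeuAc|dHex|Fuc|Hex)([0-9]+)"
  rest <- text
  counts <- c(hex = 0L, hexnac = 0L, dhex = 0L, neuac = 0L)
  while (nzchar(rest)) {
    m <- regexpr(paste0("^", pat), rest, ignore.case = TRUE, perl = TRUE)
    if (m == -1L) {
      bad <- regmatches(rest, regexpr("^[A-Za-z0-9]+", rest))
      stop("unknown residue token in composition: '",
           if (length(bad)) bad else rest, "'", call. = FALSE)
    }
    tok <- regmatches(rest, m)
    n <- as.integer(sub(pat, "\\2", tok, ignore.case = TRUE))
    slot <- .residue_tokens[[tolower(sub(pat, "\\1", tok, ignore.case = TRUE))]]
    counts[slot] <- counts[slot] + n
    rest <- substring(rest, attr(m, "match.length") + 1L)
  }
  glycan_composition(counts[["hex"]], counts[["hexnac"]],
                     counts[["dhex"]], counts[["neuac"]])
}

#' Parse many composition strings into a count table
#'
#' @param texts character vector of composition strings.
#' @return A data.frame with integer columns `hex`, `hexnac`, `dhex`,
#'   `neuac`, one row per input.
#' @export
parse_compositions <- function(texts) {
  parsed <- lapply(texts, parse_composition)
  data.frame(
    hex = vapply(parsed, `[[`, integer(1), "hex"),
    hexnac = vapply(parsed, `[[`, integer(1), "hexnac"),
    dhex = vapply(parsed, `[[`, integer(1), "dhex"),
    neuac = vapply(parsed, `[[`, integer(1), "neuac")
  )
}

#' Default glycan classification rule table
#'
#' The classifier assigns every composition to exactly one structural
#' class by the first matching row of a rule table. Each row bounds the
#' four residue counts (NA = unbounded). The default table encodes:
#'
#' 1. HexNAc <= 2 and Hex = 0: chitobiose core (most truncated species,
#'    GlcNAc1(F) and GlcNAc2(F)).
#' 2. HexNAc = 2, 1 <= Hex <= 3, no NeuAc: paucimannose (M1-M3, with or
#'    without core fucose).
#' 3. HexNAc = 2, Hex >= 4, no dHex/NeuAc: oligomannose (Man4-Man9).
#'    Hex4HexNAc2 therefore falls on the oligomannose side of the
#'    paucimannose boundary, which is defined as Man1-3 only.
#' 4. HexNAc = 3, Hex >= 5: hybrid (heuristic; composition alone cannot
#'    separate hybrid from some complex structures).
#' 5. HexNAc >= 3 otherwise: complex.
#' 6. Anything else (e.g. fucosylated Hex>=4/HexNAc2, which cannot be
#'    canonical oligomannose): other.
#'
#' @return A data.frame with columns `class` and the eight bound columns
#'   `hexnac_min`, `hexnac_max`, `hex_min`, `hex_max`, `dhex_min`,
#'   `dhex_max`, `neuac_min`, `neuac_max`.
#' @seealso [read_rule_table()] to load an alternative convention.
#' @export
default_rule_table <- function() {
  read_rule_table(system.file("extdata", "glycan_rules.tsv",
                              package = "pauciquant", mustWork = TRUE))
}

.rule_cols <- c("class",
                "hexnac_min", "hexnac_max", "hex_min", "hex_max",
                "dhex_min", "dhex_max", "neuac_min", "neuac_max")

#' Read a classification rule table from TSV
#'
#' @param path TSV file with the columns documented in
#'   [default_rule_table()]; empty cells mean unbounded.
#' @return Validated rule table data.frame.
#' @export
read_rule_table <- function(path) {
  rules <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  missing <- setdiff(.rule_cols, names(rules))
  if (length(missing))
    stop("rule table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rules
}

#' Write a classification rule table to TSV
#'
#' @param rules rule table data.frame.
#' @param path output path.
#' @export
write_rule_table <- function(rules, path) {
  utils::write.table(rules[, .rule_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

.classify_counts <- function(hex, hexnac, dhex, neuac, rules) {
  n <- length(hex)
  out <- rep(NA_character_, n)
  counts <- list(hexnac = hexnac, hex = hex, dhex = dhex, neuac = neuac)
  for (i in seq_len(nrow(rules))) {
    ok <- rep(TRUE, n)
    for (res in names(counts)) {
      lo <- rules[[paste0(res, "_min")]][i]
      hi <- rules[[paste0(res, "_max")]][i]
      if (!is.na(lo)) ok <- ok & counts[[res]] >= lo
      if (!is.na(hi)) ok <- ok & counts[[res]] <= hi
    }
    hit <- ok & is.na(out)
    out[hit] <- rules$class[i]
  }
  out[is.na(out)] <- "other"
  out
}

#' Classify glycan compositions into structural classes
#'
#' @param x a `glycan_composition`, a character vector of composition
#'   strings, or a data.frame with columns `hex`, `hexnac`, `dhex`,
#'   `neuac`.
#' @param rules classification rule table; see [default_rule_table()].
#' @return Character vector of class labels, one per composition:
#'   `"paucimannose"`, `"chitobiose_core"`, `"oligomannose"`,
#'   `"hybrid"`, `"complex"` or `"other"`.
#' @examples
#' classify_glycan(glycan_composition(3, 2, 1))  # paucimannose (M3F)
#' classify_glycan(c("Hex9HexNAc2", "Hex5HexNAc4dHex1NeuAc2"))
#' @export
classify_glycan <- function(x, rules = default_rule_table()) {
  if (inherits(x, "glycan_composition"))
    x <- data.frame(hex = x$hex, hexnac = x$hexnac,
                    dhex = x$dhex, neuac = x$neuac)
  else if (is.character(x))
    x <- parse_compositions(x)
  stopifnot(all(c("hex", "hexnac", "dhex", "neuac") %in% names(x)))
  if (any(x$hex + x$hexnac < 1))
    stop("invalid composition: needs at least one Hex or HexNAc residue",
         call. = FALSE)
  .classify_counts(x$hex, x$hexnac, x$dhex, x$neuac, rules)
}

#' Short label for truncated N-glycan species
#'
#' Species in the truncation pathway carry conventional short-hand
#' names: paucimannosidic species are `"M{hex}"` with suffix `"F"` when
#' core fucosylated (`M1`-`M3F`); chitobiose-core species are `"M0"` /
#' `"M0F"` (GlcNAc2 +/- Fuc) and `"GlcNAc1"` / `"GlcNAc1F"` (single
#' GlcNAc +/- Fuc).
#'
#' @param c a `glycan_composition` in the paucimannose or chitobiose
#'   core class.
#' @param rules classification rule table.
#' @return Label string.
#' @examples
#' short_label(glycan_composition(3, 2, 1))  # "M3F"
#' @export
short_label <- function(c, rules = default_rule_table()) {
  cls <- classify_glycan(c, rules)
  if (!cls %in% c("paucimannose", "chitobiose_core"))
    stop("short labels are defined only for truncation-pathway species; ",
         "got class '", cls, "'", call. = FALSE)
  fuc <- if (c$dhex == 0) "" else if (c$dhex == 1) "F" else paste0("F", c$dhex)
  if (cls == "paucimannose") return(paste0("M", c$hex, fuc))
  if (c$hexnac == 2) paste0("M0", fuc) else paste0("GlcNAc", c$hexnac, fuc)
}

#' Map a glycan class to its biosynthetic pathway
#'
#' Truncated species (paucimannose, chitobiose core) are products of
#' the N-glycan truncation pathway; hybrid and complex species are
#' products of the canonical elongation pathway; oligomannose species
#' are the shared precursors. Unclassifiable compositions are counted
#' with the precursors.
#'
#' @param g character vector of glycan class labels.
#' @return Character vector: `"truncation"`, `"elongation"` or
#'   `"precursor"`.
#' @export
pathway_of <- function(g) {
  map <- c(paucimannose = "truncation", chitobiose_core = "truncation",
           hybrid = "elongation", complex = "elongation",
           oligomannose = "precursor", other = "precursor")
  bad <- setdiff(unique(g), names(map))
  if (length(bad))
    stop("unknown glycan class: ", paste(bad, collapse = ", "), call. = FALSE)
  unname(map[g])
}
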