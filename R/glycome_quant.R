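#' Sample columns of a glycome table
#'
#' @param g glycome table data.frame.
#' @return Names of the per-sample abundance columns (everything other
#'   than the `composition`/`label`/`class` metadata columns).
#' @keywords internal
glycome_samples <- function(g)
  setdiff(names(g), c("composition", "label", "class"))

#' Summarize a glycome table into glycan class shares
#'
#' Classifies every species by its monosaccharide composition and sums
#' relative abundances per structural class, expressed as percent of
#' each sample's glycome. Species that no rule resolves fall into
#' class `"other"` with a warning.
#'
#' @param g glycome table: data.frame with a `composition` column and
#'   one numeric column per sample (per-sample relative abundances
#'   summing to 1).
#' @param rules classification rule table (see [default_rule_table()]).
#' @return Class share table: data.frame with `class` plus one column
#'   per sample, columns summing to 100.
#' @export
type_summary <- function(g, rules = default_rule_table()) {
  samples <- glycome_samples(g)
  if (!length(samples)) stop("glycome table has no sample columns",
                             call. = FALSE)
  cls <- classify_glycan(g$composition, rules)
  if (any(cls == "other"))
    warning(sum(cls == "other"),
            " species could not be assigned a canonical class ",
            "and were counted as 'other'", call. = FALSE)
  classes <- c("paucimannose", "chitobiose_core", "oligomannose",
               "hybrid", "complex", "other")
  classes <- classes[classes %in% cls]
  out <- data.frame(class = classes, stringsAsFactors = FALSE)
  for (s in samples)
    out[[s]] <- 100 * vapply(classes,
                             function(k) sum(g[[s]][cls == k]), numeric(1))
  out
}

#' Species shares within one glycan class
#'
#' Expresses each member species of a class as a percentage of that
#' class's total per sample. If the class is entirely absent from a
#' sample, the within-class shares are undefined and reported as NA
#' (not zero).
#'
#' @param g glycome table (see [type_summary()]).
#' @param class glycan class name.
#' @param rules classification rule table.
#' @return Data.frame: `composition`, `label` (if present) and one
#'   percentage column per sample, columns summing to 100 where
#'   defined.
#' @export
species_share_within_class <- function(g, class,
                                       rules = default_rule_table()) {
  cls <- classify_glycan(g$composition, rules)
  sub <- g[cls == class, , drop = FALSE]
  if (!nrow(sub)) stop("no species of class '", class,
                       "' in the table", call. = FALSE)
  samples <- glycome_samples(g)
  for (s in samples) {
    tot <- sum(sub[[s]])
    sub[[s]] <- if (tot > 0) 100 * sub[[s]] / tot else NA_real_
  }
  rownames(sub) <- NULL
  sub
}

#' Biosynthetic pathway usage per sample
#'
#' Maps glycan classes to their pathway (truncation / elongation /
#' precursor) and aggregates class shares, giving the relative usage
#' of each route per sample.
#'
#' @param shares class share table from [type_summary()].
#' @return Data.frame: `pathway` plus one percentage column per
#'   sample, columns summing to 100.
#' @export
pathway_usage <- function(shares) {
  pw <- pathway_of(shares$class)
  pathways <- c("truncation", "elongation", "precursor")
  out <- data.frame(pathway = pathways, stringsAsFactors = FALSE)
  for (s in setdiff(names(shares), "class"))
    out[[s]] <- vapply(pathways,
                       function(p) sum(shares[[s]][pw == p]), numeric(1))
  out
}

#' Per-species ratio between two samples
#'
#' Ratio of relative abundances of each glycan species in sample `a`
#' over sample `b` (e.g. tumor over matched normal adjacent tissue).
#' Species with zero abundance in `b` have an undefined ratio (NA,
#' flagged).
#'
#' @param g glycome table.
#' @param a,b sample column names (numerator, denominator).
#' @return Data.frame: `composition`, `label` (if present), `ratio`,
#'   logical `undefined`.
#' @export
paired_ratio <- function(g, a, b) {
  stopifnot(a %in% names(g), b %in% names(g))
  undef <- g[[b]] == 0
  out <- data.frame(composition = g$composition, stringsAsFactors = FALSE)
  if ("label" %in% names(g)) out$label <- g$label
  out$ratio <- ifelse(undef, NA_real_, g[[a]] / g[[b]])
  out$undefined <- undef
  out
}

#' Compare glycan class shares between donor groups
#'
#' Runs, per glycan class, either unpaired two-tailed t-tests of each
#' non-control group against the control group, or a one-way ANOVA
#' with Tukey-adjusted pairwise comparisons over all groups.
#'
#' @param shares class share table from [type_summary()].
#' @param design data.frame with `sample_id` and `group`; group
#'   `"control"` (or `control_group`) is the t-test baseline.
#' @param test `"ttest"` or `"anova_tukey"`.
#' @param control_group baseline group label for `test = "ttest"`.
#' @param welch use the Welch correction for t-tests.
#' @return For `"ttest"`: data.frame `class`, `group`, `difference`
#'   (group mean minus control mean), `t`, `df`, `p`. For
#'   `"anova_tukey"`: data.frame `class`, `F`, `p` plus an attribute
#'   `tukey` with the adjusted pairwise table.
#' @export
compare_groups <- function(shares, design, test = c("ttest", "anova_tukey"),
                           control_group = "control", welch = FALSE) {
  test <- match.arg(test)
  samples <- setdiff(names(shares), "class")
  grp <- design$group[match(samples, design$sample_id)]
  if (anyNA(grp)) stop("design lacks group labels for some samples",
                       call. = FALSE)
  if (any(table(grp) < 2))
    stop("every group needs at least 2 samples", call. = FALSE)
  if (test == "ttest") {
    if (!control_group %in% grp)
      stop("control group '", control_group, "' absent", call. = FALSE)
    rows <- list()
    for (i in seq_len(nrow(shares))) {
      x <- as.numeric(shares[i, samples])
      for (gname in setdiff(unique(grp), control_group)) {
        tt <- ttest(x[grp == gname], x[grp == control_group], welch = welch)
        rows[[length(rows) + 1L]] <- data.frame(
          class = shares$class[i], group = gname,
          difference = tt$difference, t = tt$t, df = tt$df, p = tt$p)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  rows <- list()
  tukey <- list()
  for (i in seq_len(nrow(shares))) {
    x <- as.numeric(shares[i, samples])
    at <- anova_tukey(split(x, grp))
    rows[[i]] <- data.frame(class = shares$class[i], F = at$F, p = at$p)
    tk <- at$tukey
    tk$class <- shares$class[i]
    tukey[[i]] <- tk
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tukey") <- do.call(rbind, tukey)
  out
}
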