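#' Map proteins to annotation sets
#'
#' Annotates each protein accession with the cell-origin sets it
#' belongs to and summarizes set coverage and Venn-style pairwise
#' overlaps among the detected proteins.
#'
#' @param proteins character vector of detected protein accessions.
#' @param sets named list of character vectors (annotation sets, e.g.
#'   from [generate_annotation_sets()] or an HPA-style export).
#' @return List: `membership` (data.frame `accession`, `sets`
#'   comma-separated, `n_sets`), `set_counts` (named vector of
#'   detected members per set), `overlaps` (symmetric matrix of
#'   pairwise detected-member overlaps).
#' @export
map_proteins <- function(proteins, sets) {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  proteins <- unique(proteins)
  hits <- lapply(sets, function(s) proteins %in% s)
  member <- vapply(seq_along(proteins), function(i) {
    nm <- names(sets)[vapply(hits, `[`, logical(1), i)]
    paste(nm, collapse = ",")
  }, character(1))
  membership <- data.frame(accession = proteins, sets = member,
                           n_sets = lengths(strsplit(member, ",")),
                           stringsAsFactors = FALSE)
  detected <- lapply(sets, function(s) intersect(proteins, s))
  set_counts <- vapply(detected, length, integer(1))
  k <- length(sets)
  overlaps <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    overlaps[i, j] <- length(intersect(detected[[i]], detected[[j]]))
  list(membership = membership, set_counts = set_counts, overlaps = overlaps)
}

#' Per-sample marker score of an annotation set
#'
#' Aggregates the normalized abundances of the set's members detected
#' in the abundance matrix into one scalar per sample (default: their
#' sum). The number of contributing proteins is recorded.
#'
#' @param mat abundance matrix (proteins x samples, rownames =
#'   accessions).
#' @param set character vector of member accessions (or a named,
#'   length-1 list element).
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @param set_name label used in error messages.
#' @return Named numeric vector of per-sample scores; attribute
#'   `n_proteins` = number of detected members.
#' @export
marker_score <- function(mat, set, aggregate = c("sum", "mean"),
                         set_name = deparse(substitute(set))) {
  aggregate <- match.arg(aggregate)
  members <- intersect(rownames(mat), set)
  if (!length(members))
    stop("no member of set '", set_name,
         "' detected in the abundance matrix", call. = FALSE)
  sub <- mat[members, , drop = FALSE]
  fun <- if (aggregate == "sum") colSums else colMeans
  score <- fun(sub, na.rm = TRUE)
  attr(score, "n_proteins") <- length(members)
  score
}

#' Correlate cell-origin marker scores with glycan-type levels
#'
#' Pearson correlation of each annotation set's marker score against
#' each glycan class share across samples, with pairwise-complete
#' handling of missing values. Cells with fewer than 3 complete pairs
#' are flagged not computable (NA).
#'
#' @param scores matrix or data.frame of marker scores (sets x
#'   samples) or named list of per-sample score vectors.
#' @param shares class share table from [type_summary()].
#' @return Data.frame: `set`, `class`, `r`, `t`, `p`, `n`.
#' @export
correlate_origin_glycotype <- function(scores, shares) {
  if (is.list(scores) && !is.data.frame(scores))
    scores <- do.call(rbind, scores)
  scores <- as.matrix(scores)
  samples <- intersect(colnames(scores), setdiff(names(shares), "class"))
  if (length(samples) < 3)
    stop("need at least 3 shared samples", call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(scores))) for (j in seq_len(nrow(shares))) {
    x <- as.numeric(scores[i, samples])
    y <- as.numeric(shares[j, samples])
    ok <- is.finite(x) & is.finite(y)
    res <- if (sum(ok) >= 3)
      tryCatch(pearson(x[ok], y[ok]),
               error = function(e) list(r = NA, t = NA, p = NA,
                                        n = sum(ok)))
    else list(r = NA_real_, t = NA_real_, p = NA_real_, n = sum(ok))
    rows[[length(rows) + 1L]] <- data.frame(
      set = rownames(scores)[i], class = shares$class[j],
      r = res$r, t = res$t, p = res$p, n = res$n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentage of a reference set that is shared
#'
#' @param size reference set size (> 0).
#' @param shared shared member count (0 <= shared <= size).
#' @return `100 * shared / size`, rounded to one decimal.
#' @examples
#' overlap_percentage(51, 7)   # 13.7
#' overlap_percentage(51, 13)  # 25.5
#' @export
overlap_percentage <- function(size, shared) {
  if (any(size <= 0)) stop("reference set size must be positive",
                           call. = FALSE)
  if (any(shared < 0) || any(shared > size))
    stop("shared count must lie in [0, size]", call. = FALSE)
  round(100 * shared / size, 1)
}

#' Correlation recovery over replicated planted simulations
#'
#' Draws `reps` bivariate-normal samples of size `n` at a planted
#' population correlation and returns the Pearson estimate of each
#' replicate, for assessing estimator bias of the correlation stage.
#'
#' @param n pairs per replicate.
#' @param rho planted population correlation.
#' @param reps number of replicates.
#' @param seed integer seed (one stream; replicate r uses draws
#'   `2n(r-1)+1 ... 2nr`).
#' @return Numeric vector of `reps` Pearson r estimates.
#' @export
recover_planted_correlation <- function(n, rho, reps = 2000, seed = 1) {
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  vapply(seq_len(reps), function(r) {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    pearson(z1, z2)$r
  }, numeric(1))
}
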