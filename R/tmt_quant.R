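#' Filter glycoPSMs on PEP 2D confidence
#'
#' Retains only confident identifications: rows with a two-dimensional
#' posterior error probability strictly below the threshold.
#'
#' @param psms glycoPSM data.frame with a `pep2d` column.
#' @param pep2d_max confidence threshold (default 0.001; rows with
#'   `pep2d >= pep2d_max` are removed).
#' @return The retained rows, with attribute `removed` holding the
#'   count filtered out.
#' @export
filter_psms <- function(psms, pep2d_max = 0.001) {
  stopifnot("pep2d" %in% names(psms))
  keep <- psms$pep2d < pep2d_max
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep)
  attr(out, "ref_channel") <- attr(psms, "ref_channel")
  out
}

.feature_key <- function(df)
  paste(df$accession, df$site, df$composition, sep = "|")

#' Group glycoPSMs into glycopeptide features
#'
#' Sums reporter-ion intensities channel-wise over all PSMs sharing
#' the same protein accession, glycosylation site and glycan
#' composition within a plex. One row per distinct (accession, site,
#' composition, plex), ordered deterministically by key.
#'
#' @param psms filtered glycoPSM data.frame with `accession`, `site`,
#'   `composition`, `plex` and reporter channel columns.
#' @param channels reporter channel column names (default: the TMT-10
#'   channels present in `psms`).
#' @return A data.frame of features with summed channel intensities.
#' @export
group_glycopsms <- function(psms, channels = NULL) {
  if (is.null(channels))
    channels <- intersect(tmt10_channels(), names(psms))
  if (!length(channels))
    stop("no reporter channel columns found", call. = FALSE)
  key <- interaction(psms$accession, psms$site, psms$composition, psms$plex,
                     drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(psms)), key)
  rows <- lapply(idx, function(i) {
    r <- psms[i[1], c("accession", "site", "composition", "plex"),
              drop = FALSE]
    r[channels] <- lapply(channels, function(ch) sum(psms[[ch]][i]))
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$accession, out$site, out$composition, out$plex), ]
  rownames(out) <- NULL
  attr(out, "channels") <- channels
  attr(out, "ref_channel") <- attr(psms, "ref_channel")
  out
}

#' Normalize feature intensities against the plex reference channel
#'
#' First normalization stage: within each plex, every sample channel
#' of a feature is divided by that feature's reference-channel
#' intensity, putting all plexes on the shared reference scale so
#' batches can be combined. Features whose reference intensity is zero
#' or missing in a plex cannot be quantified there; they are excluded
#' from that plex and logged, not errored.
#'
#' @param features grouped feature table from [group_glycopsms()].
#' @param design cohort design mapping (plex, channel) to `sample_id`.
#' @param ref_channel reference channel name (default `"126"`).
#' @return Named list of per-plex ratio matrices (feature key x
#'   sample), with attribute `excluded`: data.frame of (feature, plex)
#'   pairs dropped for unquantifiable reference.
#' @export
normalize_to_reference <- function(features, design, ref_channel = "126") {
  stopifnot(all(c("plex", "channel", "sample_id") %in% names(design)))
  excluded <- list()
  mats <- list()
  for (p in sort(unique(features$plex))) {
    f <- features[features$plex == p, , drop = FALSE]
    dsub <- design[design$plex == p, , drop = FALSE]
    ref <- f[[ref_channel]]
    bad <- is.na(ref) | ref <= 0
    if (any(bad))
      excluded[[as.character(p)]] <- data.frame(
        feature = .feature_key(f[bad, ]), plex = p)
    f <- f[!bad, , drop = FALSE]
    m <- as.matrix(f[, dsub$channel, drop = FALSE]) / f[[ref_channel]]
    dimnames(m) <- list(.feature_key(f), dsub$sample_id)
    mats[[as.character(p)]] <- m
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded)
              else data.frame(feature = character(0), plex = integer(0))
  rownames(excluded) <- NULL
  if (nrow(excluded))
    message(nrow(excluded),
            " feature/plex pair(s) excluded: reference intensity 0 or missing")
  attr(mats, "excluded") <- excluded
  mats
}

#' Combine per-plex ratio matrices into one abundance matrix
#'
#' Takes the union of features over plexes and concatenates samples;
#' a feature not quantified in a plex is missing (NA), never zero,
#' for that plex's samples.
#'
#' @param mats list of feature x sample matrices, e.g. from
#'   [normalize_to_reference()].
#' @return Combined matrix (union of features x all samples).
#' @export
merge_plexes <- function(mats) {
  samples <- unlist(lapply(mats, colnames), use.names = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample ids across plexes: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  features <- sort(unique(unlist(lapply(mats, rownames), use.names = FALSE)))
  out <- matrix(NA_real_, length(features), length(samples),
                dimnames = list(features, samples))
  for (m in mats) out[rownames(m), colnames(m)] <- m
  out
}

#' Normalize each sample column to a common center
#'
#' Second normalization stage: corrects unintended channel-to-channel
#' variation introduced during labeling and mixing by dividing each
#' sample column by a per-column location statistic computed over the
#' features quantified in that column (default: the median ratio, so
#' each column's median log-ratio becomes zero).
#'
#' @param mat reference-normalized abundance matrix (features x
#'   samples; NA = not quantified).
#' @param stat centering statistic: `"median"` (default), `"mean"` or
#'   `"total"` (column sum).
#' @return Normalized matrix of the same shape; attribute `norm_factors`
#'   holds the per-sample divisors.
#' @export
normalize_within_channel <- function(mat, stat = c("median", "mean", "total")) {
  stat <- match.arg(stat)
  fun <- switch(stat, median = stats::median, mean = mean, total = sum)
  factors <- apply(mat, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else fun(x)
  })
  if (anyNA(factors))
    stop("sample(s) with no quantified features: ",
         paste(colnames(mat)[is.na(factors)], collapse = ", "), call. = FALSE)
  if (any(factors <= 0))
    stop("non-positive normalization factor for sample(s): ",
         paste(colnames(mat)[factors <= 0], collapse = ", "), call. = FALSE)
  out <- sweep(mat, 2, factors, "/")
  attr(out, "norm_factors") <- factors
  out
}

#' Run the full two-stage TMT quantitation chain
#'
#' Convenience wrapper: PEP 2D filtering, glycoPSM grouping, reference
#' channel normalization, plex merging and within-channel
#' normalization. Set `reference = FALSE` for within-sample comparison
#' modes (e.g. relative HEXA/HEXB subunit levels), which normalize
#' only within each channel.
#'
#' @param psms glycoPSM table.
#' @param design cohort design.
#' @param pep2d_max PEP 2D threshold.
#' @param ref_channel reference channel name.
#' @param within_stat statistic for [normalize_within_channel()].
#' @param reference apply the reference-channel stage (default TRUE).
#' @return Normalized abundance matrix (features x samples).
#' @export
quantify_tmt <- function(psms, design, pep2d_max = 0.001,
                         ref_channel = "126",
                         within_stat = "median", reference = TRUE) {
  psms <- filter_psms(psms, pep2d_max)
  if (!nrow(psms))
    stop("no PSMs pass the PEP 2D threshold", call. = FALSE)
  features <- group_glycopsms(psms)
  if (reference) {
    mats <- normalize_to_reference(features, design, ref_channel)
    mat <- merge_plexes(mats)
  } else {
    mats <- list()
    for (p in sort(unique(features$plex))) {
      f <- features[features$plex == p, , drop = FALSE]
      dsub <- design[design$plex == p, , drop = FALSE]
      m <- as.matrix(f[, dsub$channel, drop = FALSE])
      dimnames(m) <- list(.feature_key(f), dsub$sample_id)
      mats[[as.character(p)]] <- m
    }
    mat <- merge_plexes(mats)
  }
  normalize_within_channel(mat, within_stat)
}
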