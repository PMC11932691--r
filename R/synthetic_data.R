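#' TMT-10plex channel names
#'
#' @param ref_channel reference channel name (excluded from the sample
#'   channels).
#' @return Character vector of the ten reporter channel names.
#' @export
tmt10_channels <- function(ref_channel = "126") {
  ch <- c("126", "127N", "127C", "128N", "128C",
          "129N", "129C", "130N", "130C", "131")
  if (!ref_channel %in% ch)
    stop("unknown reference channel: ", ref_channel, call. = FALSE)
  ch
}

#' Discovery cohort design: samples, groups, plexes, channels
#'
#' Builds the default 36-sample design: `n_per_stage` donors per CRC
#' stage I-IV plus `n_control` controls, labeled across `n_plex`
#' TMT-10plex batches sharing a pooled reference channel. Samples are
#' interleaved across groups before being dealt into plexes so that
#' every plex contains at least one sample of each stage and at least
#' one control.
#'
#' @param n_per_stage donors per CRC stage (default 7).
#' @param n_control control donors (default 8).
#' @param stages stage labels.
#' @param n_plex number of TMT-10plex batches (default 4).
#' @param ref_channel reporter channel reserved for the pooled
#'   reference in every plex (default `"126"`).
#' @return A data.frame with columns `sample_id`, `group` (`control` or
#'   `stage_*`), `plex`, `channel`; attribute `ref_channel`.
#' @export
cohort_design <- function(n_per_stage = 7, n_control = 8,
                          stages = c("I", "II", "III", "IV"),
                          n_plex = 4, ref_channel = "126") {
  groups <- c(paste0("stage_", stages), "control")
  ns <- c(rep(n_per_stage, length(stages)), n_control)
  ids <- mapply(function(g, n) paste0(g, "_", seq_len(n)),
                groups, ns, SIMPLIFY = FALSE)
  # interleave one sample per group per round, then deal into plexes
  rounds <- max(ns)
  order_ids <- character(0)
  order_grp <- character(0)
  for (r in seq_len(rounds)) {
    for (k in seq_along(groups)) {
      if (r <= ns[k]) {
        order_ids <- c(order_ids, ids[[k]][r])
        order_grp <- c(order_grp, groups[k])
      }
    }
  }
  n <- length(order_ids)
  sample_ch <- setdiff(tmt10_channels(ref_channel), ref_channel)
  per_plex <- length(sample_ch)
  if (n > n_plex * per_plex)
    stop("design does not fit: ", n, " samples exceed ", n_plex,
         " plexes x ", per_plex, " sample channels", call. = FALSE)
  plex <- ceiling(seq_len(n) / per_plex)
  channel <- sample_ch[((seq_len(n) - 1) %% per_plex) + 1]
  design <- data.frame(sample_id = order_ids, group = order_grp,
                       plex = plex, channel = channel,
                       stringsAsFactors = FALSE)
  for (p in unique(plex)) {
    g <- unique(design$group[design$plex == p])
    if (!all(groups %in% g))
      stop("plex ", p, " lacks a sample from every group", call. = FALSE)
  }
  attr(design, "ref_channel") <- ref_channel
  design
}

# species catalogue used by the default glycome profiles: composition,
# short label, class, and within-class weight
.default_species <- function() {
  sp <- rbind(
    data.frame(composition = c("Hex1HexNAc2", "Hex1HexNAc2dHex1",
                               "Hex2HexNAc2", "Hex2HexNAc2dHex1",
                               "Hex3HexNAc2", "Hex3HexNAc2dHex1"),
               label = c("M1", "M1F", "M2", "M2F", "M3", "M3F"),
               class = "paucimannose",
               weight = c(0.04, 0.04, 0.09, 0.30, 0.18, 0.35)),
    data.frame(composition = c("HexNAc1", "HexNAc1dHex1",
                               "HexNAc2", "HexNAc2dHex1"),
               label = c("GlcNAc1", "GlcNAc1F", "M0", "M0F"),
               class = "chitobiose_core",
               weight = c(0.15, 0.15, 0.35, 0.35)),
    data.frame(composition = paste0("Hex", 5:9, "HexNAc2"),
               label = paste0("Man", 5:9),
               class = "oligomannose",
               weight = c(0.30, 0.25, 0.20, 0.15, 0.10)),
    data.frame(composition = c("Hex5HexNAc3", "Hex6HexNAc3dHex1"),
               label = c("Hyb1", "Hyb2"),
               class = "hybrid",
               weight = c(0.5, 0.5)),
    data.frame(composition = c("Hex5HexNAc4", "Hex5HexNAc4dHex1",
                               "Hex5HexNAc4dHex1NeuAc2",
                               "Hex6HexNAc5dHex1NeuAc1",
                               "Hex7HexNAc6dHex1NeuAc3"),
               label = paste0("Cplx", 1:5),
               class = "complex",
               weight = c(0.25, 0.30, 0.25, 0.15, 0.05))
  )
  rownames(sp) <- NULL
  sp
}

#' Default group-level glycome profiles
#'
#' Mean class shares per donor group for the two discovery matrices.
#' Paucimannose shares follow the reported cohort means: tissue NAT
#' (control) 6.7% rising to 13.5-15.4% across tumor stages I-IV;
#' PBMC controls 14.9% rising to 19.5-27.1% across stages. Stage
#' values inside each printed range are interpolated linearly. The
#' remaining glycome is split over chitobiose core, oligomannose,
#' hybrid and complex classes in a fixed base mix (3/28/7/62), scaled
#' to fill `1 - paucimannose share`. Within-class species weights put
#' 65% of the paucimannosidic signal on the dominant core-fucosylated
#' M2F + M3F species.
#'
#' @param type `"tissue"` (TUM vs NAT) or `"pbmc"` (patient vs control
#'   PBMC).
#' @param dispersion standard deviation of the logistic-normal noise
#'   applied to log class shares per sample (0 = exact group means).
#' @return A `glycome_profile` list: `class_shares` (group x class
#'   matrix, rows summing to 1), `species` (catalogue with within-class
#'   weights summing to 1 per class), `dispersion`.
#' @export
glycome_profile <- function(type = c("tissue", "pbmc"), dispersion = 0.15) {
  type <- match.arg(type)
  pauci <- switch(type,
    tissue = c(control = 0.067, stage_I = 0.135, stage_II = 0.141,
               stage_III = 0.148, stage_IV = 0.154),
    pbmc = c(control = 0.149, stage_I = 0.195, stage_II = 0.220,
             stage_III = 0.246, stage_IV = 0.271))
  base <- c(chitobiose_core = 0.03, oligomannose = 0.28,
            hybrid = 0.07, complex = 0.62)
  shares <- t(vapply(pauci, function(p) c(paucimannose = p, base * (1 - p)),
                     numeric(5)))
  colnames(shares) <- c("paucimannose", names(base))
  profile <- list(class_shares = shares, species = .default_species(),
                  dispersion = dispersion)
  class(profile) <- "glycome_profile"
  validate_glycome_profile(profile)
}

#' @rdname glycome_profile
#' @param profile a `glycome_profile` to validate.
#' @export
validate_glycome_profile <- function(profile) {
  sh <- profile$class_shares
  if (any(sh < 0) || any(sh > 1) || any(abs(rowSums(sh) - 1) > 1e-9))
    stop("class shares must lie in [0,1] and sum to 1 per group",
         call. = FALSE)
  w <- tapply(profile$species$weight, profile$species$class, sum)
  if (any(abs(w - 1) > 1e-9))
    stop("species weights must sum to 1 within each class", call. = FALSE)
  if (!is.numeric(profile$dispersion) || profile$dispersion < 0)
    stop("dispersion must be a non-negative number", call. = FALSE)
  profile
}

#' Generate a per-sample glycome table with known ground truth
#'
#' Draws per-sample class shares around the group means of `profile`
#' with logistic-normal noise (Gaussian perturbation of log shares,
#' renormalized by softmax; dispersion 0 reproduces the means exactly),
#' then spreads each class share over its member species by the
#' profile's within-class weights. Relative abundances sum to 1 per
#' sample.
#'
#' @param design cohort design from [cohort_design()] (or any
#'   data.frame with `sample_id` and `group`).
#' @param profile a [glycome_profile()].
#' @param seed integer seed; the generator is a pure function of
#'   (design, profile, seed).
#' @return A data.frame: `composition`, `label` and one numeric column
#'   per sample; attribute `design`.
#' @export
generate_glycome_table <- function(design, profile = glycome_profile("tissue"),
                                   seed = 1) {
  validate_glycome_profile(profile)
  missing <- setdiff(unique(design$group), rownames(profile$class_shares))
  if (length(missing))
    stop("profile lacks class shares for group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sp <- profile$species
  classes <- colnames(profile$class_shares)
  out <- data.frame(composition = sp$composition, label = sp$label,
                    stringsAsFactors = FALSE)
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  for (i in seq_len(nrow(design))) {
    mu <- profile$class_shares[design$group[i], classes]
    z <- log(mu) + stats::rnorm(length(mu), 0, profile$dispersion)
    share <- exp(z - max(z))
    share <- share / sum(share)
    names(share) <- classes
    out[[design$sample_id[i]]] <- share[sp$class] * sp$weight
  }
  attr(out, "design") <- design
  out
}

# run code under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a glycoPSM table with TMT reporter intensities
#'
#' Emulates a search-engine glycoPSM export: each ground-truth feature
#' (protein accession, glycosylation site, glycan composition) with
#' per-sample true abundances spawns 1-5 PSMs per plex whose reporter
#' intensities sum to the feature total. Per-plex multiplicative batch
#' factors, per-channel multiplicative biases and multiplicative
#' log-normal measurement noise are injected; the reference channel of
#' each plex carries the pooled mean of the feature's true abundances
#' over all samples (times the plex batch factor). A `decoy_fraction`
#' of PSMs receives a PEP 2D score at or above the confidence
#' threshold, emulating identifications that downstream filtering must
#' remove.
#'
#' @param design cohort design from [cohort_design()].
#' @param truth list with `features` (data.frame: `accession`, `site`,
#'   `composition`) and `abundance` (features x samples matrix of true
#'   relative abundances; columns named by `sample_id`).
#' @param seed integer seed.
#' @param max_psms maximum PSMs per feature per plex (drawn uniformly
#'   from 1..max_psms; 1 = one PSM each).
#' @param batch_sd,channel_sd,noise_sd standard deviations of the
#'   log-normal plex batch factors, channel biases and per-measurement
#'   noise (0 = none).
#' @param decoy_fraction probability that a PSM is flagged with
#'   PEP 2D >= 0.001.
#' @return A data.frame with columns `spectrum_id`, `accession`,
#'   `site`, `composition`, `pep2d`, `plex` and one intensity column
#'   per reporter channel (named as in [tmt10_channels()]).
#' @export
generate_glycopsm_table <- function(design, truth, seed = 1, max_psms = 5,
                                    batch_sd = 0, channel_sd = 0,
                                    noise_sd = 0, decoy_fraction = 0) {
  if (is.null(truth$features) || nrow(truth$features) == 0)
    stop("truth map must contain at least one feature", call. = FALSE)
  feats <- truth$features
  ab <- truth$abundance
  stopifnot(nrow(ab) == nrow(feats), all(design$sample_id %in% colnames(ab)))
  ref_channel <- attr(design, "ref_channel")
  if (is.null(ref_channel)) ref_channel <- "126"
  channels <- tmt10_channels(ref_channel)
  plexes <- sort(unique(design$plex))

  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  batch <- stats::setNames(exp(stats::rnorm(length(plexes), 0, batch_sd)),
                           plexes)
  bias <- matrix(exp(stats::rnorm(length(plexes) * length(channels),
                                  0, channel_sd)),
                 nrow = length(plexes),
                 dimnames = list(plexes, channels))

  rows <- list()
  spec <- 0L
  for (p in plexes) {
    dsub <- design[design$plex == p, ]
    for (f in seq_len(nrow(feats))) {
      k <- if (max_psms > 1) sample.int(max_psms, 1) else 1L
      w <- stats::rexp(k)
      w <- w / sum(w)
      ref_true <- mean(ab[f, design$sample_id])
      for (j in seq_len(k)) {
        spec <- spec + 1L
        inten <- stats::setNames(numeric(length(channels)), channels)
        noise <- function() exp(stats::rnorm(1, 0, noise_sd))
        inten[ref_channel] <- ref_true * batch[[as.character(p)]] *
          bias[as.character(p), ref_channel] * w[j] * noise()
        for (s in seq_len(nrow(dsub))) {
          ch <- dsub$channel[s]
          inten[ch] <- ab[f, dsub$sample_id[s]] * batch[[as.character(p)]] *
            bias[as.character(p), ch] * w[j] * noise()
        }
        decoy <- stats::runif(1) < decoy_fraction
        pep2d <- if (decoy) stats::runif(1, 0.001, 0.5)
                 else stats::runif(1, 0, 0.0009)
        rows[[spec]] <- data.frame(
          spectrum_id = paste0("scan_", spec),
          accession = feats$accession[f], site = feats$site[f],
          composition = feats$composition[f],
          pep2d = pep2d, plex = p,
          t(inten), check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  psms <- do.call(rbind, rows)
  rownames(psms) <- NULL
  attr(psms, "ref_channel") <- ref_channel
  psms
}

#' Generate synthetic protein-to-cell-origin annotation sets
#'
#' Emulates curated tissue/blood atlas annotation sets: bone
#' marrow-annotated proteins plus the four immune cell lineages, with
#' configurable sizes and a controlled overlap between the bone-marrow
#' set and each cell-type set. Cell-type sets are pairwise disjoint.
#'
#' @param seed integer seed.
#' @param sizes named integer vector of set sizes.
#' @param overlap_fraction fraction of each cell-type set shared with
#'   the bone-marrow set (0 = all sets pairwise disjoint).
#' @return Named list of character vectors of synthetic accessions.
#' @export
generate_annotation_sets <- function(seed = 1,
                                     sizes = c(bone_marrow = 534,
                                               nk_cell = 114, b_cell = 141,
                                               t_cell = 262, monocyte = 201),
                                     overlap_fraction = 0.2) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1,
            "bone_marrow" %in% names(sizes))
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  universe <- sprintf("SYNP%05d", seq_len(sum(sizes) + 2000L))
  universe <- sample(universe)
  bm <- universe[seq_len(sizes[["bone_marrow"]])]
  used <- sizes[["bone_marrow"]]
  sets <- list(bone_marrow = bm)
  bm_pool <- bm
  for (nm in setdiff(names(sizes), "bone_marrow")) {
    n <- sizes[[nm]]
    n_shared <- round(overlap_fraction * n)
    n_shared <- min(n_shared, length(bm_pool))
    shared <- if (n_shared > 0) bm_pool[seq_len(n_shared)] else character(0)
    bm_pool <- setdiff(bm_pool, shared)  # keep cell-type sets disjoint
    own <- universe[used + seq_len(n - n_shared)]
    used <- used + (n - n_shared)
    sets[[nm]] <- sort(c(shared, own))
  }
  sets$bone_marrow <- sort(sets$bone_marrow)
  sets
}

#' Generate fluorometric plate readings with known activities
#'
#' Emulates a 4-MU hexosaminidase activity plate: standard wells at
#' known 4-MU amounts follow `fluorescence = slope * amount +
#' intercept + noise`; blank wells read `intercept + noise`; sample
#' wells (technical replicates for the MUG and MUGS substrates) encode
#' planted true activities (4-MU amount released per minute per input
#' amount) through the same linear response.
#'
#' @param activities data.frame with columns `sample_id`, `mug`,
#'   `mugs` (true activities, >= 0) and logical `is_control`.
#' @param slope,intercept standard-curve parameters (slope > 0).
#' @param noise_sd additive Gaussian fluorescence noise SD.
#' @param standards 4-MU amounts of the standard wells.
#' @param n_replicates technical replicates per sample and substrate.
#' @param time incubation time, minutes.
#' @param amount input amount (ug protein or ul plasma) per well.
#' @param n_blanks number of blank wells.
#' @param plate plate identifier recorded on every well.
#' @param seed integer seed.
#' @return A data.frame of wells: `well`, `plate`, `role`
#'   (standard/blank/sample), `sample_id`, `substrate`, `replicate`,
#'   `concentration`, `fluorescence`, `is_control`; attributes `time`
#'   and `amount`.
#' @export
generate_plate_readings <- function(activities, slope = 100, intercept = 50,
                                    noise_sd = 0,
                                    standards = c(0.5, 1, 2, 5, 10, 20),
                                    n_replicates = 3, time = 30, amount = 2,
                                    n_blanks = 3, plate = "plate1", seed = 1) {
  if (slope <= 0) stop("standard-curve slope must be positive", call. = FALSE)
  stopifnot(all(c("sample_id", "mug", "mugs", "is_control") %in%
                  names(activities)),
            all(activities$mug >= 0), all(activities$mugs >= 0))
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  noise <- function(n) stats::rnorm(n, 0, noise_sd)
  wells <- list()
  wells$std <- data.frame(role = "standard", sample_id = NA_character_,
                          substrate = NA_character_, replicate = 1L,
                          concentration = standards,
                          fluorescence = slope * standards + intercept +
                            noise(length(standards)),
                          is_control = NA)
  wells$blank <- data.frame(role = "blank", sample_id = NA_character_,
                            substrate = NA_character_,
                            replicate = seq_len(n_blanks),
                            concentration = 0,
                            fluorescence = intercept + noise(n_blanks),
                            is_control = NA)
  for (sub in c("MUG", "MUGS")) {
    act <- if (sub == "MUG") activities$mug else activities$mugs
    for (r in seq_len(n_replicates)) {
      wells[[paste0(sub, r)]] <- data.frame(
        role = "sample", sample_id = activities$sample_id,
        substrate = sub, replicate = r, concentration = NA_real_,
        fluorescence = slope * act * time * amount + intercept +
          noise(nrow(activities)),
        is_control = activities$is_control)
    }
  }
  out <- do.call(rbind, wells)
  out <- cbind(well = sprintf("W%03d", seq_len(nrow(out))),
               plate = plate, out)
  rownames(out) <- NULL
  attr(out, "time") <- time
  attr(out, "amount") <- amount
  out
}

#' Configuration for the plasma survival cohort simulator
#'
#' Defaults follow the study's 380-donor plasma cohort: 302 CRC
#' patients (of whom, in expectation, the nonsurvivor fraction 87/302
#' die within the 5-year follow-up) and 78 healthy controls; age 63.9
#' (SD 12.7) years; plasma Hex activity 1.0 (SD 0.3) relative activity
#' units; log hazard-ratio coefficients at the multivariable estimates
#' (HR 2.04 per activity unit, 1.03 per year of age). The baseline
#' hazard, when not given, is calibrated numerically so that the
#' expected 5-year event fraction among CRC donors equals
#' `event_fraction` under the covariate distribution.
#'
#' @param n_crc,n_healthy donors per arm.
#' @param age_mean,age_sd age distribution, years.
#' @param activity_mean,activity_sd plasma Hex activity distribution,
#'   relative activity units.
#' @param rho age-activity correlation.
#' @param beta_activity,beta_age log hazard ratios per unit covariate.
#' @param baseline_hazard events per year at covariate value zero;
#'   `NULL` to calibrate from `event_fraction`.
#' @param event_fraction target expected fraction of CRC donors with
#'   an event before censoring (used only when `baseline_hazard` is
#'   `NULL`).
#' @param censor_time administrative censoring time, years.
#' @return A `survival_sim_config` list.
#' @export
survival_sim_config <- function(n_crc = 302, n_healthy = 78,
                                age_mean = 63.9, age_sd = 12.7,
                                activity_mean = 1.0, activity_sd = 0.3,
                                rho = 0.2,
                                beta_activity = log(2.04),
                                beta_age = log(1.03),
                                baseline_hazard = NULL,
                                event_fraction = 87 / 302,
                                censor_time = 5) {
  cfg <- list(n_crc = n_crc, n_healthy = n_healthy,
              age_mean = age_mean, age_sd = age_sd,
              activity_mean = activity_mean, activity_sd = activity_sd,
              rho = rho, beta_activity = beta_activity, beta_age = beta_age,
              baseline_hazard = baseline_hazard,
              event_fraction = event_fraction, censor_time = censor_time)
  if (age_sd <= 0 || activity_sd <= 0)
    stop("covariate SDs must be positive", call. = FALSE)
  if (abs(rho) >= 1) stop("correlation must lie in (-1, 1)", call. = FALSE)
  if (censor_time <= 0) stop("censoring time must be positive", call. = FALSE)
  if (is.null(baseline_hazard))
    cfg$baseline_hazard <- calibrate_baseline_hazard(cfg)
  else if (baseline_hazard <= 0)
    stop("baseline hazard must be positive", call. = FALSE)
  class(cfg) <- "survival_sim_config"
  cfg
}

#' Calibrate the baseline hazard to a target event fraction
#'
#' Solves for the exponential baseline hazard h0 such that the
#' expected fraction of donors with an event before administrative
#' censoring equals `cfg$event_fraction`, integrating the conditional
#' event probability `1 - exp(-t_c * h0 * exp(eta))` over the normal
#' distribution of the linear predictor eta implied by the covariate
#' means, SDs, correlation and coefficients.
#'
#' @param cfg a [survival_sim_config()] list (baseline hazard ignored).
#' @return Baseline hazard, events per year.
#' @export
calibrate_baseline_hazard <- function(cfg) {
  mu <- cfg$beta_activity * cfg$activity_mean + cfg$beta_age * cfg$age_mean
  s2 <- cfg$beta_activity^2 * cfg$activity_sd^2 +
    cfg$beta_age^2 * cfg$age_sd^2 +
    2 * cfg$rho * cfg$beta_activity * cfg$beta_age *
      cfg$activity_sd * cfg$age_sd
  pevent <- function(log_h0) {
    f <- function(eta)
      (1 - exp(-cfg$censor_time * exp(log_h0 + eta))) *
        stats::dnorm(eta, mu, sqrt(s2))
    stats::integrate(f, mu - 8 * sqrt(s2), mu + 8 * sqrt(s2))$value
  }
  sol <- stats::uniroot(function(lh) pevent(lh) - cfg$event_fraction,
                        interval = c(-30, 10), tol = 1e-10)
  exp(sol$root)
}

#' Simulate the plasma survival cohort
#'
#' Draws (age, activity) per donor from a bivariate normal at the
#' configured means, SDs and correlation; CRC donors receive an
#' exponential event time with hazard `h0 * exp(beta_act * activity +
#' beta_age * age)`, administratively censored at `censor_time`.
#' Healthy controls carry covariates only (no follow-up).
#'
#' @param cfg a [survival_sim_config()].
#' @param seed integer seed.
#' @return A data.frame: `id`, `group` (`crc` / `healthy`), `age`,
#'   `activity`, `event` (1 = death within follow-up; NA for healthy),
#'   `time` (years; NA for healthy).
#' @export
generate_survival_cohort <- function(cfg = survival_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "survival_sim_config"))
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  n <- cfg$n_crc + cfg$n_healthy
  z1 <- stats::rnorm(n)
  z2 <- cfg$rho * z1 + sqrt(1 - cfg$rho^2) * stats::rnorm(n)
  age <- cfg$age_mean + cfg$age_sd * z1
  activity <- cfg$activity_mean + cfg$activity_sd * z2
  group <- rep(c("crc", "healthy"), c(cfg$n_crc, cfg$n_healthy))
  hazard <- cfg$baseline_hazard *
    exp(cfg$beta_activity * activity + cfg$beta_age * age)
  t_event <- stats::rexp(n, rate = hazard)
  time <- pmin(t_event, cfg$censor_time)
  event <- as.integer(t_event <= cfg$censor_time)
  time[group == "healthy"] <- NA_real_
  event[group == "healthy"] <- NA_integer_
  data.frame(id = sprintf("donor_%03d", seq_len(n)), group = group,
             age = age, activity = activity, event = event, time = time,
             stringsAsFactors = FALSE)
}

#' Draw paired variables with a planted population correlation
#'
#' Bivariate normal sampler used to emulate paired measurements whose
#' population Pearson correlation is known (marker score vs glycan
#' class share; plasma vs PBMC activity).
#'
#' @param n pairs to draw.
#' @param rho population correlation.
#' @param mean,sd length-2 means and SDs of the two variables.
#' @param seed integer seed.
#' @return A data.frame with columns `x` and `y`.
#' @export
generate_correlated_pair <- function(n, rho, mean = c(0, 0), sd = c(1, 1),
                                     seed = 1) {
  stopifnot(abs(rho) <= 1, n >= 2, all(sd > 0))
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  data.frame(x = mean[1] + sd[1] * z1, y = mean[2] + sd[2] * z2)
}
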