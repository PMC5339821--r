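# The identification/quantification engine: ppm-gated precursor matching,
# MSMS confirmation, internal-standard quantification, MSMS-ratio subspecies
# amounts, and the quality-filter cascade.

#' Identification configuration
#'
#' All thresholds follow the platform's rules read as strict inequalities
#' exactly as worded: mass deviation below 3 ppm (MS) / 8 ppm (MSMS) with
#' lock mass, 5 / 12 ppm without; signal-to-noise greater than 5; amount at
#' least 5-fold above the batch blank (>= 5x); present in at least two
#' replicates (>= 2); amount above 2 pmol (> 2).
#'
#' @param ppm_ms_lock,ppm_msms_lock,ppm_ms_nolock,ppm_msms_nolock ppm gates.
#' @param sn_min Signal-to-noise gate (exclusive).
#' @param blank_fold Required fold-change over the batch blank (inclusive).
#' @param min_replicates Minimum replicate occurrence (inclusive).
#' @param min_pmol Minimum amount in pmol (exclusive).
#' @param k_max Isotope envelope truncation used in corrections.
#' @param resolution A [resolution_model()].
#' @return A list of class `id_config`.
#' @export
id_config <- function(ppm_ms_lock = 3, ppm_msms_lock = 8,
                      ppm_ms_nolock = 5, ppm_msms_nolock = 12,
                      sn_min = 5, blank_fold = 5, min_replicates = 2,
                      min_pmol = 2, k_max = 3, resolution = resolution_model()) {
  vals <- c(ppm_ms_lock, ppm_msms_lock, ppm_ms_nolock, ppm_msms_nolock,
            sn_min, blank_fold, min_replicates, min_pmol)
  if (any(vals <= 0)) abort("all id_config thresholds must be positive")
  if (ppm_ms_lock > ppm_ms_nolock || ppm_msms_lock > ppm_msms_nolock) {
    abort("lock-mass ppm gates must not exceed the no-lock gates")
  }
  structure(list(
    ppm_ms_lock = ppm_ms_lock, ppm_msms_lock = ppm_msms_lock,
    ppm_ms_nolock = ppm_ms_nolock, ppm_msms_nolock = ppm_msms_nolock,
    sn_min = sn_min, blank_fold = blank_fold, min_replicates = min_replicates,
    min_pmol = min_pmol, k_max = k_max, resolution = resolution
  ), class = "id_config")
}

.ppm_gate <- function(cfg, level, lockmass) {
  if (level == "MS") {
    if (lockmass) cfg$ppm_ms_lock else cfg$ppm_ms_nolock
  } else {
    if (lockmass) cfg$ppm_msms_lock else cfg$ppm_msms_nolock
  }
}

#' The spiked internal-standard manifest
#'
#' One deuterated (or otherwise non-native) standard per covered class
#' group, with spiked amounts per sample: 42 pmol EOS D9 68:3;2, 14 pmol
#' NS D3 36:1;2, 50 pmol DAG D5 34:0;0, 100 pmol CE 20:0;0, 1000 pmol
#' cholesterol D6 and 100 pmol TAG D5 51:0;0. Non- and alpha-hydroxy
#' ceramides normalize to the deuterated NS; omega-hydroxy (EO) ceramides to
#' the deuterated EOS. The covered-class sets partition all 16 classes.
#'
#' @return A tibble with columns `standard_id`, `class`, `subspecies`,
#'   `n_deuterium`, `spike_pmol`, `covers` (list-column of class codes),
#'   `formula` (labelled), `neutral_mass`, `adduct`, `polarity`, `mz`,
#'   `acquisition` (which acquisition the standard appears in).
#' @export
internal_standards <- function() {
  man <- tibble(
    standard_id = c("EOS_D9", "NS_D3", "DAG_D5", "CE_20_0", "CHOL_D6", "TAG_D5"),
    class = c("EOS", "NS", "DAG", "CE", "Chol", "TAG"),
    subspecies = c("EOS 18:1;2–32:0;0–18:2;0", "NS 18:1;2–18:0;0",
                   "DAG 17:0;0–17:0;0", "CE 20:0;0", "Chol",
                   "TAG 17:0;0–17:1;0–17:0;0"),
    n_deuterium = c(9L, 3L, 5L, 0L, 6L, 5L),
    spike_pmol = c(42, 14, 50, 100, 1000, 100),
    covers = list(
      c("EOdS", "EOS", "EOP", "EOH"),
      c("NdS", "NS", "NP", "NH", "AdS", "AS", "AP", "AH"),
      "DAG", "CE", "Chol", "TAG"
    )
  )
  info <- purrr::pmap(man, function(standard_id, class, subspecies, n_deuterium, ...) {
    sub <- parse_subspecies_name(subspecies)
    f <- apply_label(species_formula(class, sub$chains), n_deuterium)
    row <- .class_row(class)
    m <- monoisotopic_mass(f)
    tibble(formula = format(f), neutral_mass = m, adduct = row$adduct,
           polarity = row$ion_mode, mz = adduct_mz(m, row$adduct))
  })
  out <- dplyr::bind_cols(man, dplyr::bind_rows(info))
  out$acquisition <- ifelse(out$class == "Chol", "cholesterol-derivatized", "main")
  out
}

.sn_of <- function(intensity, noise) {
  ifelse(noise > 0, intensity / noise, Inf) # noise 0 = unknown: gate not applicable
}

.match_peaks_to_targets <- function(peaks, targets, gate_ppm, sn_min) {
  # peak-centric: each peak is assigned to the nearest target within the ppm
  # gate; peaks matching >= 2 targets (isobaric/isomeric candidates) carry
  # all of them, flagged ambiguous, for MSMS arbitration downstream.
  if (nrow(peaks) == 0 || nrow(targets) == 0) return(NULL)
  t_ord <- order(targets$mz)
  t_mz <- targets$mz[t_ord]
  acc <- list(target = integer(), mz_obs = numeric(), ppm_error = numeric(),
              intensity = numeric(), noise = numeric(), sn = numeric(),
              nearest = logical(), ambiguous = logical(), peak_index = integer())
  for (p in seq_len(nrow(peaks))) {
    mz <- peaks$mz[p]
    sn <- .sn_of(peaks$intensity[p], peaks$noise[p])
    if (!(sn > sn_min)) next
    ppm_all <- abs(mz - t_mz) / t_mz * 1e6
    within <- which(ppm_all < gate_ppm)
    if (length(within) == 0) next
    within <- within[order(ppm_all[within])] # nearest first
    k <- length(within)
    acc$target <- c(acc$target, t_ord[within])
    acc$mz_obs <- c(acc$mz_obs, rep(mz, k))
    acc$ppm_error <- c(acc$ppm_error, (mz - t_mz[within]) / t_mz[within] * 1e6)
    acc$intensity <- c(acc$intensity, rep(peaks$intensity[p], k))
    acc$noise <- c(acc$noise, rep(peaks$noise[p], k))
    acc$sn <- c(acc$sn, rep(sn, k))
    acc$nearest <- c(acc$nearest, seq_len(k) == 1)
    acc$ambiguous <- c(acc$ambiguous, rep(k >= 2, k))
    acc$peak_index <- c(acc$peak_index, rep(p, k))
  }
  if (length(acc$target) == 0) return(NULL)
  tibble::new_tibble(acc, nrow = length(acc$target))
}

#' Match MS precursor peaks against a candidate database
#'
#' A peak matches a candidate iff its relative mass deviation is below the
#' scan's ppm gate (3 ppm with lock mass, 5 without) and its S/N exceeds the
#' gate (> 5). Each peak is assigned to its nearest candidate within the
#' gate; peaks falling within the gate of two or more distinct species (e.g.
#' the isobaric NP/AdS and NH/AS pairs) are flagged ambiguous, to be
#' resolved by MSMS. Candidates are collapsed to species level (all chain
#' splits of a sum composition share one precursor m/z).
#'
#' @param run An `acquisition_run`.
#' @param db Candidate tibble from [enumerate_species()].
#' @param cfg An [id_config()].
#' @param standards Optional [internal_standards()] manifest, matched in the
#'   same pass (rows marked with `standard_id`).
#' @return Identification tibble: one row per (species, MS scan) match.
#' @export
match_precursors <- function(run, db, cfg = id_config(), standards = NULL) {
  targets <- dplyr::distinct(db, .data$class, .data$species, .data$polarity,
                             .data$mz, .data$formula)
  targets$standard_id <- NA_character_
  targets$spike_pmol <- NA_real_
  if (!is.null(standards)) {
    std <- standards[standards$acquisition ==
                       ifelse(run$kind == "cholesterol-derivatized", "cholesterol-derivatized", "main"), ]
    targets <- dplyr::bind_rows(targets, tibble(
      class = std$class, species = std$subspecies, polarity = std$polarity,
      mz = std$mz, formula = std$formula,
      standard_id = std$standard_id, spike_pmol = std$spike_pmol
    ))
  }
  ms <- run$spectra[run$spectra$level == "MS", ]
  out <- list()
  for (i in seq_len(nrow(ms))) {
    s <- ms[i, ]
    t_pol <- targets[targets$polarity == s$polarity, ]
    if (nrow(t_pol) == 0) next
    gate <- .ppm_gate(cfg, "MS", s$lockmass)
    m <- .match_peaks_to_targets(s$peaks[[1]], t_pol, gate, cfg$sn_min)
    if (is.null(m)) next
    # a target hit by several peaks keeps its nearest-in-ppm peak
    m <- m |>
      dplyr::group_by(.data$target) |>
      dplyr::slice_min(abs(.data$ppm_error), n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    hit <- t_pol[m$target, ]
    out[[length(out) + 1]] <- tibble(
      sample_id = run$sample_id,
      class = hit$class, species = hit$species, formula = hit$formula,
      polarity = hit$polarity, mz_theor = hit$mz,
      mz_obs = m$mz_obs, ppm_error = m$ppm_error,
      intensity = m$intensity, noise = m$noise, sn = m$sn,
      nearest = m$nearest, ambiguous = m$ambiguous,
      ms_scan = i, lockmass = s$lockmass,
      standard_id = hit$standard_id, spike_pmol = hit$spike_pmol
    )
  }
  if (length(out) == 0) {
    return(tibble(
      sample_id = character(), class = character(), species = character(),
      formula = character(), polarity = character(), mz_theor = numeric(),
      mz_obs = numeric(), ppm_error = numeric(), intensity = numeric(),
      noise = numeric(), sn = numeric(), nearest = logical(),
      ambiguous = logical(), ms_scan = integer(), lockmass = logical(),
      standard_id = character(), spike_pmol = numeric()
    ))
  }
  dplyr::bind_rows(out)
}

.msms_covering <- function(run, mz, polarity) {
  s <- run$spectra
  which(s$level == "MSMS" & s$polarity == polarity &
          !is.na(s$precursor_low) & s$precursor_low <= mz & mz <= s$precursor_high)
}

#' Confirm chain-resolved subspecies from MSMS fragments
#'
#' For each species-level identification, every candidate chain split in the
#' database is tested against the MSMS spectra whose precursor window covers
#' the precursor: a subspecies is confirmed iff all its required diagnostic
#' fragments are found within the MSMS ppm gate and above the S/N gate.
#' The NP/AdS and NH/AS isobaric pairs are decided solely by the
#' LCB-diagnostic fragment; when one member of an ambiguous precursor group
#' is confirmed and the other is not, the unconfirmed member is dropped.
#' Identifications without MSMS coverage or without a fully confirmed chain
#' split are retained at species level with a flag.
#'
#' @param ids Output of [match_precursors()].
#' @param run The same `acquisition_run`.
#' @param db Candidate tibble (subspecies level).
#' @param cfg An [id_config()].
#' @param rules Fragment-rule table ([fragment_rules()]).
#' @return Tibble: one row per confirmed subspecies or species-level
#'   identification, with `quant_intensity` (the subspecies quantification
#'   fragment intensity; NA at species level) and `evidence` (list-column).
#' @export
confirm_subspecies <- function(ids, run, db, cfg = id_config(), rules = fragment_rules()) {
  sp_ids <- ids |>
    dplyr::filter(is.na(.data$standard_id)) |>
    dplyr::group_by(.data$class, .data$species, .data$formula, .data$polarity,
                    .data$mz_theor, .data$ambiguous) |>
    dplyr::summarise(
      sample_id = .data$sample_id[1],
      intensity = mean(.data$intensity), sn = mean(.data$sn),
      ppm_error = .data$ppm_error[which.min(abs(.data$ppm_error))],
      .groups = "drop"
    )
  out <- list()
  for (r in seq_len(nrow(sp_ids))) {
    id <- sp_ids[r, ]
    cands <- db[db$class == id$class & db$species == id$species, ]
    scans <- .msms_covering(run, id$mz_theor, id$polarity)
    confirmed <- list()
    if (length(scans) > 0 && nrow(cands) > 0 &&
        id$class %in% rules$cls) {
      for (ci in seq_len(nrow(cands))) {
        fr <- expected_fragments(cands$subspecies[ci], rules, precursor_mz = id$mz_theor)
        nf <- nrow(fr)
        ev_obs <- numeric(nf); ev_int <- numeric(nf); ev_sn <- numeric(nf)
        ev_ppm <- numeric(nf); ev_found <- logical(nf)
        ok <- TRUE
        for (k in seq_len(nf)) {
          for (si in scans) {
            s <- run$spectra[si, ]
            gate <- .ppm_gate(cfg, "MSMS", s$lockmass)
            p <- s$peaks[[1]]
            ppm_all <- abs(p$mz - fr$mz[k]) / fr$mz[k] * 1e6
            sn_all <- .sn_of(p$intensity, p$noise)
            hit <- which(ppm_all < gate & sn_all > cfg$sn_min)
            if (length(hit) > 0) {
              b <- hit[which.min(ppm_all[hit])]
              ev_found[k] <- TRUE
              ev_obs[k] <- p$mz[b]; ev_int[k] <- p$intensity[b]
              ev_sn[k] <- sn_all[b]; ev_ppm[k] <- ppm_all[b]
              break
            }
          }
          if (!ev_found[k] && fr$required[k]) { ok <- FALSE; break }
        }
        if (ok && any(ev_found)) {
          ev <- tibble(
            kind = fr$kind[ev_found], chain = fr$chain[ev_found],
            mz_theor = fr$mz[ev_found], mz_obs = ev_obs[ev_found],
            ppm_error = ev_ppm[ev_found], intensity = ev_int[ev_found],
            sn = ev_sn[ev_found], quant = fr$quant[ev_found]
          )
          q <- ev$intensity[ev$quant]
          confirmed[[length(confirmed) + 1]] <- tibble(
            subspecies = cands$subspecies[ci],
            quant_intensity = if (length(q) > 0) sum(q) else NA_real_,
            evidence = list(ev)
          )
        }
      }
    }
    base <- id[, c("sample_id", "class", "species", "formula", "polarity",
                   "mz_theor", "ppm_error", "intensity", "sn", "ambiguous")]
    if (length(confirmed) > 1) {
      # unique-evidence rule: a chain split whose entire fragment set is
      # shared with the other passing splits (e.g. TAG 18/18/18 under a
      # spectrum of TAG 16/18/20) is not independently evidenced and is
      # dropped in their favour
      sets <- lapply(confirmed, function(cc) round(cc$evidence[[1]]$mz_theor, 4))
      uniq <- vapply(seq_along(sets), function(i) {
        others <- unlist(sets[-i])
        any(!sets[[i]] %in% others)
      }, logical(1))
      if (any(uniq)) confirmed <- confirmed[uniq]
    }
    if (length(confirmed) > 0) {
      conf <- dplyr::bind_rows(confirmed)
      out[[length(out) + 1]] <- dplyr::bind_cols(
        base[rep(1, nrow(conf)), ], conf,
        tibble(species_level_only = FALSE, msms_covered = TRUE)
      )
    } else {
      out[[length(out) + 1]] <- dplyr::bind_cols(
        base,
        tibble(subspecies = NA_character_, quant_intensity = NA_real_,
               evidence = list(tibble()), species_level_only = TRUE,
               msms_covered = length(scans) > 0)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  # ambiguous precursor groups: keep only confirmed members when any member
  # of the group (same theoretical m/z) was confirmed
  if (nrow(res) > 0) {
    res <- res |>
      dplyr::group_by(.data$polarity, grp = round(.data$mz_theor, 4)) |>
      dplyr::filter(!(.data$ambiguous & .data$species_level_only &
                        any(!.data$species_level_only))) |>
      dplyr::ungroup() |>
      dplyr::select(-"grp")
  }
  res
}

#' Split a species amount over its chain-resolved subspecies
#'
#' Amounts are proportional to the subspecies' characteristic MSMS fragment
#' intensities and sum exactly to the species amount. All-zero (or missing)
#' fragment intensities collapse to a single unresolved bucket carrying the
#' full amount.
#'
#' @param species_pmol Species amount (pmol).
#' @param fragment_intensities Named numeric vector, subspecies -> counts.
#' @return Named numeric vector of pmol (name `"unresolved"` when ratios are
#'   unavailable).
#' @export
resolve_subspecies_amounts <- function(species_pmol, fragment_intensities) {
  fi <- fragment_intensities[!is.na(fragment_intensities)]
  tot <- sum(fi)
  if (length(fi) == 0 || tot <= 0) {
    return(stats::setNames(species_pmol, "unresolved"))
  }
  stats::setNames(species_pmol * fi / tot, names(fi))
}

#' Quantify identifications against internal standards
#'
#' Species-level precursor intensities (averaged over MS scans) are type I
#' corrected across co-detected species at MS resolution, type II corrected
#' for their non-monoisotopic envelope fraction, and normalized to the
#' equally corrected intensity of the class's internal standard:
#' pmol = I_corr(species) / I_corr(standard) x spiked pmol. Species amounts
#' are then split over confirmed subspecies by their characteristic MSMS
#' fragment ratios.
#'
#' @param ids Output of [confirm_subspecies()] (or [match_precursors()] for
#'   species-level-only quantification).
#' @param match_ids Raw [match_precursors()] output for the same run (needed
#'   for the standards' intensities); when `ids` came straight from
#'   [match_precursors()] it is reused.
#' @param standards [internal_standards()] manifest.
#' @param cfg An [id_config()].
#' @return A QuantTable tibble: `sample_id`, `class`, `species`,
#'   `subspecies`, `pmol`, plus flags.
#' @export
quantify <- function(ids, match_ids = NULL, standards = internal_standards(),
                     cfg = id_config()) {
  if (!"subspecies" %in% names(ids)) {
    ids <- ids |>
      dplyr::filter(is.na(.data$standard_id)) |>
      dplyr::group_by(.data$class, .data$species, .data$formula, .data$polarity,
                      .data$mz_theor, .data$ambiguous) |>
      dplyr::summarise(sample_id = .data$sample_id[1],
                       intensity = mean(.data$intensity),
                       ppm_error = .data$ppm_error[which.min(abs(.data$ppm_error))],
                       sn = mean(.data$sn), .groups = "drop") |>
      dplyr::mutate(subspecies = NA_character_, quant_intensity = NA_real_,
                    species_level_only = TRUE, msms_covered = FALSE)
    if (is.null(match_ids)) abort("match_ids required when ids lack standards")
  }
  if (is.null(match_ids)) abort("match_ids (raw precursor matches incl. standards) required")
  std_obs <- match_ids |>
    dplyr::filter(!is.na(.data$standard_id)) |>
    dplyr::group_by(.data$standard_id, .data$formula, .data$polarity, .data$mz_theor) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop")

  sp <- dplyr::distinct(ids, .data$class, .data$species, .data$formula,
                        .data$polarity, .data$mz_theor, .data$intensity)
  # type I across everything sharing the acquisition (species + standards)
  all_pk <- dplyr::bind_rows(
    tibble(key = paste0("sp:", sp$class, "|", sp$species), mz = sp$mz_theor,
           intensity = sp$intensity, formula = sp$formula, polarity = sp$polarity),
    tibble(key = paste0("std:", std_obs$standard_id), mz = std_obs$mz_theor,
           intensity = std_obs$intensity, formula = std_obs$formula,
           polarity = std_obs$polarity)
  )
  corr <- all_pk |>
    dplyr::group_by(.data$polarity) |>
    dplyr::group_modify(function(g, ...) {
      correct_type1(g, model = cfg$resolution, level = "MS", k_max = cfg$k_max)
    }) |>
    dplyr::ungroup()
  corr$intensity_corr <- vapply(seq_len(nrow(corr)), function(i) {
    correct_type2(corr$intensity_type1[i], corr$formula[i], cfg$k_max)
  }, numeric(1))

  std_tbl <- standards
  std_tbl$intensity_corr <- corr$intensity_corr[match(paste0("std:", std_tbl$standard_id), corr$key)]
  cls2std <- tidyr::unnest(std_tbl[, c("standard_id", "spike_pmol", "intensity_corr", "covers")],
                           "covers")

  sp_key <- paste0("sp:", ids$class, "|", ids$species)
  ids$intensity_corr <- corr$intensity_corr[match(sp_key, corr$key)]
  j <- match(ids$class, cls2std$covers)
  if (anyNA(j)) {
    abort(paste0("no internal standard covers class(es): ",
                 paste(unique(ids$class[is.na(j)]), collapse = ", ")))
  }
  std_int <- cls2std$intensity_corr[j]
  unquantifiable <- is.na(std_int)
  zero_std <- !unquantifiable & std_int == 0
  if (any(zero_std)) {
    abort(paste0("internal standard intensity is zero for class(es): ",
                 paste(unique(ids$class[zero_std]), collapse = ", ")))
  }
  ids$species_pmol <- ifelse(unquantifiable, NA_real_,
                             ids$intensity_corr / std_int * cls2std$spike_pmol[j])

  # split species amounts over confirmed subspecies by fragment ratios
  out <- ids |>
    dplyr::group_by(.data$sample_id, .data$class, .data$species) |>
    dplyr::group_modify(function(g, ...) {
      pm <- g$species_pmol[1]
      if (is.na(pm)) {
        return(tibble(subspecies = NA_character_, pmol = NA_real_,
                      ambiguous = g$ambiguous[1], species_level_only = TRUE,
                      unquantifiable = TRUE))
      }
      if (all(is.na(g$subspecies))) {
        return(tibble(subspecies = NA_character_, pmol = pm,
                      ambiguous = g$ambiguous[1], species_level_only = TRUE,
                      unquantifiable = FALSE))
      }
      amounts <- resolve_subspecies_amounts(
        pm, stats::setNames(g$quant_intensity, g$subspecies))
      tibble(subspecies = names(amounts), pmol = unname(amounts),
             ambiguous = g$ambiguous[1],
             species_level_only = names(amounts) == "unresolved",
             unquantifiable = FALSE)
    }) |>
    dplyr::ungroup()
  out$subspecies[out$subspecies == "unresolved"] <- NA_character_
  dplyr::arrange(out, .data$sample_id, .data$class, .data$species, .data$subspecies)
}

#' Apply the quality-filter cascade to a quantitative table
#'
#' Per sample, a lipid is dropped when its amount is not above `min_pmol`
#' (> 2 pmol), or not at least `blank_fold` times the batch-blank mean
#' (>= 5x; lipids absent from blanks pass); lipids surviving in fewer than
#' `min_replicates` samples of their replicate group are then dropped from
#' the whole group. Every drop records its reason. Blanks themselves are
#' removed from the output. Batches without blanks skip the blank filter
#' with a warning.
#'
#' @param qt QuantTable tibble ([quantify()] output, possibly row-bound over
#'   samples).
#' @param meta Sample metadata ([read_sample_table()]).
#' @param cfg An [id_config()].
#' @return `qt` restricted to non-blank samples, with `kept` (logical) and
#'   `drop_reason` columns.
#' @export
apply_filters <- function(qt, meta, cfg = id_config()) {
  m <- meta[match(qt$sample_id, meta$sample_id), ]
  if (anyNA(m$sample_id)) {
    abort(paste0("samples missing from metadata: ",
                 paste(unique(qt$sample_id[is.na(m$sample_id)]), collapse = ", ")))
  }
  qt$lipid_key <- paste(qt$class, qt$species, dplyr::coalesce(qt$subspecies, "-"))
  qt$batch <- m$batch
  qt$replicate_group <- m$replicate_group
  qt$is_blank <- m$is_blank

  # batch blank aggregate (mean over the batch's blanks; absent = 0)
  blanks <- qt[qt$is_blank, ]
  blank_batches <- unique(meta$batch[meta$is_blank])
  no_blank <- setdiff(unique(qt$batch), blank_batches)
  if (length(no_blank) > 0) {
    warn(paste0("no blank samples in batch(es) ", paste(no_blank, collapse = ", "),
                "; blank filter skipped there"))
  }
  blank_level <- blanks |>
    dplyr::group_by(.data$batch, .data$lipid_key) |>
    dplyr::summarise(blank_sum = sum(.data$pmol, na.rm = TRUE), .groups = "drop")
  n_blanks <- meta |>
    dplyr::filter(.data$is_blank) |>
    dplyr::count(.data$batch, name = "n_blank")

  d <- qt[!qt$is_blank, ]
  d <- dplyr::left_join(d, blank_level, by = c("batch", "lipid_key"))
  d <- dplyr::left_join(d, n_blanks, by = "batch")
  d$blank_mean <- ifelse(is.na(d$n_blank), NA_real_,
                         dplyr::coalesce(d$blank_sum, 0) / d$n_blank)

  d$drop_reason <- NA_character_
  low <- !is.na(d$pmol) & d$pmol <= cfg$min_pmol
  d$drop_reason[low] <- "below_min_pmol"
  blank_fail <- is.na(d$drop_reason) & !is.na(d$blank_mean) & d$blank_mean > 0 &
    d$pmol < cfg$blank_fold * d$blank_mean
  d$drop_reason[blank_fail] <- "blank_fold"
  d$drop_reason[is.na(d$pmol)] <- "unquantifiable"

  # replicate occurrence: only where replicate groups exist
  surv <- is.na(d$drop_reason)
  has_grp <- !is.na(d$replicate_group)
  occ <- d[surv & has_grp, ] |>
    dplyr::distinct(.data$replicate_group, .data$lipid_key, .data$sample_id) |>
    dplyr::count(.data$replicate_group, .data$lipid_key, name = "n_occ")
  d <- dplyr::left_join(d, occ, by = c("replicate_group", "lipid_key"))
  rep_fail <- surv & has_grp & dplyr::coalesce(d$n_occ, 0L) < cfg$min_replicates
  d$drop_reason[rep_fail] <- "replicate_occurrence"

  d$kept <- is.na(d$drop_reason)
  d |>
    dplyr::select(-"blank_sum", -"n_blank", -"blank_mean", -"n_occ",
                  -"is_blank", -"lipid_key")
}
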