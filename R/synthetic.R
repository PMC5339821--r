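# In-silico study generator: ground-truth lipidomes for the study designs
# (replicate reproducibility, depth series, body-site panels, age/sex
# cohorts, spike series) and an acquisition renderer producing centroided
# spectra with isotope envelopes, per-peak noise, spiked standards and
# blanks -- the inverse of the identification engine, used to validate it.

#' Reference class mol% profiles
#'
#' Two endmember compositions: `sc_proper` approximates the ceramide- and
#' cholesterol-dominated stratum corneum matrix; `sebum_rich` the TAG/DAG-
#' dominated surface film. Any sample profile is a convex mix of the two
#' (the sebum mix fraction), which reproduces the depth gradients: sebum
#' classes decay with layer while ceramides and cholesterol rise.
#'
#' @return A tibble `class`, `sc_proper`, `sebum_rich` (mol%, each column
#'   sums to 100).
#' @export
class_profiles <- function() {
  tibble(
    class = c("NdS", "NS", "NP", "NH", "AdS", "AS", "AP", "AH",
              "EOdS", "EOS", "EOP", "EOH", "CE", "DAG", "TAG", "Chol"),
    sc_proper = c(4, 12, 8, 6, 3, 7, 5, 4, 1, 3, 1.5, 1.5, 8, 2, 4, 30),
    sebum_rich = c(1.6, 4.8, 3.2, 2.4, 1.2, 2.8, 2, 1.6, 0.4, 1.2, 0.6, 0.6,
                   12, 12, 41.6, 12)
  )
}

#' Narrowed enumeration constraints for simulation-scale candidate spaces
#' @param ... Overrides passed to [default_constraints()].
#' @return An `enum_constraints` list (a few hundred candidates).
#' @export
sim_constraints <- function(...) {
  default_constraints(
    lcb_c = c(18, 20),
    fa_c = seq(16, 26, 2), fa_db = 0:1,
    ester_c = seq(16, 20, 2), ester_db = 0:1,
    ce_fa_c = seq(14, 24, 2), ce_fa_db = 0:1,
    dag_fa_c = seq(16, 20, 2), dag_fa_db = 0:1,
    tag_fa_c = seq(16, 20, 2), tag_fa_db = 0:1,
    ...
  )
}

# ---- study designs ----------------------------------------------------------

.meta_row <- function(sample_id, subject_id = NA, sex = NA, age = NA,
                      site = "volar forearm", layer = 2L, replicate_group = NA,
                      is_blank = FALSE, batch = "B1") {
  tibble(sample_id = sample_id, subject_id = as.character(subject_id),
         sex = as.character(sex), age = as.numeric(age), site = site,
         layer = as.integer(layer), replicate_group = as.character(replicate_group),
         is_blank = is_blank, batch = batch)
}

.add_blanks <- function(meta, n_blanks, batch = "B1") {
  if (n_blanks == 0) return(meta)
  dplyr::bind_rows(meta, .meta_row(
    paste0("blank_", seq_len(n_blanks)), site = NA, layer = NA,
    is_blank = TRUE, batch = batch
  ))
}

#' Replicate-acquisition design (reproducibility assessment)
#'
#' Emulates repeated independent acquisitions of one pooled extract: `n`
#' samples sharing one replicate group and identical true composition.
#'
#' @param n Number of acquisitions (default 10).
#' @param n_blanks Blank discs per batch (default 2).
#' @return A design list consumed by [sim_config()].
#' @export
design_replicates <- function(n = 10, n_blanks = 2) {
  meta <- .meta_row(sprintf("rep_%02d", seq_len(n)), subject_id = "pool",
                    replicate_group = "pool")
  list(type = "replicates", meta = .add_blanks(meta, n_blanks))
}

#' Sequential tape-stripping depth design
#'
#' Triplicates per layer for each subject; total lipid amount and the sebum
#' mix fraction decay exponentially with layer toward a plateau. The
#' configured fractional drop in total amount is reached (asymptotically) at
#' the subject's plateau layer.
#'
#' @param layers Layer indices sampled (default 1:10 then every second to 20).
#' @param subjects Tibble with `subject_id`, `sex`, `drop` (fractional total
#'   decline), `plateau_layer`.
#' @param n_replicates Adjacent-position replicates per layer (default 3).
#' @param n_blanks Blank discs (default 2).
#' @return A design list.
#' @export
design_depth <- function(layers = c(1:10, seq(12, 20, 2)),
                         subjects = tibble(
                           subject_id = c("F1", "M1"), sex = c("F", "M"),
                           drop = c(0.85, 0.87), plateau_layer = c(5L, 7L)
                         ),
                         n_replicates = 3, n_blanks = 2) {
  meta <- purrr::pmap_dfr(subjects, function(subject_id, sex, drop, plateau_layer) {
    g <- tidyr::expand_grid(layer = layers, rep = seq_len(n_replicates))
    .meta_row(sprintf("%s_L%02d_r%d", subject_id, g$layer, g$rep),
              subject_id = subject_id, sex = sex, age = 30,
              layer = g$layer,
              replicate_group = sprintf("%s_L%02d", subject_id, g$layer))
  })
  list(type = "depth", meta = .add_blanks(meta, n_blanks), subjects = subjects)
}

#' Body-site panel design (intra-individual variability)
#'
#' Triplicates at each of the 14 surveyed sites for each subject. Site
#' effects (total-amount multipliers and sebum mix) are fixed site
#' properties shared by subjects, with sebum-rich faces/neckline.
#'
#' @param subjects Tibble with `subject_id`, `sex`.
#' @param n_replicates Replicates per site (default 3).
#' @param n_blanks Blanks (default 2).
#' @return A design list.
#' @export
design_sites <- function(subjects = tibble(subject_id = c("M1", "F1"), sex = c("M", "F")),
                         n_replicates = 3, n_blanks = 2) {
  site_tbl <- tibble(
    site = .KNOWN_SITES,
    total_mult = c(12, 8, 4, 1, 1.5, 1, 0.15, 0.8, 4, 1, 0.3, 0.6, 0.5, 1),
    sebum_mix = c(0.85, 0.8, 0.65, 0.3, 0.35, 0.3, 0.1, 0.3, 0.65, 0.3,
                  0.15, 0.25, 0.25, 0.3)
  )
  meta <- purrr::pmap_dfr(subjects, function(subject_id, sex) {
    g <- tidyr::expand_grid(site = site_tbl$site, rep = seq_len(n_replicates))
    .meta_row(sprintf("%s_%s_r%d", subject_id, gsub("[^a-z]", "", g$site), g$rep),
              subject_id = subject_id, sex = sex, age = 30, site = g$site,
              replicate_group = sprintf("%s_%s", subject_id, gsub("[^a-z]", "", g$site)))
  })
  list(type = "sites", meta = .add_blanks(meta, n_blanks), site_tbl = site_tbl)
}

#' Age/sex cohort design (inter-individual variability)
#'
#' Volar-forearm samples from `n_female` + `n_male` subjects with ages drawn
#' uniformly over `age_range`. Sebum classes carry the sex effect and (in
#' females more than males) an age-related decline; ceramide composition is
#' age-invariant.
#'
#' @param n_female,n_male Cohort sizes (defaults 65 and 39).
#' @param age_range Years (default 20-89).
#' @param n_blanks Blanks (default 2).
#' @return A design list.
#' @export
design_cohort <- function(n_female = 65, n_male = 39, age_range = c(20, 89),
                          n_blanks = 2) {
  list(type = "cohort", n_female = n_female, n_male = n_male,
       age_range = age_range, n_blanks = n_blanks)
}

# ---- simulation config ------------------------------------------------------

#' Simulation configuration
#'
#' Defaults define the emulated study conditions: 500 counts/pmol response
#' with a 50-count noise floor (so the 2 pmol reporting limit sits at
#' S/N 20), 10% multiplicative log-normal intensity noise, 0.2 pmol blank
#' background on sebum-type lipids, per-class biological variability of
#' 0.25 (log-sd) and subject-level total-amount variability of 0.6 (log-sd),
#' a male sebum-class excess of exp(0.35) and a female age-related sebum and
#' total-amount decline.
#'
#' @param design A design list from one of the `design_*()` constructors.
#' @param seed Integer seed; identical seeds reproduce identical studies.
#' @param species_per_class Subspecies drawn per class (default 3).
#' @param total_pmol Baseline total lipid amount per sample (default 2000).
#' @param intensity_per_pmol Detector response, counts per pmol (default 500).
#' @param noise_sigma Log-sd of multiplicative intensity noise (default 0.1;
#'   0 renders noiseless spectra).
#' @param noise_floor Per-peak noise estimate, counts (default 50).
#' @param sigma_class Log-sd of per-sample class-abundance variation (0.25).
#' @param sigma_subject Log-sd of subject total-amount variation (0.6).
#' @param sebum_mix Baseline sebum mix fraction at the volar forearm (0.3).
#' @param sex_effect Log-scale male excess of sebum-class amounts (0.35,
#'   i.e. ~40% more TAG/DAG in males).
#' @param age_effect_female,age_effect_male Log-scale decline of sebum-class
#'   amounts over the full age range (1.0 and 0.35).
#' @param age_total_slope_female Log-scale total-amount decline over the full
#'   age range in females (1.0; males 0).
#' @param blank_pmol Blank background amount per sebum-type lipid (0.2).
#' @param fragment_yield Fraction of precursor response appearing in each
#'   diagnostic fragment (0.25).
#' @param decay_rate Exponential rate of the depth decay per layer (1.2).
#' @param constraints Candidate-space constraints ([sim_constraints()]).
#' @param k_max Isotope envelope truncation (3).
#' @param resolution A [resolution_model()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(design = design_replicates(), seed = 1,
                       species_per_class = 3, total_pmol = 2000,
                       intensity_per_pmol = 500, noise_sigma = 0.1,
                       noise_floor = 50, sigma_class = 0.25,
                       sigma_subject = 0.6, sebum_mix = 0.3,
                       sex_effect = 0.35, age_effect_female = 1.0,
                       age_effect_male = 0.35, age_total_slope_female = 1.0,
                       blank_pmol = 0.2, fragment_yield = 0.25,
                       decay_rate = 1.2, constraints = sim_constraints(),
                       k_max = 3, resolution = resolution_model()) {
  stopifnot(total_pmol > 0, intensity_per_pmol > 0, noise_floor > 0,
            noise_sigma >= 0, species_per_class >= 1)
  structure(as.list(environment()), class = "sim_config")
}

.mix_profile <- function(s) {
  pr <- class_profiles()
  stats::setNames(s * pr$sebum_rich + (1 - s) * pr$sc_proper, pr$class)
}

.SEBUM_CLASSES <- c("TAG", "DAG")

# pick the study's species panel from the candidate space (deterministic
# under the active RNG state); excludes internal-standard species and
# precursor-unresolvable collisions (isobaric cross-class pairs whose peaks
# the MS resolution would merge: those the engine reports but cannot
# apportion without MSMS-level splitting)
.pick_species <- function(cfg, standards) {
  db <- enumerate_species(cfg$constraints)
  db <- db[!db$subspecies %in% standards$subspecies, ]
  picked <- db |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(function(g, ...) {
      n <- min(cfg$species_per_class, nrow(g))
      g[sort(sample(nrow(g), n)), ]
    }) |>
    dplyr::ungroup()
  # one species per resolvable precursor position (incl. vs the standards)
  picked <- picked[order(picked$polarity, picked$mz), ]
  sep <- 1.5 * fwhm(cfg$resolution, picked$mz, "MS")
  keep <- rep(TRUE, nrow(picked))
  last_mz <- -Inf; last_pol <- ""
  for (i in seq_len(nrow(picked))) {
    if (picked$polarity[i] == last_pol && picked$mz[i] - last_mz < sep[i]) {
      keep[i] <- FALSE
    } else {
      last_mz <- picked$mz[i]; last_pol <- picked$polarity[i]
    }
  }
  for (i in seq_len(nrow(picked))) {
    if (any(standards$polarity == picked$polarity[i] &
              abs(standards$mz - picked$mz[i]) < sep[i])) keep[i] <- FALSE
  }
  picked <- picked[keep, ]
  picked$weight <- stats::rlnorm(nrow(picked), 0, 0.8)
  picked |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(weight = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup()
}

.depth_scale <- function(layer, drop, rate) {
  (1 - drop) + drop * exp(-rate * (layer - 1))
}

#' Expected fractional total-amount decline between two layers
#'
#' The generator's own analytic expectation for the depth design, used as
#' the oracle when checking recovered depth profiles.
#'
#' @param cfg A [sim_config()] with a depth design.
#' @param subject_id Subject in the design.
#' @param from,to Layer indices (defaults 1 and the subject's plateau layer).
#' @return Fractional decline in (0, 1).
#' @export
expected_depth_drop <- function(cfg, subject_id, from = 1, to = NULL) {
  sub <- cfg$design$subjects
  i <- match(subject_id, sub$subject_id)
  if (is.na(i)) abort(paste0("unknown subject '", subject_id, "'"))
  to <- to %||% sub$plateau_layer[i]
  s_from <- .depth_scale(from, sub$drop[i], cfg$decay_rate)
  s_to <- .depth_scale(to, sub$drop[i], cfg$decay_rate)
  1 - s_to / s_from
}

# per-sample (total pmol, sebum mix) pairs from the design
.sample_conditions <- function(cfg, meta) {
  des <- cfg$design
  n <- nrow(meta)
  total <- rep(cfg$total_pmol, n)
  mix <- rep(cfg$sebum_mix, n)
  if (des$type == "replicates") {
    # one pooled extract: identical truth across acquisitions
  } else if (des$type == "depth") {
    i <- match(meta$subject_id, des$subjects$subject_id)
    sc <- .depth_scale(meta$layer, des$subjects$drop[i], cfg$decay_rate)
    total <- cfg$total_pmol * 4 * sc
    mix <- 0.85 * exp(-cfg$decay_rate * (meta$layer - 1)) + 0.1
    # adjacent-position biological scatter
    total <- total * stats::rlnorm(n, 0, 0.08)
  } else if (des$type == "sites") {
    i <- match(meta$site, des$site_tbl$site)
    total <- cfg$total_pmol * des$site_tbl$total_mult[i]
    mix <- des$site_tbl$sebum_mix[i]
    subj_mult <- stats::setNames(
      stats::rlnorm(length(unique(meta$subject_id)), 0, 0.2),
      unique(meta$subject_id))
    total <- total * subj_mult[meta$subject_id] * stats::rlnorm(n, 0, 0.12)
  } else if (des$type == "cohort") {
    # sex and age act on the sebum classes only (amounts of ceramides,
    # cholesterol and CE are sex- and age-invariant by design); females
    # additionally lose total amount with age
    a <- (meta$age - cfg$design$age_range[1]) /
      diff(cfg$design$age_range)
    male <- meta$sex == "M"
    sebum_mult <- exp(cfg$sex_effect * male) *
      exp(-ifelse(male, cfg$age_effect_male, cfg$age_effect_female) * a)
    total <- cfg$total_pmol *
      exp(-cfg$age_total_slope_female * a * (!male)) *
      stats::rlnorm(n, 0, cfg$sigma_subject)
  }
  mix <- pmin(pmax(mix, 0.02), 0.95)
  sebum_mult <- if (exists("sebum_mult", inherits = FALSE)) sebum_mult else rep(1, n)
  list(total = total, mix = mix, sebum_mult = sebum_mult)
}

#' Simulate a ground-truth lipidome study
#'
#' Draws the study's species panel, then per-sample true amounts: the class
#' profile is a sebum/stratum-corneum endmember mix determined by the design
#' (layer, site or subject), perturbed by per-class biological variation and
#' split over species by fixed within-class weights. Blank discs carry only
#' the configured background on sebum-type lipids. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param standards [internal_standards()] manifest (excluded from the panel).
#' @return A list of class `sim_truth`: `truth` (tibble `sample_id`, `class`,
#'   `species`, `subspecies`, `pmol`), `meta`, `panel` (species table with
#'   m/z), `conditions` (per-sample total/mix).
#' @export
simulate_lipidome <- function(cfg, standards = internal_standards()) {
  set.seed(cfg$seed)
  des <- cfg$design
  if (des$type == "cohort") {
    n <- des$n_female + des$n_male
    if (n < 1) abort("cohort design needs at least one subject")
    meta <- .meta_row(sprintf("subj_%03d", seq_len(n)),
                      subject_id = sprintf("S%03d", seq_len(n)),
                      sex = c(rep("F", des$n_female), rep("M", des$n_male)),
                      age = stats::runif(n, des$age_range[1], des$age_range[2]))
    meta <- .add_blanks(meta, des$n_blanks)
  } else {
    meta <- des$meta
  }
  panel <- .pick_species(cfg, standards)
  real <- meta[!meta$is_blank, ]
  cond <- .sample_conditions(cfg, real)

  profiles <- vapply(cond$mix, .mix_profile, numeric(16))
  # per-sample per-class biological variation, renormalized to 100 mol%
  noise <- matrix(stats::rlnorm(length(profiles), 0, cfg$sigma_class),
                  nrow = nrow(profiles))
  if (des$type == "replicates") noise[] <- 1 # one shared pooled extract
  profiles <- profiles * noise
  profiles <- sweep(profiles, 2, colSums(profiles), "/") * 100

  truth <- purrr::map_dfr(seq_len(nrow(real)), function(i) {
    cls_pmol <- cond$total[i] * profiles[, i] / 100
    cls_pmol[.SEBUM_CLASSES] <- cls_pmol[.SEBUM_CLASSES] * cond$sebum_mult[i]
    tibble(
      sample_id = real$sample_id[i],
      class = panel$class, species = panel$species, subspecies = panel$subspecies,
      pmol = cls_pmol[panel$class] * panel$weight
    )
  })

  blanks <- meta[meta$is_blank, ]
  if (nrow(blanks) > 0 && cfg$blank_pmol > 0) {
    bg <- panel[panel$class %in% c(.SEBUM_CLASSES, "CE"), ]
    truth <- dplyr::bind_rows(truth, purrr::map_dfr(blanks$sample_id, function(sid) {
      tibble(sample_id = sid, class = bg$class, species = bg$species,
             subspecies = bg$subspecies,
             pmol = cfg$blank_pmol * stats::rlnorm(nrow(bg), 0, 0.3))
    }))
  }
  structure(list(truth = truth, meta = meta, panel = panel,
                 conditions = cond, cfg = cfg),
            class = "sim_truth")
}

# merge peaks closer than the instrument FWHM into one centroid
.merge_peaks <- function(pk, model, level) {
  if (nrow(pk) < 2) return(pk)
  pk <- pk[order(pk$mz), ]
  w <- fwhm(model, pk$mz, level)
  grp <- cumsum(c(1, as.integer(diff(pk$mz) >= model$overlap_multiplier * w[-1])))
  pk |>
    dplyr::mutate(grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      mz = sum(.data$mz * .data$intensity) / sum(.data$intensity),
      intensity = sum(.data$intensity),
      noise = max(.data$noise), .groups = "drop"
    ) |>
    dplyr::select("mz", "intensity", "noise") |>
    dplyr::arrange(.data$mz)
}

#' Render in-silico acquisition runs for one sample
#'
#' MS peaks appear at the adduct m/z of each species with monoisotopic
#' intensity pmol x response x monoisotopic fraction (x log-normal noise),
#' followed by its isotope envelope up to `k_max`; peaks the configured
#' resolution cannot separate are merged into one centroid. MSMS spectra per
#' precursor group contain the diagnostic fragments at intensities
#' proportional to subspecies amounts. Internal standards are rendered at
#' their label-shifted m/z; cholesterol (and its D6 standard) goes into a
#' separate derivatized acquisition. Blanks render their background only.
#'
#' @param truth A `sim_truth` from [simulate_lipidome()].
#' @param sample_id Sample to render.
#' @param standards [internal_standards()] manifest.
#' @param rules Fragment-rule table.
#' @param lockmass Lock-mass availability flag written to every spectrum.
#' @return A list of `acquisition_run`s: `main` and (when cholesterol is
#'   present) `chol`.
#' @export
render_run <- function(truth, sample_id, standards = internal_standards(),
                       rules = fragment_rules(), lockmass = TRUE) {
  cfg <- truth$cfg
  rows <- truth$truth[truth$truth$sample_id == sample_id, ]
  panel <- truth$panel
  i <- match(rows$subspecies, panel$subspecies)
  rows$formula <- panel$formula[i]
  rows$mz <- panel$mz[i]
  rows$polarity <- panel$polarity[i]

  std <- standards
  std$pmol <- std$spike_pmol
  make_runs <- function(rows, std, kind) {
    # one log-normal intensity factor per subspecies; fragments share it so
    # MSMS ratios stay commensurate with amounts
    fac <- if (cfg$noise_sigma > 0) stats::rlnorm(nrow(rows), 0, cfg$noise_sigma) else rep(1, nrow(rows))
    rows$resp <- rows$pmol * cfg$intensity_per_pmol * fac
    std_fac <- if (cfg$noise_sigma > 0) stats::rlnorm(nrow(std), 0, cfg$noise_sigma) else rep(1, nrow(std))
    std$resp <- std$spike_pmol * cfg$intensity_per_pmol * std_fac

    specs <- list()
    for (pol in c("+", "-")) {
      r <- rows[rows$polarity == pol, ]
      s <- std[std$polarity == pol, ]
      if (nrow(r) + nrow(s) == 0) next
      # species-level precursor response
      sp <- dplyr::bind_rows(
        r |> dplyr::group_by(.data$species, .data$formula, .data$mz) |>
          dplyr::summarise(resp = sum(.data$resp), .groups = "drop"),
        tibble(species = s$subspecies, formula = s$formula, mz = s$mz, resp = s$resp)
      )
      pk <- purrr::map_dfr(seq_len(nrow(sp)), function(k) {
        env <- isotope_envelope(sp$formula[k], cfg$k_max)
        # whole-cluster response distributed over the truncated envelope
        mono <- sp$resp[k] / sum(env$abundance)
        tibble(mz = sp$mz[k] + env$mass_offset,
               intensity = mono * env$abundance,
               noise = cfg$noise_floor)
      })
      pk <- .merge_peaks(pk, cfg$resolution, "MS")
      specs[[length(specs) + 1]] <- tibble(
        level = "MS", polarity = pol, precursor_low = NA_real_,
        precursor_high = NA_real_, lockmass = lockmass, peaks = list(pk)
      )
      # MSMS per precursor group (isobaric species share one window)
      prec <- dplyr::bind_rows(
        tibble(name = r$subspecies, cls_is_std = FALSE, mz = r$mz,
               resp = r$resp, polarity = pol),
        tibble(name = s$subspecies, cls_is_std = TRUE, mz = s$mz,
               resp = s$resp, polarity = pol)
      )
      prec$grp <- round(prec$mz, 3)
      for (g in unique(prec$grp)) {
        sub <- prec[prec$grp == g, ]
        fr <- purrr::map_dfr(seq_len(nrow(sub)), function(k) {
          f <- tryCatch(expected_fragments(sub$name[k], rules, precursor_mz = sub$mz[k]),
                        error = function(e) NULL)
          if (is.null(f)) return(tibble())
          tibble(mz = f$mz, intensity = sub$resp[k] * cfg$fragment_yield,
                 noise = cfg$noise_floor)
        })
        if (nrow(fr) == 0) next
        fr <- fr |>
          dplyr::group_by(.data$mz) |>
          dplyr::summarise(intensity = sum(.data$intensity),
                           noise = max(.data$noise), .groups = "drop")
        fr <- .merge_peaks(fr, cfg$resolution, "MSMS")
        specs[[length(specs) + 1]] <- tibble(
          level = "MSMS", polarity = pol,
          precursor_low = g - 0.5, precursor_high = g + 0.5,
          lockmass = lockmass, peaks = list(fr)
        )
      }
    }
    acquisition_run(sample_id, dplyr::bind_rows(specs), kind = kind)
  }

  is_chol <- rows$class == "Chol"
  std_chol <- std[std$acquisition == "cholesterol-derivatized", ]
  std_main <- std[std$acquisition == "main", ]
  out <- list(main = make_runs(rows[!is_chol, ], std_main, "main"))
  out$chol <- make_runs(rows[is_chol, ], std_chol, "cholesterol-derivatized")
  out
}

#' Simulate and render a whole study
#'
#' @param cfg A [sim_config()].
#' @param standards,rules As in [render_run()].
#' @param lockmass Lock-mass flag for all rendered spectra.
#' @return A list of class `sim_study`: the `sim_truth` fields plus `runs`
#'   (named list sample_id -> list(main, chol)).
#' @export
simulate_study <- function(cfg, standards = internal_standards(),
                           rules = fragment_rules(), lockmass = TRUE) {
  truth <- simulate_lipidome(cfg, standards)
  runs <- lapply(truth$meta$sample_id, function(sid) {
    render_run(truth, sid, standards, rules, lockmass)
  })
  names(runs) <- truth$meta$sample_id
  truth$runs <- runs
  class(truth) <- c("sim_study", class(truth))
  truth
}

#' Run the identification/quantification engine over a rendered study
#'
#' For each sample: precursor matching (main and derivatized acquisitions),
#' MSMS confirmation, and internal-standard quantification; the cholesterol
#' amount from the derivatized acquisition is merged in by sample id.
#'
#' @param study A `sim_study` (or any list with `meta` and `runs` shaped the
#'   same way).
#' @param db Candidate database (defaults to the study's constraints, with
#'   standard species removed).
#' @param cfg_id An [id_config()].
#' @param standards,rules As elsewhere.
#' @return A QuantTable tibble over all samples.
#' @export
process_study <- function(study, db = NULL, cfg_id = id_config(),
                          standards = internal_standards(), rules = fragment_rules()) {
  if (is.null(db)) {
    db <- enumerate_species(study$cfg$constraints)
    db <- db[!db$subspecies %in% standards$subspecies, ]
  }
  out <- purrr::map_dfr(names(study$runs), function(sid) {
    runs <- study$runs[[sid]]
    qt <- list()
    for (run in runs) {
      if (is.null(run) || nrow(run$spectra) == 0) next
      ids <- match_precursors(run, db, cfg_id, standards)
      if (nrow(ids[is.na(ids$standard_id), ]) == 0) next
      conf <- confirm_subspecies(ids, run, db, cfg_id, rules)
      if (nrow(conf) == 0) next
      qt[[length(qt) + 1]] <- quantify(conf, match_ids = ids,
                                       standards = standards, cfg = cfg_id)
    }
    dplyr::bind_rows(qt)
  })
  out
}

#' Simulate a spike dilution series and measure S/N
#'
#' Renders one acquisition per spike level containing the internal standards
#' plus the reference species at the given amount, runs precursor matching,
#' and reports the recovered S/N -- the input for [dynamic_range_fit()].
#'
#' @param species A subspecies name present in the candidate space (default
#'   `"NS 18:1;2–24:0;0"`).
#' @param pmols Spike amounts (default 1, 3, 10, 30, 100, 300).
#' @param cfg A [sim_config()] (its noise and response settings are used).
#' @param cfg_id An [id_config()].
#' @return A tibble `pmol`, `sn`.
#' @export
simulate_spike_series <- function(species = "NS 18:1;2–24:0;0",
                                  pmols = c(1, 3, 10, 30, 100, 300),
                                  cfg = sim_config(noise_sigma = 0),
                                  cfg_id = id_config()) {
  set.seed(cfg$seed)
  sub <- parse_subspecies_name(species)
  f <- species_formula(sub$cls, sub$chains)
  row <- .class_row(sub$cls)
  mz <- adduct_mz(monoisotopic_mass(f), row$adduct)
  standards <- internal_standards()
  purrr::map_dfr(pmols, function(pm) {
    truth <- structure(list(
      truth = tibble(sample_id = "spike", class = sub$cls, species = sub$species,
                     subspecies = sub$subspecies, pmol = pm),
      panel = tibble(class = sub$cls, species = sub$species,
                     subspecies = sub$subspecies, formula = format(f),
                     mz = mz, polarity = row$ion_mode),
      cfg = cfg
    ), class = "sim_truth")
    runs <- render_run(truth, "spike", standards)
    db <- tibble(class = sub$cls, species = sub$species, subspecies = sub$subspecies,
                 formula = format(f), neutral_mass = monoisotopic_mass(f),
                 adduct = row$adduct, polarity = row$ion_mode, mz = mz)
    ids <- match_precursors(runs$main, db, cfg_id, standards)
    hit <- ids[is.na(ids$standard_id), ]
    tibble(pmol = pm, sn = if (nrow(hit) > 0) max(hit$sn) else NA_real_)
  })
}
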