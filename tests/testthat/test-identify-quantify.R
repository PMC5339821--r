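# Precursor matching gates, MSMS confirmation, standards quantification,
# subspecies ratios and the filter cascade.

# intensity that type-II-corrects to `level` for a given formula
raw_for <- function(formula, level, k_max = 3) {
  level / sum(isotope_envelope(formula, k_max)$abundance)
}

test_that("ppm gates are strict and lock-mass dependent", {
  db <- db_rows("NS 18:1;2-16:0;0")
  cfg <- id_config()
  at_ppm <- function(ppm, pad = 0) db$mz * (1 + ppm * 1e-6) + pad
  # exact match: 0 ppm
  id0 <- match_precursors(make_run(db$mz, 1000, noise = 10), db, cfg)
  expect_equal(id0$ppm_error, 0)
  # 2.9 ppm deviation passes the 3 ppm lock-mass MS gate
  id1 <- match_precursors(make_run(at_ppm(2.9), 1000, noise = 10), db, cfg)
  expect_equal(nrow(id1), 1)
  expect_equal(id1$ppm_error, 2.9, tolerance = 1e-6)
  # 3.0 ppm (padded above the boundary) is rejected: "below 3 ppm" is strict
  id2 <- match_precursors(make_run(at_ppm(3.0, pad = 1e-9), 1000, noise = 10), db, cfg)
  expect_equal(nrow(id2), 0)
  # without lock mass the gate widens to 5 ppm
  id3 <- match_precursors(make_run(at_ppm(4.5), 1000, noise = 10, lockmass = FALSE),
                          db, cfg)
  expect_equal(nrow(id3), 1)
  id4 <- match_precursors(make_run(at_ppm(5.0, pad = 1e-9), 1000, noise = 10,
                                   lockmass = FALSE), db, cfg)
  expect_equal(nrow(id4), 0)
})

test_that("the signal-to-noise gate is strictly greater than 5", {
  db <- db_rows("NS 18:1;2-16:0;0")
  cfg <- id_config()
  # S/N exactly 5.0 fails
  id <- match_precursors(make_run(db$mz, 500, noise = 100), db, cfg)
  expect_equal(nrow(id), 0)
  id2 <- match_precursors(make_run(db$mz, 501, noise = 100), db, cfg)
  expect_equal(nrow(id2), 1)
})

test_that("MSMS confirmation resolves chains and arbitrates isobaric classes", {
  cfg <- id_config()
  db <- db_rows("NS 18:1;2-16:0;0", "NP 18:0;3-18:0;0", "AdS 18:0;2-18:0;1")

  # chain-resolved NS call when both diagnostic fragments are present
  ns <- db[db$class == "NS", ]
  fr_ns <- expected_fragments(ns$subspecies, precursor_mz = ns$mz)
  run_ns <- acquisition_run("s1", dplyr::bind_rows(
    tibble::tibble(level = "MS", polarity = "-", precursor_low = NA_real_,
                   precursor_high = NA_real_, lockmass = TRUE,
                   peaks = list(tibble::tibble(mz = ns$mz, intensity = 1000, noise = 10))),
    tibble::tibble(level = "MSMS", polarity = "-", precursor_low = ns$mz - 0.5,
                   precursor_high = ns$mz + 0.5, lockmass = TRUE,
                   peaks = list(tibble::tibble(mz = sort(fr_ns$mz),
                                               intensity = 200, noise = 10)))
  ))
  ids <- match_precursors(run_ns, db, cfg)
  conf <- confirm_subspecies(ids, run_ns, db, cfg)
  expect_equal(conf$subspecies, ns$subspecies)
  expect_false(conf$species_level_only)

  # an AdS spectrum under the shared NP/AdS precursor is called AdS only
  ads <- db[db$class == "AdS", ]
  np <- db[db$class == "NP", ]
  expect_equal(ads$mz, np$mz, tolerance = 1e-9) # isobaric pair
  fr_ads <- expected_fragments(ads$subspecies, precursor_mz = ads$mz)
  run_ads <- acquisition_run("s1", dplyr::bind_rows(
    tibble::tibble(level = "MS", polarity = "-", precursor_low = NA_real_,
                   precursor_high = NA_real_, lockmass = TRUE,
                   peaks = list(tibble::tibble(mz = ads$mz, intensity = 800, noise = 10))),
    tibble::tibble(level = "MSMS", polarity = "-", precursor_low = ads$mz - 0.5,
                   precursor_high = ads$mz + 0.5, lockmass = TRUE,
                   peaks = list(tibble::tibble(mz = sort(fr_ads$mz),
                                               intensity = 150, noise = 10)))
  ))
  ids2 <- match_precursors(run_ads, db, cfg)
  expect_true(any(ids2$ambiguous))
  conf2 <- confirm_subspecies(ids2, run_ads, db, cfg)
  expect_equal(conf2$class, "AdS")
  expect_equal(conf2$subspecies, ads$subspecies)

  # fragments below the S/N gate: identification stays species-level
  run_low <- acquisition_run("s1", dplyr::bind_rows(
    run_ns$spectra[1, ],
    tibble::tibble(level = "MSMS", polarity = "-", precursor_low = ns$mz - 0.5,
                   precursor_high = ns$mz + 0.5, lockmass = TRUE,
                   peaks = list(tibble::tibble(mz = sort(fr_ns$mz),
                                               intensity = 40, noise = 10)))
  ))
  conf3 <- confirm_subspecies(match_precursors(run_low, db, cfg), run_low, db, cfg)
  expect_true(conf3$species_level_only[conf3$class == "NS"])
  expect_true(is.na(conf3$subspecies[conf3$class == "NS"]))
})

test_that("amounts are intensity ratios to the class internal standard", {
  cfg <- id_config()
  std <- internal_standards()
  ns <- db_row("NS 18:1;2-16:0;0")
  eoh <- db_row("EOH 18:1;3-30:0;0-18:2;0")
  db <- dplyr::bind_rows(ns, eoh)
  ns_d3 <- std[std$standard_id == "NS_D3", ]
  eos_d9 <- std[std$standard_id == "EOS_D9", ]
  # corrected intensities: native NS == NS-D3; EOH at 0.25 x EOS-D9
  pk <- tibble::tibble(
    mz = c(ns$mz, eoh$mz, ns_d3$mz, eos_d9$mz),
    intensity = c(raw_for(ns$formula, 1000), raw_for(eoh$formula, 250),
                  raw_for(ns_d3$formula, 1000), raw_for(eos_d9$formula, 1000))
  )
  pk <- pk[order(pk$mz), ]
  run <- make_run(pk$mz, pk$intensity, noise = 1, polarity = "-")
  ids <- match_precursors(run, db, cfg, standards = std)
  qt <- quantify(ids, match_ids = ids, standards = std, cfg = cfg)
  # equal corrected intensity -> the spiked 14 pmol of NS-D3
  expect_equal(qt$pmol[qt$class == "NS"], 14, tolerance = 1e-9)
  # omega-hydroxy ceramides normalize to deuterated EOS (42 pmol), not NS
  expect_equal(qt$pmol[qt$class == "EOH"], 0.25 * 42, tolerance = 1e-9)

  # a missing class standard leaves its species flagged unquantifiable
  tag <- db_row("TAG 16:0;0-16:0;0-18:1;0")
  run2 <- make_run(sort(c(tag$mz, std$mz[std$standard_id == "NS_D3"])),
                   c(1000, 1000), noise = 1, polarity = "+")
  # only the positive-polarity spectrum: TAG matched, TAG-D5 absent
  ids2 <- match_precursors(run2, tag, cfg, standards = std)
  qt2 <- quantify(ids2, match_ids = ids2, standards = std, cfg = cfg)
  expect_true(qt2$unquantifiable[qt2$class == "TAG"])
  expect_true(is.na(qt2$pmol[qt2$class == "TAG"]))
})

test_that("TAG at half its standard's corrected intensity gives 50 pmol", {
  cfg <- id_config()
  std <- internal_standards()
  tag <- db_row("TAG 16:0;0-16:0;0-18:1;0")
  tag_d5 <- std[std$standard_id == "TAG_D5", ]
  run <- make_run(
    mz = c(tag$mz, tag_d5$mz),
    intensity = c(raw_for(tag$formula, 500), raw_for(tag_d5$formula, 1000)),
    noise = 1, polarity = "+"
  )
  ids <- match_precursors(run, tag, cfg, standards = std)
  qt <- quantify(ids, match_ids = ids, standards = std, cfg = cfg)
  expect_equal(qt$pmol, 50, tolerance = 1e-9)
})

test_that("subspecies amounts split by fragment ratio and conserve the total", {
  expect_equal(unname(resolve_subspecies_amounts(10, c(a = 3, b = 1))), c(7.5, 2.5))
  expect_equal(unname(resolve_subspecies_amounts(8, c(a = 1, b = 1, c = 2))), c(2, 2, 4))
  expect_equal(resolve_subspecies_amounts(5, c(only = 123)), c(only = 5))
  expect_equal(resolve_subspecies_amounts(7, c(a = 0, b = 0)), c(unresolved = 7))
  set.seed(9)
  for (i in 1:20) {
    w <- stats::runif(sample(2:6, 1))
    tot <- stats::runif(1, 1, 100)
    out <- resolve_subspecies_amounts(tot, stats::setNames(w, seq_along(w)))
    expect_equal(sum(out), tot, tolerance = 1e-12)
  }
})

test_that("the filter cascade applies strict thresholds with recorded reasons", {
  cfg <- id_config()
  meta <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "bl"), subject_id = c("a", "a", "a", NA),
    sex = "F", age = 30, site = "volar forearm", layer = 2L,
    replicate_group = c("g", "g", "g", NA),
    is_blank = c(FALSE, FALSE, FALSE, TRUE), batch = "B1"
  )
  qt <- tibble::tibble(
    sample_id = c("s1", "s2", "s3",   # lipid A: fine everywhere
                  "s1",               # lipid B: 9 pmol vs blank 2 -> 4.5x < 5x
                  "s1", "s2",         # lipid C: exactly 2.0 pmol ("above 2" strict)
                  "s1",               # lipid D: 1 of 3 replicates only
                  "bl", "bl"),
    class = c("NS", "NS", "NS", "TAG", "CE", "CE", "DAG", "TAG", "DAG"),
    species = c("NS 34:1;2", "NS 34:1;2", "NS 34:1;2", "TAG 50:1;0",
                "CE 16:0;0", "CE 16:0;0", "DAG 34:1;0", "TAG 50:1;0", "DAG 34:1;0"),
    subspecies = NA_character_,
    pmol = c(20, 22, 21, 9, 2.0, 2.0, 30, 2, 0.5)
  )
  res <- apply_filters(qt, meta, cfg)
  keep_a <- res$kept[res$class == "NS"]
  expect_true(all(keep_a))
  expect_equal(res$drop_reason[res$class == "TAG"], "blank_fold")
  expect_equal(unique(res$drop_reason[res$class == "CE"]), "below_min_pmol")
  # lipid D passes amount and blank... wait it is vs blank DAG 0.5: 30 >= 2.5
  expect_equal(res$drop_reason[res$class == "DAG"], "replicate_occurrence")
  expect_false(any(res$sample_id == "bl")) # blanks removed from output
})

test_that("a lipid just above all gates survives; 4.9x blank does not", {
  cfg <- id_config()
  meta <- tibble::tibble(
    sample_id = c("s1", "s2", "bl"), subject_id = "a", sex = "F", age = 1,
    site = "volar forearm", layer = 1L, replicate_group = c("g", "g", NA),
    is_blank = c(FALSE, FALSE, TRUE), batch = "B1"
  )
  mk <- function(p1, p2, bl) tibble::tibble(
    sample_id = c("s1", "s2", "bl"), class = "NS", species = "NS 34:1;2",
    subspecies = NA_character_, pmol = c(p1, p2, bl)
  )
  # exactly 5x the blank passes ("at least 5-fold")
  r1 <- apply_filters(mk(10, 10, 2), meta, cfg)
  expect_true(all(r1$kept))
  r2 <- apply_filters(mk(9.8, 9.8, 2), meta, cfg)
  expect_true(all(!r2$kept))
  # 2.05 pmol is "above 2 pmol"
  r3 <- apply_filters(mk(2.05, 2.05, 0), meta, cfg)
  expect_true(all(r3$kept))
})

test_that("tightening any filter threshold never increases survivors", {
  set.seed(21)
  meta <- tibble::tibble(
    sample_id = c(sprintf("s%d", 1:6), "bl1"),
    subject_id = "a", sex = "F", age = 30, site = "volar forearm", layer = 1L,
    replicate_group = c(rep("g1", 3), rep("g2", 3), NA),
    is_blank = c(rep(FALSE, 6), TRUE), batch = "B1"
  )
  qt <- tidyr::expand_grid(sample_id = meta$sample_id,
                           species = sprintf("NS %d:1;2", seq(30, 58, 2)))
  qt$class <- "NS"
  qt$subspecies <- NA_character_
  qt$pmol <- stats::rlnorm(nrow(qt), log(5), 1.2)
  qt$pmol[qt$sample_id == "bl1"] <- stats::rlnorm(15, log(1), 0.5)
  base <- sum(apply_filters(qt, meta, id_config())$kept)
  for (cfg2 in list(id_config(min_pmol = 4), id_config(blank_fold = 8),
                    id_config(min_replicates = 3), id_config(sn_min = 10))) {
    expect_lte(sum(apply_filters(qt, meta, cfg2)$kept), base)
  }
})
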