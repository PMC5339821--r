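# Combinatorial enumeration, inclusion lists and fragment rules.

test_that("single-chain-choice ceramide enumeration yields exactly the 12 subclasses", {
  cons <- default_constraints(lcb_c = 18, fa_c = 24, fa_db = 0,
                              ester_c = 18, ester_db = 2)
  cer <- lipid_classes()$code[lipid_classes()$category == "ceramide"]
  e <- enumerate_species(cons, classes = cer)
  expect_equal(nrow(e), 12)
  expect_setequal(e$class, cer)
})

test_that("enumeration counts match the brute-force Cartesian product", {
  # non-EO ceramide: |LCB C| x |FA C x FA DB| (after chain-validity filter)
  brute_non_eo <- function(lcb_c, fa_c, fa_db, lcb_db) {
    g <- expand.grid(l = lcb_c, c = fa_c, d = fa_db)
    sum(g$d <= floor((g$c - 1) / 2) & lcb_db <= floor((g$l - 1) / 2))
  }
  set.seed(11)
  for (i in 1:10) {
    lcb_c <- sort(sample(seq(14, 24, 2), sample(2:4, 1)))
    fa_c <- sort(sample(seq(14, 30, 2), sample(2:6, 1)))
    fa_db <- 0:sample(0:3, 1)
    cons <- default_constraints(lcb_c = lcb_c, fa_c = fa_c, fa_db = fa_db)
    e <- enumerate_species(cons, classes = "NS")
    expect_equal(nrow(e), brute_non_eo(lcb_c, fa_c, fa_db, lcb_db = 1))
    # EO adds the ester-FA dimension
    est_c <- sort(sample(seq(14, 22, 2), 2))
    est_db <- 0:1
    cons2 <- default_constraints(lcb_c = lcb_c, fa_c = fa_c, fa_db = fa_db,
                                 ester_c = est_c, ester_db = est_db)
    e2 <- enumerate_species(cons2, classes = "EOS")
    expect_equal(nrow(e2),
                 brute_non_eo(lcb_c, fa_c, fa_db, 1) * length(est_c) * length(est_db))
  }
  # worked micro-example
  e3 <- enumerate_species(default_constraints(lcb_c = 18, fa_c = c(16, 24), fa_db = 0),
                          classes = "NS")
  expect_equal(nrow(e3), 2)
  # empty FA range is an empty result, not an error
  e4 <- enumerate_species(default_constraints(fa_c = integer(0)), classes = "NS")
  expect_equal(nrow(e4), 0)
})

test_that("glyceride enumeration equals unordered FA multisets after total filters", {
  fa_c <- c(16, 18); fa_db <- 0:1
  e <- enumerate_species(default_constraints(
    dag_fa_c = fa_c, dag_fa_db = fa_db, dag_total_c = c(0, 100)
  ), classes = "DAG")
  # 4 distinct FAs -> 4 + choose(4,2) = 10 unordered pairs
  expect_equal(nrow(e), 10)
  ce <- enumerate_species(default_constraints(ce_fa_c = c(14, 16), ce_fa_db = 0),
                          classes = "CE")
  expect_equal(nrow(ce), 2)
})

test_that("target lists cover every precursor and merge overlapping windows", {
  db <- db_rows("NS 18:1;2-24:0;0", "NS 18:1;2-26:0;0")
  tl1 <- build_target_list(db, window_halfwidth = 0.5)
  expect_equal(nrow(tl1), 2) # 28 Da apart: no merge
  # two species 0.5 Da apart with halfwidth 0.5 merge into one window
  fake <- db
  fake$mz <- c(700, 700.5)
  tl2 <- build_target_list(fake, window_halfwidth = 0.5)
  expect_equal(nrow(tl2), 1)
  expect_equal(tl2$n_species, 2L)
  # coverage: every species m/z inside at least one of its polarity's windows
  big <- enumerate_species(default_constraints(lcb_c = 18, fa_c = 24, fa_db = 0,
                                               ester_c = 18, ester_db = 2))
  tl3 <- build_target_list(big, window_halfwidth = 0.5)
  covered <- vapply(seq_len(nrow(big)), function(i) {
    any(tl3$polarity == big$polarity[i] &
          tl3$mz_low <= big$mz[i] & big$mz[i] <= tl3$mz_high)
  }, logical(1))
  expect_true(all(covered))
  expect_error(build_target_list(db, window_halfwidth = 0), "positive")
})

test_that("fragment rules give LCB/FA diagnostics and separate the isobaric class pairs", {
  fr <- expected_fragments("NS 18:1;2-16:0;0")
  expect_true(all(c("lcb", "fa") %in% fr$kind))
  expect_true(all(fr$polarity == "-"))

  # NP 36:0;3 and AdS 36:0;3 share an elemental formula (same precursor) but
  # their LCB-diagnostic fragments differ
  np <- parse_subspecies_name("NP 18:0;3-18:0;0")
  ads <- parse_subspecies_name("AdS 18:0;2-18:0;1")
  expect_equal(format(species_formula("NP", np$chains)),
               format(species_formula("AdS", ads$chains)))
  fr_np <- expected_fragments("NP 18:0;3-18:0;0")
  fr_ads <- expected_fragments("AdS 18:0;2-18:0;1")
  expect_false(setequal(round(fr_np$mz, 4), round(fr_ads$mz, 4)))
  expect_false(isTRUE(all.equal(fr_np$mz[fr_np$kind == "lcb"],
                                fr_ads$mz[fr_ads$kind == "lcb"])))
  # same for NH vs AS
  fr_nh <- expected_fragments("NH 18:1;3-18:1;0")
  fr_as <- expected_fragments("AS 18:1;2-18:1;1")
  expect_false(setequal(round(fr_nh$mz, 4), round(fr_as$mz, 4)))

  # a rule table without the class is an error
  expect_error(expected_fragments("NS 18:1;2-16:0;0",
                                  rules = fragment_rules()[0, ]),
               "no fragment rules")
})

test_that("neutral-loss fragments sit below the ammonium precursor by FA + NH3", {
  sub <- parse_subspecies_name("DAG 16:0;0-18:1;0")
  prec <- adduct_mz(monoisotopic_mass(species_formula("DAG", sub$chains)), "ammonium")
  fr <- expected_fragments("DAG 16:0;0-18:1;0")
  loss_16 <- prec - fr$mz[fr$chain == "16:0;0"]
  expect_equal(loss_16, monoisotopic_mass("C16H32O2") + monoisotopic_mass("NH3"),
               tolerance = 1e-4)
})

test_that("ambiguity audit separates co-falling candidates via fragments", {
  db <- db_rows("NP 18:0;3-18:0;0", "AdS 18:0;2-18:0;1",
                "NS 18:1;2-24:0;0", "NS 18:1;2-26:0;0")
  log <- audit_ambiguity(db, ppm = 3)
  expect_equal(nrow(log), 0) # the NP/AdS pair is separable by its LCB fragment
  # an identical species listed twice is genuinely inseparable
  dup <- dplyr::bind_rows(db_row("NS 18:1;2-24:0;0"), db_row("NS 18:1;2-24:0;0"))
  log2 <- audit_ambiguity(dup, ppm = 3)
  expect_equal(nrow(log2), 1)
})
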