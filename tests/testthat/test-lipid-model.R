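# Lipid name grammar, chain chemistry, masses and adducts.

test_that("species names parse, round-trip and reject malformed input", {
  k <- parse_species_name("EOS 70:3;2")
  expect_equal(unname(unlist(k)), c("EOS", "70", "3", "2"))
  expect_equal(format_species_name(k$cls, k$C, k$DB, k$OH), "EOS 70:3;2")

  k2 <- parse_species_name("NS 36:1;2")
  expect_equal(k2$C, 36L)
  expect_equal(k2$DB, 1L)
  expect_equal(k2$OH, 2L)

  expect_error(parse_species_name("XYZ 10:0;0"), "unknown lipid class")
  expect_error(parse_species_name("NS 36:1"), "missing the ';<OH>'")
  expect_error(parse_species_name("NS 36.1;2"), "malformed")
  # OH structurally fixed for neutral classes: ";0" optional
  expect_equal(parse_species_name("CE 20:0")$OH, 0L)
  expect_equal(parse_species_name("Chol")$cls, "Chol")

  # fuzzed round-trip over grammar-valid names
  set.seed(42)
  codes <- lipid_classes()$code[lipid_classes()$n_chains > 0]
  for (i in 1:50) {
    nm <- format_species_name(sample(codes, 1), sample(20:80, 1),
                              sample(0:6, 1), sample(0:4, 1))
    expect_equal(with(parse_species_name(nm),
                      format_species_name(cls, C, DB, OH)), nm)
  }
})

test_that("subspecies names parse chains LCB-first and sum to the parent", {
  # bare chain list with explicit class (en-dash as printed)
  s <- parse_subspecies_name("18:1;0–24:2;0", cls = "DAG")
  expect_equal(s$chains$C, c(18L, 24L))
  expect_equal(s$chains$DB, c(1L, 2L))

  # ASCII hyphen accepted; canonical output uses the en-dash
  s2 <- parse_subspecies_name("NS 18:1;2-18:0;0")
  expect_equal(s2$chains$role, c("LCB", "FA"))
  expect_equal(s2$chains$C[1], 18L)
  expect_equal(s2$species, "NS 36:1;2")
  expect_equal(s2$subspecies, "NS 18:1;2–18:0;0")

  # the deuterated-EOS chain pattern: ester-FA third, omega-OH not counted
  s3 <- parse_subspecies_name("EOS 18:1;2-32:0;0-18:2;0")
  expect_equal(s3$chains$role, c("LCB", "FA", "esterFA"))
  expect_equal(s3$species, "EOS 68:3;2")

  expect_error(parse_subspecies_name("18:0;0-18:0;0", cls = "TAG"), "3 chains")
})

test_that("chain formulas follow free-acid / sphingoid-base chemistry", {
  expect_equal(format(chain_formula(chain("FA", 16, 0, 0))), "C16H32O2")  # palmitic
  expect_equal(format(chain_formula(chain("LCB", 18, 1, 2))), "C18H37NO2") # sphingosine
  expect_equal(format(chain_formula(chain("FA", 18, 0, 1))), "C18H36O3")  # alpha-OH stearic
  expect_error(chain_formula(chain("FA", 16, 9, 0)), "over-unsaturated")
})

test_that("species formulas implement the class condensation chemistry", {
  ns <- parse_subspecies_name("NS 18:1;2-16:0;0")
  expect_equal(format(species_formula("NS", ns$chains)), "C34H67NO3")
  # cholesterol measured as its acetate derivative
  expect_equal(format(species_formula("Chol")), "C29H48O2")
  dag <- parse_subspecies_name("DAG 17:0;0-17:0;0")
  expect_equal(format(species_formula("DAG", dag$chains)), "C37H72O5")
  # EO ceramide gains the esterified omega-oxygen not written in the name
  eos <- parse_subspecies_name("EOS 18:1;2-32:0;0-18:2;0")
  expect_equal(format(species_formula("EOS", eos$chains)), "C68H129NO5")
  ce <- parse_subspecies_name("CE 16:0;0")
  expect_equal(format(species_formula("CE", ce$chains)), "C43H76O2") # cholesteryl palmitate
  expect_error(species_formula("TAG", dag$chains), "3 chains")
})

test_that("monoisotopic masses agree with an independent atomic-mass oracle", {
  cases <- list(
    list(f = "H2O", counts = c(H = 2, O = 1)),
    list(f = "C16H32O2", counts = c(C = 16, H = 32, O = 2)),
    list(f = "C18H37NO2", counts = c(C = 18, H = 37, N = 1, O = 2)),
    list(f = "C34H67NO3", counts = c(C = 34, H = 67, N = 1, O = 3)),
    list(f = "C27H46O", counts = c(C = 27, H = 46, O = 1)),
    list(f = "C29H48O2", counts = c(C = 29, H = 48, O = 2)),
    list(f = "C2H3O2", counts = c(C = 2, H = 3, O = 2)),
    list(f = "NH4", counts = c(N = 1, H = 4)),
    list(f = "C68H129NO5", counts = c(C = 68, H = 129, N = 1, O = 5)),
    list(f = "C3H8O3", counts = c(C = 3, H = 8, O = 3)),
    list(f = "C36H68D3NO3", counts = c(C = 36, H = 68, D = 3, N = 1, O = 3))
  )
  for (cs in cases) {
    expect_equal(monoisotopic_mass(cs$f), ref_mass(cs$counts), tolerance = 1e-5)
  }
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-5)
  expect_equal(monoisotopic_mass("C34H67NO3"), 537.5121, tolerance = 5e-4)
  expect_equal(monoisotopic_mass(el_formula()), 0)
})

test_that("formula arithmetic is element-wise and mass-additive", {
  a <- parse_formula("C18H37NO2")
  b <- parse_formula("C16H32O2")
  ab <- formula_add(a, b)
  expect_equal(monoisotopic_mass(ab),
               monoisotopic_mass(a) + monoisotopic_mass(b), tolerance = 1e-9)
  expect_equal(format(formula_subtract(ab, b)), format(a))
  expect_error(formula_subtract(b, a), "negative")
  set.seed(1)
  for (i in 1:20) {
    x <- el_formula(C = sample(1:50, 1), H = sample(1:100, 1), O = sample(0:6, 1) + 1)
    y <- el_formula(C = sample(1:50, 1), H = sample(1:100, 1), N = 1)
    expect_equal(monoisotopic_mass(formula_add(x, y)),
                 monoisotopic_mass(x) + monoisotopic_mass(y), tolerance = 1e-9)
  }
})

test_that("adduct m/z includes the electron mass for both polarities", {
  m <- 537.5121
  expect_equal(adduct_mz(m, "acetate"), m + 59.013305 + 0.000549, tolerance = 1e-3)
  # ammonium shift alone: NH4 minus the electron
  expect_equal(adduct_mz(m, "ammonium") - m, 18.033825, tolerance = 1e-3)
  expect_error(adduct_mz(0, "acetate"), "positive")
})

test_that("deuterium labelling shifts mass by n x (D - H)", {
  ns <- parse_subspecies_name("NS 18:1;2-18:0;0")
  f <- species_formula("NS", ns$chains)
  f3 <- apply_label(f, 3)
  expect_equal(monoisotopic_mass(f3) - monoisotopic_mass(f), 3.01883,
               tolerance = 5e-4)
  expect_identical(apply_label(f, 0), f)
  expect_error(apply_label(el_formula(C = 1, H = 2), 5), "only 2 H")
})

test_that("chain-wise and sum-composition formulas agree for non-EO ceramides", {
  # same class chemistry: any chain split of a sum composition gives the
  # same elemental formula
  set.seed(3)
  for (i in 1:15) {
    lcb_c <- sample(seq(16, 22, 2), 1)
    fa_c <- sample(seq(14, 28, 2), 1)
    fa_db <- sample(0:2, 1)
    for (cls in c("NS", "AP", "NdS", "AH")) {
      base <- lipid_classes()$base[lipid_classes()$code == cls]
      link <- lipid_classes()$linkage[lipid_classes()$code == cls]
      lcb_db <- c(dS = 0, S = 1, P = 0, H = 1)[[base]]
      lcb_oh <- c(dS = 2, S = 2, P = 3, H = 3)[[base]]
      fa_oh <- c(N = 0, A = 1)[[link]]
      ch1 <- dplyr::bind_rows(chain("LCB", lcb_c, lcb_db, lcb_oh),
                              chain("FA", fa_c, fa_db, fa_oh))
      ch2 <- dplyr::bind_rows(chain("LCB", lcb_c + 2, lcb_db, lcb_oh),
                              chain("FA", fa_c - 2, fa_db, fa_oh))
      expect_equal(format(species_formula(cls, ch1)),
                   format(species_formula(cls, ch2)))
    }
  }
})
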