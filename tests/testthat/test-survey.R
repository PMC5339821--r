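# Survey statistics: totals, mol%, CVs, dynamic range, depth, PCA,
# clustering, correlations, random forest.

toy_qt <- function() {
  tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3"), each = 3),
    class = rep(c("NS", "TAG", "Chol"), 3),
    species = rep(c("NS 34:1;2", "TAG 50:1;0", "Chol"), 3),
    subspecies = NA_character_,
    pmol = c(10, 20, 30, 90, 100, 110, 1, 1, 2)
  )
}

test_that("totals and mol% behave on worked examples and under scaling", {
  tot <- total_lipid(toy_qt())
  expect_equal(tot$total_pmol[tot$sample_id == "s1"], 60)
  mp <- mol_percent(toy_qt())
  s3 <- mp[mp$sample_id == "s3", ]
  expect_equal(sort(s3$molpct), c(25, 25, 50))
  sums <- tapply(mp$molpct, mp$sample_id, sum)
  expect_equal(as.numeric(sums), rep(100, 3), tolerance = 1e-9)
  # scaling a sample's amounts leaves its mol% unchanged
  qt2 <- toy_qt()
  qt2$pmol[qt2$sample_id == "s2"] <- qt2$pmol[qt2$sample_id == "s2"] * 7.3
  mp2 <- mol_percent(qt2)
  expect_equal(mp2$molpct[mp2$sample_id == "s2"], mp$molpct[mp$sample_id == "s2"])
  # a zero-total sample is excluded with a warning
  qt3 <- toy_qt(); qt3$pmol[qt3$sample_id == "s1"] <- 0
  expect_warning(mp3 <- mol_percent(qt3), "zero-total")
  expect_false("s1" %in% mp3$sample_id)
})

test_that("cv_report matches hand-computed CVs and summaries", {
  wide <- tibble::tibble(
    sample_id = c("r1", "r2", "r3"),
    lipA = c(90, 100, 110),         # CV 10
    lipB = c(100, 100, 100),        # CV 0
    lipC = c(50, 100, 150),         # CV 50
    lipD = c(NA, 100, 100)          # not present in all replicates
  )
  cv <- cv_report(wide, threshold = 15)
  per <- tidy(cv)
  expect_equal(per$cv[per$lipid == "lipA"], 10, tolerance = 1e-9)
  expect_equal(per$cv[per$lipid == "lipB"], 0)
  expect_false("lipD" %in% per$lipid)
  g <- glance(cv)
  expect_equal(g$n_lipids, 3)
  expect_equal(g$median_cv, 10)
  expect_equal(g$frac_below, 2 / 3)
  # identical replicates: all CVs zero
  same <- tibble::tibble(sample_id = c("a", "b"), x = c(5, 5), y = c(7, 7))
  expect_equal(max(tidy(cv_report(same))$cv), 0)
})

test_that("dynamic-range fits recover exact proportionality and the spec'd range", {
  spikes <- tibble::tibble(pmol = c(10, 30, 100, 300, 1000, 3000),
                           sn = c(10, 30, 100, 300, 1000, 3000) * 0.7)
  fit <- dynamic_range_fit(spikes)
  g <- glance(fit)
  expect_equal(g$slope, 1, tolerance = 1e-9)
  expect_equal(g$r.squared, 1, tolerance = 1e-9)
  expect_equal(g$range_orders, log10(3000 / 10), tolerance = 1e-9) # 2.48 orders
  expect_equal(g$loq_pmol, 10)
  expect_error(dynamic_range_fit(tibble::tibble(pmol = c(1, -2, 3), sn = c(1, 2, 3))),
               "positive")
})

test_that("depth profiles find plateaus and report gaps", {
  meta <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:12), subject_id = "x", sex = "F", age = 1,
    site = "volar forearm", layer = rep(c(1:5, 8), each = 2),
    replicate_group = NA_character_, is_blank = FALSE, batch = "B1"
  )
  mk_qt <- function(totals) purrr::map_dfr(seq_len(nrow(meta)), function(i) {
    tibble::tibble(sample_id = meta$sample_id[i], class = c("NS", "TAG"),
                   species = c("NS 34:1;2", "TAG 50:1;0"), subspecies = NA,
                   pmol = totals[i] * c(0.4, 0.6))
  })
  # flat series: zero drop, plateau at the first layer
  flat <- depth_profile(mk_qt(rep(100, 12)), meta)
  expect_equal(flat$drop_pct, 0)
  expect_equal(flat$plateau_layer, 1)
  # decaying series with a configured 85% drop by layer 5
  decay <- 15 + 85 * exp(-1.5 * (rep(c(1:5, 8), each = 2) - 1))
  dp <- depth_profile(mk_qt(decay), meta, from = 1, to = 5)
  expect_equal(dp$drop_pct, (1 - decay[9] / decay[1]) * 100, tolerance = 1e-9)
  expect_message(depth_profile(mk_qt(decay), meta), "no samples for layer")
  # plateau detection is monotone in the tolerance
  p_loose <- depth_profile(mk_qt(decay), meta, tol = 0.5)$plateau_layer
  p_tight <- depth_profile(mk_qt(decay), meta, tol = 0.01)$plateau_layer
  expect_lte(p_loose, p_tight)
})

test_that("PCA is invariant to lipid order, duplicates map together, variance sums to 100", {
  set.seed(12)
  wide <- tibble::tibble(sample_id = sprintf("s%d", 1:8))
  for (l in c("NS a", "NS b", "TAG a", "TAG b", "Chol")) {
    wide[[l]] <- stats::rnorm(8, 10, 3)
  }
  wide2 <- wide[, c("sample_id", sample(setdiff(names(wide), "sample_id")))]
  p1 <- pca_lipidome(wide); p2 <- pca_lipidome(wide2)
  expect_equal(abs(p1$scores$PC1), abs(p2$scores$PC1), tolerance = 1e-9)
  expect_equal(sum(p1$var_explained), 100, tolerance = 1e-9)
  expect_true(all(diff(p1$var_explained) <= 1e-12))
  # duplicated sample: identical scores
  wide3 <- dplyr::bind_rows(wide, wide[1, ])
  p3 <- pca_lipidome(wide3)
  expect_equal(unlist(p3$scores[9, -1]), unlist(p3$scores[1, -1]), tolerance = 1e-9)
  # subsetting: ceramides-only drops the TAG/Chol columns
  p4 <- pca_lipidome(wide, subset = "ceramides")
  expect_equal(ncol(p4$loadings), 2)
})

test_that("site clustering uses 1 - r distances and groups sebum-rich sites", {
  set.seed(8)
  base <- stats::runif(12, 5, 20)
  sebum <- base + c(rep(30, 4), rep(0, 8))[1:12]
  mk_site <- function(profile, jitter) profile * stats::rlnorm(12, 0, jitter)
  sites <- c("cheek", "forehead", "pectoral region", "shoulder blade",
             "abdomen", "thigh", "palm", "heel sole")
  lipids <- c(sprintf("TAG %d:1;0", seq(44, 54, 2)), sprintf("NS %d:1;2", seq(34, 44, 2)))
  prof <- rbind(
    t(replicate(4, mk_site(sebum, 0.08))),
    t(replicate(4, mk_site(base, 0.08)))
  )
  wide <- tibble::tibble(sample_id = sites)
  for (j in seq_along(lipids)) wide[[lipids[j]]] <- prof[, j]
  cl <- cluster_sites(wide, sites)
  expect_true(grepl("cheek", cl$newick))
  expect_equal(unname(diag(cl$dist)), rep(0, 8), tolerance = 1e-12)
  expect_equal(cl$dist, t(cl$dist), tolerance = 1e-12)
  memb <- site_clusters(cl, 2)
  expect_equal(length(unique(memb[c("cheek", "forehead", "pectoral region",
                                    "shoulder blade")])), 1)
  # identical sites merge at distance ~0
  wide2 <- wide; wide2[2, -1] <- wide2[1, -1]
  cl2 <- cluster_sites(wide2, sites)
  expect_lt(cl2$hclust$height[1], 1e-9)
})

test_that("correlations match their closed-form extremes", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x, "pearson")$estimate, 1, tolerance = 1e-12)
  expect_equal(correlate(x, rev(x), "spearman")$estimate, -1, tolerance = 1e-12)
  r <- correlate(c(1, 2, 3, 5, 8), c(2, 1, 4, 4, 9), "pearson")
  ct <- stats::cor.test(c(1, 2, 3, 5, 8), c(2, 1, 4, 4, 9))
  expect_equal(r$estimate, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r$p.value, ct$p.value, tolerance = 1e-12)
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
})

test_that("the occurrence filter keeps cohort-shared lipids", {
  wide <- tibble::tibble(
    sample_id = sprintf("s%d", 1:4),
    common = c(1, 2, 3, 4),
    rare = c(1, NA, NA, NA),
    cohA = c(5, 6, NA, NA)
  )
  # one cohort: 'rare' present in 25% only
  f1 <- occurrence_filter(wide, occurrence = 0.5)
  expect_setequal(setdiff(names(f1), "sample_id"), c("common", "cohA"))
  # two cohorts: cohA qualifies via cohort 1 and is kept for everyone
  f2 <- occurrence_filter(wide, cohorts = c("c1", "c1", "c2", "c2"))
  expect_true("cohA" %in% names(f2))
})

test_that("random-forest sex prediction sits at the null rate for permuted labels", {
  set.seed(99)
  n <- 60
  wide <- tibble::tibble(sample_id = sprintf("s%03d", 1:n))
  for (l in sprintf("NS %d:1;2", seq(30, 48, 2))) wide[[l]] <- stats::rlnorm(n, 3, 0.4)
  meta <- tibble::tibble(sample_id = wide$sample_id,
                         sex = sample(rep(c("F", "M"), c(36, 24))))
  fit <- rf_sex_prediction(wide, meta, spec = model_spec(folds = 5, repeats = 2,
                                                         ntree = 200))
  expect_equal(fit$null_rate, 0.6)
  # labels carry no signal: accuracy within 2 sd of the null rate
  expect_lt(abs(fit$mean_accuracy - fit$null_rate), 2 * max(fit$sd_accuracy, 0.05))
})
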