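# Downstream survey statistics on quantitative lipid tables: totals and
# mol%, replicate CVs, dynamic-range fits, depth profiles, PCA, correlation
# clustering of body sites, correlations, and repeated cross-validated
# random-forest sex classification.

#' Pivot a quantitative table to a samples-by-lipids matrix
#'
#' @param qt QuantTable tibble (`sample_id`, `class`, `species`,
#'   `subspecies`, `pmol`); typically [apply_filters()] output restricted to
#'   `kept` rows.
#' @param value `"pmol"` or `"molpct"` (per-sample mol% of the included
#'   lipids).
#' @param level `"subspecies"` (default; falls back to the species name
#'   where chains are unresolved), `"species"` or `"class"`.
#' @return A wide tibble: `sample_id` plus one column per lipid; absent
#'   (sample, lipid) pairs are `NA`.
#' @export
lipidome_matrix <- function(qt, value = c("pmol", "molpct"),
                            level = c("subspecies", "species", "class")) {
  value <- match.arg(value)
  level <- match.arg(level)
  d <- qt
  d$lipid <- switch(level,
    subspecies = dplyr::coalesce(d$subspecies, d$species),
    species = d$species,
    class = d$class
  )
  d <- d |>
    dplyr::group_by(.data$sample_id, .data$lipid) |>
    dplyr::summarise(pmol = sum(.data$pmol), .groups = "drop")
  if (value == "molpct") {
    d <- d |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(total = sum(.data$pmol)) |>
      dplyr::ungroup()
    zero <- unique(d$sample_id[d$total <= 0])
    if (length(zero) > 0) {
      warn(paste0("excluding zero-total sample(s): ", paste(zero, collapse = ", ")))
      d <- d[!d$sample_id %in% zero, ]
    }
    d$pmol <- d$pmol / d$total * 100
    d$total <- NULL
  }
  wide <- tidyr::pivot_wider(d, names_from = "lipid", values_from = "pmol")
  attr(wide, "value") <- value
  wide
}

#' Total lipid amount per sample
#' @param qt QuantTable tibble.
#' @return Tibble `sample_id`, `total_pmol` (missing amounts count as 0).
#' @export
total_lipid <- function(qt) {
  qt |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total_pmol = sum(.data$pmol, na.rm = TRUE), .groups = "drop")
}

#' Relative (mol%) amounts per sample
#' @param qt QuantTable tibble.
#' @return `qt` with `pmol` replaced by `molpct`; zero-total samples are
#'   excluded with a warning.
#' @export
mol_percent <- function(qt) {
  tot <- total_lipid(qt)
  d <- dplyr::left_join(qt, tot, by = "sample_id")
  zero <- unique(d$sample_id[d$total_pmol <= 0])
  if (length(zero) > 0) {
    warn(paste0("excluding zero-total sample(s): ", paste(zero, collapse = ", ")))
    d <- d[!d$sample_id %in% zero, ]
  }
  d$molpct <- d$pmol / d$total_pmol * 100
  d$total_pmol <- NULL
  d
}

# ---- replicate CVs ----------------------------------------------------------

#' Replicate coefficient-of-variation report
#'
#' CV = sample (n-1) standard deviation / mean x 100, per lipid, over a set
#' of replicate acquisitions. Only lipids present (positive) in all
#' replicates are considered; zero-mean lipids are excluded.
#'
#' @param wide Samples-by-lipids tibble ([lipidome_matrix()]) restricted to
#'   the replicate set (>= 2 rows).
#' @param threshold Reporting threshold in CV% for the summary fraction
#'   (default 15).
#' @return An object of class `cv_report` with `per_lipid` (tibble `lipid`,
#'   `mean_pmol`, `cv`) and `summary` (`n_lipids`, `median_cv`,
#'   `frac_below`); see [tidy.cv_report()] / [glance.cv_report()].
#' @export
cv_report <- function(wide, threshold = 15) {
  stopifnot(nrow(wide) >= 2)
  m <- as.matrix(wide[, setdiff(names(wide), "sample_id"), drop = FALSE])
  present_all <- apply(m, 2, function(x) all(!is.na(x) & x > 0))
  m <- m[, present_all, drop = FALSE]
  mu <- colMeans(m)
  keep <- mu > 0
  m <- m[, keep, drop = FALSE]; mu <- mu[keep]
  cv <- apply(m, 2, stats::sd) / mu * 100
  per <- tibble(lipid = colnames(m), mean_pmol = unname(mu), cv = unname(cv))
  structure(list(
    per_lipid = per,
    summary = tibble(
      n_lipids = nrow(per),
      median_cv = stats::median(per$cv),
      frac_below = mean(per$cv < threshold),
      threshold = threshold
    )
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv_report> %d lipids; median CV %.2f%%; %.0f%% below %g%% CV\n",
              s$n_lipids, s$median_cv, 100 * s$frac_below, s$threshold))
  invisible(x)
}

#' @rdname cv_report
#' @param x A `cv_report`.
#' @param ... Unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$per_lipid

#' @rdname cv_report
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) x$summary

# ---- dynamic range ----------------------------------------------------------

#' Fit the spike-series dynamic range
#'
#' Least-squares fit of log10(S/N) on log10(pmol). The limit of
#' quantification is the lowest spike whose S/N exceeds the gate; the linear
#' range is reported in orders of magnitude spanned by quantifiable spikes.
#'
#' @param spikes Tibble with columns `pmol`, `sn` (>= 3 positive levels).
#' @param sn_gate Quantification S/N gate (default 5, exclusive).
#' @return An object of class `dynrange_fit`; see [glance.dynrange_fit()].
#' @export
dynamic_range_fit <- function(spikes, sn_gate = 5) {
  stopifnot(all(c("pmol", "sn") %in% names(spikes)))
  d <- spikes[!is.na(spikes$sn), ]
  if (any(d$pmol <= 0) || any(d$sn <= 0)) abort("spike amounts and S/N must be positive")
  if (nrow(d) < 3) abort("need at least 3 spike levels")
  fit <- stats::lm(log10(sn) ~ log10(pmol), data = d)
  quantifiable <- d$pmol[d$sn > sn_gate]
  loq <- if (length(quantifiable) > 0) min(quantifiable) else NA_real_
  range_orders <- if (length(quantifiable) > 1) {
    log10(max(quantifiable) / min(quantifiable))
  } else NA_real_
  structure(list(fit = fit, data = d, sn_gate = sn_gate,
                 loq_pmol = loq, range_orders = range_orders),
            class = "dynrange_fit")
}

#' @export
print.dynrange_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<dynrange_fit> slope %.3f (R2 %.4f); LoQ %g pmol; linear range %.2f orders\n",
              g$slope, g$r.squared, g$loq_pmol, g$range_orders))
  invisible(x)
}

#' @rdname dynamic_range_fit
#' @param x A `dynrange_fit`.
#' @param ... Unused.
#' @method tidy dynrange_fit
#' @export
tidy.dynrange_fit <- function(x, ...) {
  co <- stats::coef(suppressWarnings(summary(x$fit)))
  tibble(term = rownames(co), estimate = co[, 1], std.error = co[, 2],
         statistic = co[, 3], p.value = co[, 4])
}

#' @rdname dynamic_range_fit
#' @method glance dynrange_fit
#' @export
glance.dynrange_fit <- function(x, ...) {
  tibble(
    slope = unname(stats::coef(x$fit)[2]),
    intercept = unname(stats::coef(x$fit)[1]),
    r.squared = suppressWarnings(summary(x$fit))$r.squared,
    loq_pmol = x$loq_pmol,
    range_orders = x$range_orders,
    n = nrow(x$data)
  )
}

# ---- depth profiles ---------------------------------------------------------

#' Depth (tape-stripping layer) profile of totals and class composition
#'
#' Per-layer replicate means of the total lipid amount and of class mol%,
#' the percent decline of the total between two layers, and a plateau
#' estimate: the first sampled layer after which every successive relative
#' change of the layer mean is below `tol`.
#'
#' @param qt QuantTable tibble.
#' @param meta Sample metadata with `layer`.
#' @param from,to Layers for the percent-decline summary (default 1 and the
#'   plateau layer).
#' @param tol Relative-change tolerance for the plateau call (default 0.1).
#' @return An object of class `depth_profile`: `layer_totals`,
#'   `class_curves`, `plateau_layer`, `drop_pct`, `gaps`.
#' @export
depth_profile <- function(qt, meta, from = 1, to = NULL, tol = 0.1) {
  m <- meta[match(qt$sample_id, meta$sample_id), ]
  d <- qt
  d$layer <- m$layer
  d <- d[!is.na(d$layer), ]
  if (nrow(d) == 0) abort("no layer-annotated samples")
  tot <- total_lipid(d) |>
    dplyr::left_join(dplyr::distinct(meta[, c("sample_id", "layer")]), by = "sample_id")
  layer_totals <- tot |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(mean_total = mean(.data$total_pmol),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$layer)
  all_layers <- seq(min(layer_totals$layer), max(layer_totals$layer))
  gaps <- setdiff(all_layers, layer_totals$layer)
  if (length(gaps) > 0) {
    message("depth_profile: no samples for layer(s) ", paste(gaps, collapse = ", "))
  }
  cls <- mol_percent(d) |>
    dplyr::group_by(.data$sample_id, .data$layer, .data$class) |>
    dplyr::summarise(molpct = sum(.data$molpct), .groups = "drop") |>
    dplyr::group_by(.data$layer, .data$class) |>
    dplyr::summarise(mean_molpct = mean(.data$molpct), .groups = "drop")

  mns <- layer_totals$mean_total
  rel <- abs(diff(mns)) / mns[-length(mns)]
  plateau_idx <- 1
  if (length(rel) > 0) {
    ok <- rev(cumprod(rev(rel < tol))) == 1 # TRUE where all later changes small
    plateau_idx <- if (any(ok)) min(which(ok)) else length(mns)
  }
  plateau_layer <- layer_totals$layer[plateau_idx]
  to <- to %||% plateau_layer
  m_from <- layer_totals$mean_total[match(from, layer_totals$layer)]
  m_to <- layer_totals$mean_total[match(to, layer_totals$layer)]
  drop_pct <- if (is.na(m_from) || is.na(m_to) || m_from <= 0) NA_real_ else
    (1 - m_to / m_from) * 100
  structure(list(layer_totals = layer_totals, class_curves = cls,
                 plateau_layer = plateau_layer, drop_pct = drop_pct,
                 from = from, to = to, tol = tol, gaps = gaps),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> layers %d-%d; total declines %.1f%% (layer %d to %d); plateau at layer %d\n",
              min(x$layer_totals$layer), max(x$layer_totals$layer),
              x$drop_pct, x$from, x$to, x$plateau_layer))
  invisible(x)
}

# ---- PCA --------------------------------------------------------------------

.lipid_class_of <- function(lipid) sub("\\s.*$", "", lipid)

.subset_lipids <- function(lipids, subset) {
  cls <- .lipid_class_of(lipids)
  switch(subset,
    all = lipids,
    ceramides = lipids[is_ceramide(cls)],
    sebum = lipids[cls %in% .SEBUM_CLASSES]
  )
}

#' PCA of sample lipidomes
#'
#' Standard principal component analysis of a (typically mol%) lipid matrix,
#' optionally restricted to ceramides or sebum lipids; columns are centered
#' and unit-variance scaled by default (lipid abundances span orders of
#' magnitude). Missing values are median-imputed per lipid;
#' constant lipids are removed. Rank-deficient inputs simply return fewer
#' components.
#'
#' @param wide Samples-by-lipids tibble ([lipidome_matrix()]).
#' @param subset `"all"`, `"ceramides"` or `"sebum"`.
#' @param center,scale. Passed to [stats::prcomp()].
#' @return An object of class `lipid_pca`: `scores` (tibble with
#'   `sample_id`), `loadings`, `var_explained`, and the underlying `prcomp`.
#' @export
pca_lipidome <- function(wide, subset = c("all", "ceramides", "sebum"),
                         center = TRUE, scale. = TRUE) {
  subset <- match.arg(subset)
  lipids <- .subset_lipids(setdiff(names(wide), "sample_id"), subset)
  if (length(lipids) < 2) abort("need at least 2 lipids after subsetting")
  if (nrow(wide) < 2) abort("need at least 2 samples")
  m <- as.matrix(wide[, lipids, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- stats::median(m[, j], na.rm = TRUE)
  }
  sdev <- apply(m, 2, stats::sd)
  m <- m[, sdev > 0, drop = FALSE]
  if (ncol(m) < 2) abort("fewer than 2 non-constant lipids")
  pc <- stats::prcomp(m, center = center, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2) * 100
  scores <- as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble(sample_id = wide$sample_id), scores)
  structure(list(scores = scores, loadings = pc$rotation,
                 var_explained = ve, prcomp = pc, subset = subset),
            class = "lipid_pca")
}

#' @export
print.lipid_pca <- function(x, ...) {
  cat(sprintf("<lipid_pca> (%s lipids) %d samples x %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              x$subset, nrow(x$scores), length(x$var_explained),
              x$var_explained[1],
              ifelse(length(x$var_explained) > 1, x$var_explained[2], NA)))
  invisible(x)
}

#' @rdname pca_lipidome
#' @param x A `lipid_pca`.
#' @param ... Unused.
#' @method tidy lipid_pca
#' @export
tidy.lipid_pca <- function(x, ...) x$scores

#' @rdname pca_lipidome
#' @method glance lipid_pca
#' @export
glance.lipid_pca <- function(x, ...) {
  tibble(component = seq_along(x$var_explained), var_explained = x$var_explained)
}

# ---- site clustering --------------------------------------------------------

#' Correlation-based hierarchical clustering of body-site lipidomes
#'
#' Site profiles are replicate means of the lipid matrix; the distance
#' between two sites is 1 - Pearson correlation of their profiles, and the
#' dendrogram is built by agglomerative clustering (average linkage by
#' default) and serialized to Newick text.
#'
#' @param wide Samples-by-lipids tibble (mol% recommended).
#' @param sites Character vector of site labels aligned with `wide` rows
#'   (duplicated labels are averaged).
#' @param subset `"all"` or `"sebum"`.
#' @param linkage [stats::hclust()] method (default `"average"`).
#' @return An object of class `site_clustering`: `hclust`, `newick`,
#'   `dist` (matrix), `profiles`.
#' @export
cluster_sites <- function(wide, sites, subset = c("all", "sebum"),
                          linkage = "average") {
  subset <- match.arg(subset)
  stopifnot(length(sites) == nrow(wide))
  lipids <- .subset_lipids(setdiff(names(wide), "sample_id"), subset)
  if (length(lipids) < 2) abort("need at least 2 lipids after subsetting")
  m <- as.matrix(wide[, lipids, drop = FALSE])
  m[is.na(m)] <- 0
  prof <- rowsum(m, group = sites)
  prof <- prof / as.vector(table(sites)[rownames(prof)])
  if (nrow(prof) < 3) abort("need at least 3 sites")
  sds <- apply(prof, 1, stats::sd)
  if (any(sds == 0)) {
    warn(paste0("excluding constant site profile(s): ",
                paste(rownames(prof)[sds == 0], collapse = ", ")))
    prof <- prof[sds > 0, , drop = FALSE]
    if (nrow(prof) < 3) abort("fewer than 3 usable sites")
  }
  dmat <- 1 - stats::cor(t(prof))
  hc <- stats::hclust(stats::as.dist(dmat), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, newick = newick, dist = dmat, profiles = prof,
                 subset = subset, linkage = linkage),
            class = "site_clustering")
}

#' @export
print.site_clustering <- function(x, ...) {
  cat(sprintf("<site_clustering> %d sites, %s lipids, %s linkage\n%s\n",
              nrow(x$profiles), x$subset, x$linkage, x$newick))
  invisible(x)
}

#' Extract the members of the cluster containing given leaves
#' @param x A `site_clustering`.
#' @param k Number of clusters to cut into.
#' @return A named integer vector of cluster memberships.
#' @export
site_clusters <- function(x, k) stats::cutree(x$hclust, k = k)

# ---- correlations -----------------------------------------------------------

#' Two-tailed Pearson or Spearman correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return Tibble `estimate`, `p.value`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("zero-variance input")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided", exact = FALSE)
  )
  tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
         method = method, n = length(x))
}

# ---- random-forest sex prediction -------------------------------------------

#' Statistical-modelling specification
#'
#' Mirrors the survey's training protocol: only lipids present in at least
#' `occurrence` of samples per cohort are used (a lipid present in one
#' cohort is included for all); model training uses `repeats` times repeated
#' `folds`-fold cross validation, with centering, scaling, median imputation
#' of missing values and near-zero-variance removal fitted inside each
#' resampling fold.
#'
#' @param occurrence Presence fraction per cohort (default 0.5).
#' @param folds,repeats CV scheme (defaults 10 and 5).
#' @param ntree Random-forest trees (default 500); `mtry` is sqrt(p).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(occurrence = 0.5, folds = 10, repeats = 5, ntree = 500) {
  structure(list(occurrence = occurrence, folds = folds, repeats = repeats,
                 ntree = ntree), class = "model_spec")
}

#' Occurrence filter across cohorts
#'
#' @param wide Samples-by-lipids tibble.
#' @param cohorts Cohort labels per row (default: one cohort).
#' @param occurrence Required presence fraction within at least one cohort.
#' @return `wide` with non-qualifying lipid columns removed.
#' @export
occurrence_filter <- function(wide, cohorts = NULL, occurrence = 0.5) {
  lipids <- setdiff(names(wide), "sample_id")
  cohorts <- cohorts %||% rep("all", nrow(wide))
  keep <- vapply(lipids, function(l) {
    pres <- !is.na(wide[[l]]) & wide[[l]] > 0
    any(tapply(pres, cohorts, mean) >= occurrence)
  }, logical(1))
  wide[, c("sample_id", lipids[keep])]
}

#' Random-forest sex prediction with repeated cross-validation
#'
#' Trains a random forest on the lipid matrix to predict sex, with the
#' resampling and fold-internal preprocessing of [model_spec()] (via caret:
#' center, scale, median imputation, near-zero-variance removal inside each
#' fold). Reports held-out accuracy per resample and the null error rate
#' (majority-class proportion).
#'
#' @param wide Samples-by-lipids tibble (mol% recommended).
#' @param meta Sample metadata with `sex` (two classes).
#' @param spec A [model_spec()].
#' @param subset `"all"` or `"no_sebum"` (drops TAG/DAG lipids).
#' @return An object of class `rf_sex_fit`: `resample_accuracy`,
#'   `mean_accuracy`, `sd_accuracy`, `null_rate`, the caret `train` object.
#' @export
rf_sex_prediction <- function(wide, meta, spec = model_spec(),
                              subset = c("all", "no_sebum")) {
  subset <- match.arg(subset)
  sex <- meta$sex[match(wide$sample_id, meta$sample_id)]
  ok <- !is.na(sex)
  wide <- wide[ok, ]; sex <- factor(sex[ok])
  if (nlevels(sex) != 2) abort("sex prediction needs exactly two classes")
  wide <- occurrence_filter(wide, cohorts = NULL, occurrence = spec$occurrence)
  lipids <- setdiff(names(wide), "sample_id")
  if (subset == "no_sebum") {
    lipids <- lipids[!.lipid_class_of(lipids) %in% .SEBUM_CLASSES]
  }
  if (length(lipids) < 2) abort("need at least 2 predictor lipids")
  x <- as.data.frame(wide[, lipids, drop = FALSE])
  names(x) <- make.names(names(x))
  ctrl <- caret::trainControl(method = "repeatedcv", number = spec$folds,
                              repeats = spec$repeats, classProbs = FALSE)
  fit <- caret::train(
    x = x, y = sex, method = "rf",
    trControl = ctrl,
    preProcess = c("medianImpute", "center", "scale", "nzv"),
    tuneGrid = data.frame(mtry = max(1, floor(sqrt(ncol(x))))),
    ntree = spec$ntree,
    na.action = stats::na.pass
  )
  acc <- fit$resample$Accuracy
  structure(list(
    resample_accuracy = acc,
    mean_accuracy = mean(acc),
    sd_accuracy = stats::sd(acc),
    null_rate = max(table(sex)) / length(sex),
    n_samples = length(sex), n_lipids = ncol(x),
    subset = subset, train = fit
  ), class = "rf_sex_fit")
}

#' @export
print.rf_sex_fit <- function(x, ...) {
  cat(sprintf("<rf_sex_fit> (%s) accuracy %.3f +- %.3f over %d resamples; null rate %.3f\n",
              x$subset, x$mean_accuracy, x$sd_accuracy,
              length(x$resample_accuracy), x$null_rate))
  invisible(x)
}

#' @rdname rf_sex_prediction
#' @param x An `rf_sex_fit`.
#' @param ... Unused.
#' @method tidy rf_sex_fit
#' @export
tidy.rf_sex_fit <- function(x, ...) {
  tibble(resample = seq_along(x$resample_accuracy),
         accuracy = x$resample_accuracy)
}

#' @rdname rf_sex_prediction
#' @method glance rf_sex_fit
#' @export
glance.rf_sex_fit <- function(x, ...) {
  tibble(mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy,
         null_rate = x$null_rate, n_samples = x$n_samples,
         n_lipids = x$n_lipids, subset = x$subset)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
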