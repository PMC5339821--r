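# Isotope envelopes and type I / type II intensity correction.
#
# Type II rescales a species' monoisotopic intensity for the fraction of its
# ion current carried by heavier isotopologues; type I removes the
# contribution that isotopologues of lighter species make to a heavier
# species' monoisotopic peak when the instrument cannot resolve them.

# Natural heavy-isotope abundances and mass shifts (Da) relative to the
# lightest isotope. Pinned constants: corrections must be reproducible to
# the tolerances the engine promises.
.ISOTOPE_DATA <- list(
  C = list(p = c(0.0107), dk = c(1L), dm = c(1.0033548)),
  H = list(p = c(0.000115), dk = c(1L), dm = c(1.0062767)),
  N = list(p = c(0.00364), dk = c(1L), dm = c(0.9970349)),
  O = list(p = c(0.00038, 0.00205), dk = c(1L, 2L), dm = c(1.0042169, 2.0042449)),
  D = list(p = numeric(0), dk = integer(0), dm = numeric(0)) # label: no natural variation modelled
)

.env_cache <- new.env(parent = emptyenv())

# distribution representation: list(p = abundance by nominal offset 0..k_max,
# m = abundance-weighted mean exact mass offset per nominal offset)
.dist_delta <- function(k_max) list(p = c(1, rep(0, k_max)), m = rep(0, k_max + 1))

.dist_convolve <- function(a, b, k_max) {
  p <- rep(0, k_max + 1); mw <- rep(0, k_max + 1)
  for (i in seq_along(a$p)) {
    if (a$p[i] == 0) next
    jmax <- k_max + 2 - i
    js <- seq_len(min(jmax, length(b$p)))
    w <- a$p[i] * b$p[js]
    ks <- i + js - 1
    p[ks] <- p[ks] + w
    mw[ks] <- mw[ks] + w * (a$m[i] + b$m[js])
  }
  list(p = p, m = ifelse(p > 0, mw / p, 0))
}

# exact single-element distribution for n atoms of one element
.element_dist <- function(el, n, k_max) {
  iso <- .ISOTOPE_DATA[[el]]
  if (is.null(iso)) abort(paste0("no isotope data for element '", el, "'"))
  if (length(iso$p) == 0 || n == 0) return(.dist_delta(k_max))
  p_light <- 1 - sum(iso$p)
  p <- rep(0, k_max + 1); mw <- rep(0, k_max + 1)
  # enumerate heavy-substitution counts (i per heavy isotope), truncated at k_max
  max_per <- pmin(n, k_max %/% iso$dk)
  grid <- expand.grid(lapply(max_per, function(m) 0:m))
  for (r in seq_len(nrow(grid))) {
    cnt <- as.numeric(grid[r, ])
    k <- sum(cnt * iso$dk)
    if (k > k_max || sum(cnt) > n) next
    # multinomial: n atoms over (light, heavy_1, heavy_2, ...)
    lw <- lgamma(n + 1) - sum(lgamma(cnt + 1)) - lgamma(n - sum(cnt) + 1) +
      sum(cnt * log(iso$p)) + (n - sum(cnt)) * log(p_light)
    w <- exp(lw)
    p[k + 1] <- p[k + 1] + w
    mw[k + 1] <- mw[k + 1] + w * sum(cnt * iso$dm)
  }
  list(p = p, m = ifelse(p > 0, mw / p, 0))
}

#' Natural isotope envelope of an elemental formula
#'
#' Full polynomial convolution of per-element multinomial isotope
#' distributions, truncated at nominal offset `k_max` and normalized so the
#' monoisotopic (k = 0) abundance is 1. Each row carries the
#' abundance-weighted exact mass offset of its nominal isotopologue peak.
#'
#' @param f An `el_formula` or formula string.
#' @param k_max Highest nominal isotopologue retained (default 3; M+3 is
#'   below 1% of M for the lipid formulas covered).
#' @return A tibble `k`, `mass_offset`, `abundance`.
#' @examples
#' isotope_envelope("C1") # M+1/M ~ 0.0108 (13C/12C odds)
#' @export
isotope_envelope <- function(f, k_max = 3) {
  if (is.character(f)) f <- parse_formula(f)
  if (length(f) == 0) abort("empty formula has no isotope envelope")
  key <- paste0(format(f), "@", k_max)
  hit <- .env_cache[[key]]
  if (!is.null(hit)) return(hit)
  d <- .dist_delta(k_max)
  for (el in names(f)) {
    d <- .dist_convolve(d, .element_dist(el, as.integer(f[[el]]), k_max), k_max)
  }
  out <- tibble(
    k = 0:k_max,
    mass_offset = d$m,
    abundance = d$p / d$p[1]
  )
  .env_cache[[key]] <- out
  out
}

#' Fraction of a species' ion current in its monoisotopic peak
#'
#' Computed in closed form over all isotopologues (no truncation):
#' the product over atoms of the lightest-isotope probability.
#'
#' @param f An `el_formula` or formula string.
#' @return A scalar in (0, 1].
#' @export
monoisotopic_fraction <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  out <- 1
  for (el in names(f)) {
    iso <- .ISOTOPE_DATA[[el]]
    if (is.null(iso)) abort(paste0("no isotope data for element '", el, "'"))
    out <- out * (1 - sum(iso$p))^as.integer(f[[el]])
  }
  out
}

#' Orbitrap-style resolution model
#'
#' Resolving power is specified at m/z 200 and scales as m/z^(-1/2), so
#' FWHM(m/z) = m/z / (R200 * sqrt(200 / m/z)).
#'
#' @param r_ms,r_msms Resolving power at m/z 200 for MS and MSMS scans
#'   (defaults 280000 and 17500, the platform's acquisition settings).
#' @param overlap_multiplier Peaks closer than `overlap_multiplier * FWHM`
#'   are treated as unresolved (default 1).
#' @return A list of class `resolution_model`.
#' @export
resolution_model <- function(r_ms = 280000, r_msms = 17500, overlap_multiplier = 1) {
  stopifnot(r_ms > 0, r_msms > 0, overlap_multiplier > 0)
  structure(list(r_ms = r_ms, r_msms = r_msms, ref_mz = 200,
                 overlap_multiplier = overlap_multiplier),
            class = "resolution_model")
}

#' Peak full width at half maximum under a resolution model
#' @param model A [resolution_model()].
#' @param mz m/z value(s).
#' @param level `"MS"` or `"MSMS"`.
#' @return FWHM in Da.
#' @export
fwhm <- function(model, mz, level = c("MS", "MSMS")) {
  level <- match.arg(level)
  r200 <- if (level == "MS") model$r_ms else model$r_msms
  mz / (r200 * sqrt(model$ref_mz / mz))
}

#' Type I isotope correction: remove isotopologue overlap between species
#'
#' Proceeding from light to heavy, the contribution that each species'
#' heavier isotopologues make to the monoisotopic peak of any heavier
#' species is subtracted whenever the exact isotopologue mass falls within
#' `overlap_multiplier * FWHM` of that peak at the given scan level.
#' Corrected intensities are floored at zero with a flag.
#'
#' @param df Tibble with columns `mz` (monoisotopic peak m/z, sorted or not),
#'   `intensity` and `formula` (string or `el_formula` list-column).
#' @param model A [resolution_model()].
#' @param level `"MS"` or `"MSMS"`.
#' @param k_max Envelope truncation (default 3).
#' @return `df` with added columns `intensity_type1` (corrected),
#'   `subtracted` (total contribution removed) and `floored` (logical).
#' @export
correct_type1 <- function(df, model = resolution_model(), level = "MS", k_max = 3) {
  stopifnot(all(c("mz", "intensity", "formula") %in% names(df)))
  ord <- order(df$mz)
  d <- df[ord, ]
  n <- nrow(d)
  corr <- d$intensity
  subtracted <- rep(0, n)
  floored <- rep(FALSE, n)
  if (n > 1) {
    envs <- lapply(d$formula, isotope_envelope, k_max = k_max)
    for (i in seq_len(n - 1)) {
      if (corr[i] <= 0) next
      env <- envs[[i]]
      for (k in seq_len(k_max)) {
        ab <- env$abundance[k + 1]
        if (ab <= 0) next
        iso_mz <- d$mz[i] + env$mass_offset[k + 1]
        js <- which(d$mz > d$mz[i] &
                      abs(d$mz - iso_mz) < model$overlap_multiplier * fwhm(model, d$mz, level))
        for (j in js) {
          contrib <- corr[i] * ab
          subtracted[j] <- subtracted[j] + contrib
          corr[j] <- corr[j] - contrib
        }
      }
    }
    neg <- corr < 0
    if (any(neg)) {
      floored[neg] <- TRUE
      corr[neg] <- 0
    }
  }
  res <- df
  res$intensity_type1 <- NA_real_
  res$subtracted <- NA_real_
  res$floored <- NA
  res$intensity_type1[ord] <- corr
  res$subtracted[ord] <- subtracted
  res$floored[ord] <- floored
  res
}

#' Type II isotope correction: rescale to the whole isotope cluster
#'
#' Divides a monoisotopic-peak intensity by the monoisotopic fraction of the
#' species' envelope so the value represents the full isotope cluster. With
#' finite `k_max` the fraction is taken over the truncated envelope (the
#' complement of what a `k_max`-truncated renderer distributes to heavier
#' isotopologues); `k_max = Inf` uses the closed-form full fraction.
#'
#' @param intensity Non-negative intensity (vectorized).
#' @param f An `el_formula` or formula string (single species).
#' @param k_max Envelope truncation (default 3) or `Inf`.
#' @return Rescaled intensity.
#' @export
correct_type2 <- function(intensity, f, k_max = 3) {
  stopifnot(all(intensity >= 0))
  frac <- if (is.infinite(k_max)) {
    monoisotopic_fraction(f)
  } else {
    env <- isotope_envelope(f, k_max)
    1 / sum(env$abundance)
  }
  intensity / frac
}
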