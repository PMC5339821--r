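# Independent oracles and fixture builders used across the suite.

# Reference monoisotopic masses (CODATA/IUPAC, more digits than the package
# table) for the independent mass oracle.
REF_MASS <- c(C = 12.0, H = 1.00782503207, D = 2.01410177785,
              N = 14.0030740048, O = 15.9949146196)
REF_ELECTRON <- 0.00054857991

# hand-rolled mass computation from a count vector, independent of the
# package's formula machinery
ref_mass <- function(counts) sum(REF_MASS[names(counts)] * counts)

# Natural-abundance table as pinned by the package (the correction
# tolerances are defined against these constants).
REF_ISO <- list(
  C = list(p = 0.0107, dk = 1),
  H = list(p = 0.000115, dk = 1),
  N = list(p = 0.00364, dk = 1),
  O = list(p = c(0.00038, 0.00205), dk = c(1, 2))
)

# Brute-force isotopologue enumeration: loops over heavy-substitution counts
# per isotope with binomial/multinomial weights, sums abundance by nominal
# mass offset. Independent of the package's convolution path.
brute_envelope <- function(counts, k_max = 3) {
  ab <- c(1, rep(0, k_max))
  dists <- lapply(names(counts), function(el) {
    n <- counts[[el]]
    d <- c(1, rep(0, k_max))
    if (el == "D" || n == 0) return(d)
    iso <- REF_ISO[[el]]
    d <- rep(0, k_max + 1)
    if (length(iso$p) == 1) {
      for (i in 0:min(n, k_max)) d[i + 1] <- stats::dbinom(i, n, iso$p)
    } else {
      p_light <- 1 - sum(iso$p)
      for (i in 0:min(n, k_max)) {
        for (j in 0:min(n - i, k_max %/% 2)) {
          k <- i * iso$dk[1] + j * iso$dk[2]
          if (k > k_max) next
          w <- exp(lgamma(n + 1) - lgamma(i + 1) - lgamma(j + 1) -
                     lgamma(n - i - j + 1) +
                     i * log(iso$p[1]) + j * log(iso$p[2]) +
                     (n - i - j) * log(p_light))
          d[k + 1] <- d[k + 1] + w
        }
      }
    }
    d
  })
  for (d in dists) {
    out <- rep(0, k_max + 1)
    for (i in seq_along(ab)) {
      for (j in seq_along(d)) {
        if (i + j - 1 > k_max + 1) break
        out[i + j - 1] <- out[i + j - 1] + ab[i] * d[j]
      }
    }
    ab <- out
  }
  ab / ab[1]
}

# one-spectrum acquisition run around explicit peaks
make_run <- function(mz, intensity, noise = 100, polarity = "-", level = "MS",
                     lockmass = TRUE, sample_id = "s1",
                     precursor_low = NA_real_, precursor_high = NA_real_) {
  acquisition_run(sample_id, tibble::tibble(
    level = level, polarity = polarity,
    precursor_low = precursor_low, precursor_high = precursor_high,
    lockmass = lockmass,
    peaks = list(tibble::tibble(mz = mz, intensity = intensity,
                                noise = rep(noise, length(mz))))
  ))
}

# single-candidate database row for a subspecies name
db_row <- function(subspecies) {
  sub <- parse_subspecies_name(subspecies)
  f <- species_formula(sub$cls, sub$chains)
  cls_tbl <- lipid_classes()
  i <- match(sub$cls, cls_tbl$code)
  m <- monoisotopic_mass(f)
  tibble::tibble(
    class = sub$cls, species = sub$species, subspecies = sub$subspecies,
    formula = format(f), neutral_mass = m, adduct = cls_tbl$adduct[i],
    polarity = cls_tbl$ion_mode[i], mz = adduct_mz(m, cls_tbl$adduct[i])
  )
}

db_rows <- function(...) dplyr::bind_rows(lapply(c(...), db_row))

# minimal mzML writer (64-bit float, little-endian, no compression) for
# reader-equivalence fixtures
write_mini_mzml <- function(path, spectra) {
  b64 <- function(x) {
    gsub("\n", "", jsonlite::base64_enc(writeBin(x, raw(), size = 8, endian = "little")))
  }
  spec_xml <- function(i, s) {
    polcv <- if (s$polarity == "+") {
      '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>'
    } else {
      '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>'
    }
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>%s',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'
    ), i - 1, i, length(s$mz), s$msLevel, polcv,
    nchar(b64(s$mz)), b64(s$mz), nchar(b64(s$intensity)), b64(s$intensity))
  }
  body <- paste(vapply(seq_along(spectra),
                       function(i) spec_xml(i, spectra[[i]]), ""), collapse = "\n")
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="x"/></cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="s" version="1"/></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="i"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="s"/></dataProcessing></dataProcessingList>',
    '<run id="r" defaultInstrumentConfigurationRef="i">',
    '<spectrumList count="%d" defaultDataProcessingRef="dp">%s</spectrumList>',
    '</run></mzML>'), length(spectra), body)
  writeLines(doc, path)
  path
}
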