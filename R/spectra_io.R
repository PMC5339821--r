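# Acquisition-data readers/writers.
#
# Native peak-list dialect (UTF-8, tab-delimited): one header line per
# spectrum,
#   #spectrum  level=MS|MSMS  polarity=+|-  precursor_low=<f>|NA
#   precursor_high=<f>|NA  lockmass=0|1
# followed by "mz<TAB>intensity<TAB>noise" rows; several spectra per file.
# Per-peak noise makes the S/N > 5 gate exercisable from plain-text fixtures.

#' Construct an acquisition run
#'
#' @param sample_id Sample identifier.
#' @param spectra Tibble with columns `level` ("MS"/"MSMS"), `polarity`
#'   ("+"/"-"), `precursor_low`, `precursor_high` (NA for MS), `lockmass`
#'   (logical) and `peaks` (list-column of tibbles `mz`, `intensity`,
#'   `noise`, sorted by m/z).
#' @param kind `"main"` or `"cholesterol-derivatized"` (cholesterol is
#'   acquired separately as its acetate).
#' @return A list of class `acquisition_run`.
#' @export
acquisition_run <- function(sample_id, spectra, kind = c("main", "cholesterol-derivatized")) {
  kind <- match.arg(kind)
  stopifnot(all(c("level", "polarity", "precursor_low", "precursor_high",
                  "lockmass", "peaks") %in% names(spectra)))
  spectra$peaks <- lapply(spectra$peaks, function(p) {
    if (any(p$intensity < 0)) abort("negative peak intensity")
    if (any(p$mz <= 0)) abort("non-positive peak m/z")
    if (is.unsorted(p$mz)) {
      warn("peaks not sorted by m/z; sorting")
      p <- p[order(p$mz), ]
    }
    p
  })
  structure(list(sample_id = sample_id, kind = kind, spectra = spectra),
            class = "acquisition_run")
}

#' @export
print.acquisition_run <- function(x, ...) {
  cat("<acquisition_run> sample ", x$sample_id, " (", x$kind, "): ",
      nrow(x$spectra), " spectra, ",
      sum(vapply(x$spectra$peaks, nrow, integer(1))), " peaks\n", sep = "")
  invisible(x)
}

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6f", x))
}

#' Write an acquisition run in the native peak-list dialect
#' @param run An `acquisition_run`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(run, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#run\tsample_id=", run$sample_id, "\tkind=", run$kind), con)
  for (i in seq_len(nrow(run$spectra))) {
    s <- run$spectra[i, ]
    writeLines(paste0(
      "#spectrum\tlevel=", s$level, "\tpolarity=", s$polarity,
      "\tprecursor_low=", .fmt_num(s$precursor_low),
      "\tprecursor_high=", .fmt_num(s$precursor_high),
      "\tlockmass=", as.integer(s$lockmass)
    ), con)
    p <- s$peaks[[1]]
    if (nrow(p) > 0) {
      writeLines(sprintf("%.6f\t%.4f\t%.4f", p$mz, p$intensity, p$noise), con)
    }
  }
  invisible(path)
}

.parse_header_fields <- function(line, lineno) {
  toks <- strsplit(line, "\t", fixed = TRUE)[[1]][-1]
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

#' Read an acquisition run from the native peak-list dialect
#'
#' Malformed peak lines are reported with their line numbers; unsorted peaks
#' are sorted with a warning; negative intensities are an error.
#'
#' @param path Input file.
#' @param sample_id Overrides the sample id recorded in the file.
#' @return An `acquisition_run`.
#' @export
read_peaklist <- function(path, sample_id = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[1], "#")) {
    abort(paste0("missing header line in '", path, "'"))
  }
  kind <- "main"
  file_sample <- NULL
  specs <- list()
  cur <- NULL
  flush_cur <- function() {
    if (is.null(cur)) return()
    pk <- if (length(cur$rows) == 0) {
      tibble(mz = numeric(), intensity = numeric(), noise = numeric())
    } else {
      m <- do.call(rbind, cur$rows)
      tibble(mz = m[, 1], intensity = m[, 2], noise = m[, 3])
    }
    cur$spec$peaks <- list(pk)
    specs[[length(specs) + 1]] <<- cur$spec
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (line == "") next
    if (startsWith(line, "#run")) {
      f <- .parse_header_fields(line, i)
      file_sample <- f[["sample_id"]]
      if ("kind" %in% names(f)) kind <- f[["kind"]]
    } else if (startsWith(line, "#spectrum")) {
      flush_cur()
      f <- .parse_header_fields(line, i)
      need <- c("level", "polarity", "precursor_low", "precursor_high", "lockmass")
      if (!all(need %in% names(f))) {
        abort(paste0("line ", i, ": spectrum header missing field(s): ",
                     paste(setdiff(need, names(f)), collapse = ", ")))
      }
      pol <- f[["polarity"]]
      if (pol == "−") pol <- "-" # accept unicode minus
      cur <- list(spec = tibble(
        level = f[["level"]], polarity = pol,
        precursor_low = suppressWarnings(as.numeric(f[["precursor_low"]])),
        precursor_high = suppressWarnings(as.numeric(f[["precursor_high"]])),
        lockmass = f[["lockmass"]] == "1"
      ), rows = list())
    } else {
      if (is.null(cur)) abort(paste0("line ", i, ": peak row before any #spectrum header"))
      v <- suppressWarnings(as.numeric(strsplit(line, "\t", fixed = TRUE)[[1]]))
      if (length(v) != 3 || any(is.na(v))) {
        abort(paste0("line ", i, ": malformed peak row (expected mz<TAB>intensity<TAB>noise)"))
      }
      if (v[2] < 0) abort(paste0("line ", i, ": negative intensity"))
      cur$rows[[length(cur$rows) + 1]] <- v
    }
  }
  flush_cur()
  if (length(specs) == 0) abort(paste0("no spectra in '", path, "'"))
  spectra <- dplyr::bind_rows(specs)
  acquisition_run(
    sample_id = sample_id %||% file_sample %||% basename(path),
    spectra = spectra,
    kind = if (kind %in% c("main", "cholesterol-derivatized")) kind else "main"
  )
}

#' Read centroided spectra from mzML
#'
#' Uses the `mzR` Bioconductor reader. Profile-mode spectra are rejected
#' with an instruction to centroid first; per-peak noise is not carried by
#' plain mzML and is set to 0 (unknown).
#'
#' @param path mzML file.
#' @param sample_id Sample id (default: file name).
#' @param kind Acquisition kind, as in [acquisition_run()].
#' @return An `acquisition_run`.
#' @export
read_mzml <- function(path, sample_id = NULL, kind = "main") {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("reading mzML requires the 'mzR' package")
  }
  h <- NULL
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  h <- mzR::header(ms)
  if (nrow(h) == 0) abort(paste0("no spectra in '", path, "'"))
  if (any(!h$centroided, na.rm = TRUE)) {
    abort("profile-mode spectra found: centroid the data before import")
  }
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  specs <- purrr::map(seq_len(nrow(h)), function(i) {
    p <- pk[[i]]
    msms <- h$msLevel[i] >= 2
    iso_lo <- h$isolationWindowTargetMZ[i] - h$isolationWindowLowerOffset[i]
    iso_hi <- h$isolationWindowTargetMZ[i] + h$isolationWindowUpperOffset[i]
    if (msms && (is.na(iso_lo) || is.na(iso_hi))) {
      iso_lo <- h$precursorMZ[i] - 0.5
      iso_hi <- h$precursorMZ[i] + 0.5
    }
    tibble(
      level = if (msms) "MSMS" else "MS",
      polarity = if (!is.null(h$polarity) && !is.na(h$polarity[i]) && h$polarity[i] == 0) "-" else
        if (!is.null(h$polarity) && !is.na(h$polarity[i]) && h$polarity[i] == 1) "+" else "+",
      precursor_low = if (msms) iso_lo else NA_real_,
      precursor_high = if (msms) iso_hi else NA_real_,
      lockmass = TRUE,
      peaks = list(tibble(
        mz = p[, 1], intensity = p[, 2], noise = 0
      ))
    )
  })
  acquisition_run(sample_id %||% basename(path), dplyr::bind_rows(specs), kind = kind)
}

.KNOWN_SITES <- c(
  "forehead", "cheek", "pectoral region", "abdomen", "groin", "thigh",
  "heel sole", "central calf", "shoulder blade", "buttock", "palm",
  "outside of hand", "top side of foot", "volar forearm"
)

#' Read and validate a sample-metadata table
#'
#' Tab-delimited columns: `sample_id`, `subject_id`, `sex`, `age`, `site`,
#' `layer`, `replicate_group`, `is_blank`, `batch`. Blanks (sampling disc
#' without skin) need no subject-level fields. Unknown site names are allowed
#' with a warning.
#'
#' @param path File path, or a data frame already in memory.
#' @return A validated tibble.
#' @export
read_sample_table <- function(path) {
  meta <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_tsv(path, col_types = readr::cols(
      sample_id = "c", subject_id = "c", sex = "c", age = "d", site = "c",
      layer = "i", replicate_group = "c", is_blank = "l", batch = "c"
    ), progress = FALSE)
  }
  need <- c("sample_id", "subject_id", "sex", "age", "site", "layer",
            "replicate_group", "is_blank", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) abort(paste0("sample table missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(meta$sample_id)) {
    abort(paste0("duplicate sample id(s): ",
                 paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", ")))
  }
  unknown <- setdiff(stats::na.omit(unique(meta$site[!meta$is_blank])), c(.KNOWN_SITES, "other"))
  if (length(unknown) > 0) {
    warn(paste0("unknown site name(s): ", paste(unknown, collapse = ", ")))
  }
  bad_layer <- !meta$is_blank & !is.na(meta$layer) & meta$layer < 1
  if (any(bad_layer)) abort("layer indices must be >= 1")
  meta
}

#' Read a long-format quantitative lipid table
#'
#' Loader for supplementary-style quantitative datasets: a delimited text
#' table with one row per (sample, lipid) amount. Column names are detected
#' case-insensitively among common variants and reported.
#'
#' @param path File path (tab- or comma-delimited; auto-detected).
#' @return A tibble `sample_id`, `class`, `species`, `subspecies`, `pmol`.
#' @export
read_quant_table <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  pick <- function(cands) {
    hit <- which(tolower(names(raw)) %in% cands)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  i_sample <- pick(c("sample_id", "sample", "sampleid"))
  i_class <- pick(c("class", "lipid_class", "lipid class"))
  i_species <- pick(c("species", "lipid_species", "lipid", "species_name"))
  i_sub <- pick(c("subspecies", "sub_species", "molecular_species"))
  i_pmol <- pick(c("pmol", "amount", "amount_pmol", "quantity"))
  if (is.na(i_sample) || is.na(i_pmol)) {
    abort("quant table needs at least a sample and a pmol/amount column")
  }
  out <- tibble(
    sample_id = raw[[i_sample]],
    class = if (is.na(i_class)) NA_character_ else raw[[i_class]],
    species = if (is.na(i_species)) NA_character_ else raw[[i_species]],
    subspecies = if (is.na(i_sub)) NA_character_ else raw[[i_sub]],
    pmol = as.numeric(raw[[i_pmol]])
  )
  if (all(is.na(out$class)) && !all(is.na(out$species))) {
    out$class <- sub("\\s.*$", "", out$species)
  }
  message("read_quant_table: mapped columns ",
          paste(names(raw)[stats::na.omit(c(i_sample, i_class, i_species, i_sub, i_pmol))],
                collapse = ", "))
  out
}

#' Write a quantitative lipid table (long format, tab-delimited)
#' @param qt QuantTable tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(qt, path) {
  readr::write_tsv(qt, path, progress = FALSE)
  invisible(path)
}
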