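# Combinatorial candidate database: enumeration of chain-resolved species
# under per-class constraints, precursor inclusion lists, and per-class MSMS
# fragment rules.

#' Default chain-enumeration constraints
#'
#' Chain ranges bracketing the lipid species reported in human stratum
#' corneum and sebum while keeping the candidate space desk-scale. All
#' fields may be overridden via `...`.
#'
#' @param even_only If `TRUE` (default) only even-carbon FA/LCB chains are
#'   enumerated; odd chains (e.g. the deuterated 17:0-based standards) can be
#'   added by turning this off or by passing explicit carbon vectors.
#' @param ... Named overrides of any constraint field.
#' @return A list of class `enum_constraints`.
#' @export
default_constraints <- function(even_only = TRUE, ...) {
  step <- if (even_only) 2 else 1
  cons <- list(
    lcb_c = seq(16, 22, by = step),
    bases = c("dS", "S", "P", "H"),
    linkages = c("N", "A", "EO"),
    fa_c = seq(14, 30, by = step),
    fa_db = 0:2,
    ester_c = seq(14, 22, by = step),
    ester_db = 0:3,
    ce_fa_c = seq(12, 26, by = step),
    ce_fa_db = 0:2,
    dag_fa_c = seq(14, 22, by = step),
    dag_fa_db = 0:2,
    dag_total_c = c(28, 44),
    tag_fa_c = seq(14, 20, by = step),
    tag_fa_db = 0:2,
    tag_total_c = c(40, 60),
    tag_total_db = c(0, 6),
    even_only = even_only
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cons))
  if (length(bad) > 0) abort(paste0("unknown constraint field(s): ", paste(bad, collapse = ", ")))
  cons[names(dots)] <- dots
  structure(cons, class = "enum_constraints")
}

# vectorized element counts of free chains (no validity check here)
.fa_elements <- function(c_, d, h) {
  list(C = c_, H = 2 * c_ - 2 * d, N = rep(0, length(c_)), O = 2 + h)
}
.lcb_elements <- function(c_, d, h) {
  list(C = c_, H = 2 * c_ + 3 - 2 * d, N = rep(1, length(c_)), O = h)
}

.valid_chain <- function(c_, d) d <= floor((c_ - 1) / 2)

.mass_from_elements <- function(C, H, N, O) {
  C * .ATOMIC_MASS[["C"]] + H * .ATOMIC_MASS[["H"]] +
    N * .ATOMIC_MASS[["N"]] + O * .ATOMIC_MASS[["O"]]
}

.formula_string <- function(C, H, N, O) {
  paste0(
    ifelse(C > 0, paste0("C", C), ""),
    ifelse(H > 0, paste0("H", H), ""),
    ifelse(N > 0, paste0("N", ifelse(N == 1, "", N)), ""),
    ifelse(O > 0, paste0("O", ifelse(O == 1, "", O)), "")
  )
}

.chain_token <- function(c_, d, h) paste0(c_, ":", d, ";", h)

.enumerate_ceramides <- function(cons) {
  grid <- tidyr::expand_grid(
    linkage = cons$linkages, base = cons$bases,
    lcb_c = cons$lcb_c, fa_c = cons$fa_c, fa_db = cons$fa_db
  )
  grid$lcb_db <- .base_db(grid$base)
  grid$lcb_oh <- .base_oh(grid$base)
  grid$fa_oh <- unname(.LINKAGE_FA_OH[grid$linkage])
  grid <- grid[.valid_chain(grid$lcb_c, grid$lcb_db) & .valid_chain(grid$fa_c, grid$fa_db), ]
  eo <- grid$linkage == "EO"
  non_eo <- grid[!eo, ]
  eo_grid <- tidyr::expand_grid(
    grid[eo, ],
    ester_c = cons$ester_c, ester_db = cons$ester_db
  )
  eo_grid <- eo_grid[.valid_chain(eo_grid$ester_c, eo_grid$ester_db), ]
  non_eo$ester_c <- NA_integer_; non_eo$ester_db <- NA_integer_
  grid <- dplyr::bind_rows(non_eo, eo_grid)
  if (nrow(grid) == 0) return(tibble())

  grid$cls <- paste0(grid$linkage, grid$base)

  lcb <- .lcb_elements(grid$lcb_c, grid$lcb_db, grid$lcb_oh)
  fa <- .fa_elements(grid$fa_c, grid$fa_db, grid$fa_oh)
  C <- lcb$C + fa$C; H <- lcb$H + fa$H - 2; N <- lcb$N + fa$N; O <- lcb$O + fa$O - 1
  is_eo <- grid$linkage == "EO"
  ec <- ifelse(is_eo, grid$ester_c, 0L); ed <- ifelse(is_eo, grid$ester_db, 0L)
  est <- .fa_elements(ec, ed, 0)
  C <- C + ifelse(is_eo, est$C, 0)
  H <- H + ifelse(is_eo, est$H - 2, 0)
  O <- O + ifelse(is_eo, est$O - 1 + 1, 0) # ester bond -H2O, plus omega-O

  chains_txt <- paste0(
    .chain_token(grid$lcb_c, grid$lcb_db, grid$lcb_oh), "–",
    .chain_token(grid$fa_c, grid$fa_db, grid$fa_oh),
    ifelse(is_eo, paste0("–", .chain_token(ec, ed, 0)), "")
  )
  tot_c <- grid$lcb_c + grid$fa_c + ifelse(is_eo, ec, 0L)
  tot_db <- grid$lcb_db + grid$fa_db + ifelse(is_eo, ed, 0L)
  tot_oh <- grid$lcb_oh + grid$fa_oh

  tibble(
    class = grid$cls,
    species = paste0(grid$cls, " ", tot_c, ":", tot_db, ";", tot_oh),
    subspecies = paste0(grid$cls, " ", chains_txt),
    formula = .formula_string(C, H, N, O),
    neutral_mass = .mass_from_elements(C, H, N, O)
  )
}

.enumerate_single_chain <- function(cls, fa_c, fa_db, base_f) {
  grid <- tidyr::expand_grid(fa_c = fa_c, fa_db = fa_db)
  grid <- grid[.valid_chain(grid$fa_c, grid$fa_db), ]
  if (nrow(grid) == 0) return(tibble())
  fa <- .fa_elements(grid$fa_c, grid$fa_db, 0)
  bc <- .as_counts(base_f)
  C <- bc[["C"]] + fa$C; H <- bc[["H"]] + fa$H - 2; O <- bc[["O"]] + fa$O - 1
  tibble(
    class = cls,
    species = paste0(cls, " ", grid$fa_c, ":", grid$fa_db, ";0"),
    subspecies = paste0(cls, " ", .chain_token(grid$fa_c, grid$fa_db, 0)),
    formula = .formula_string(C, H, 0, O),
    neutral_mass = .mass_from_elements(C, H, 0, O)
  )
}

.enumerate_glycerides <- function(cls, fa_c, fa_db, n_chains, total_c = NULL, total_db = NULL) {
  fa <- tidyr::expand_grid(c_ = fa_c, d = fa_db)
  fa <- fa[.valid_chain(fa$c_, fa$d), ]
  if (nrow(fa) == 0) return(tibble())
  # unordered FA multisets with repetition via stars-and-bars index shift
  combs <- utils::combn(seq_len(nrow(fa) + n_chains - 1L), n_chains)
  combs <- combs - (seq_len(n_chains) - 1L)
  tot_c <- rep(0L, ncol(combs)); tot_d <- rep(0L, ncol(combs))
  for (k in seq_len(n_chains)) {
    tot_c <- tot_c + fa$c_[combs[k, ]]
    tot_d <- tot_d + fa$d[combs[k, ]]
  }
  keep <- rep(TRUE, ncol(combs))
  if (!is.null(total_c)) keep <- keep & tot_c >= total_c[1] & tot_c <= total_c[2]
  if (!is.null(total_db)) keep <- keep & tot_d >= total_db[1] & tot_d <= total_db[2]
  combs <- combs[, keep, drop = FALSE]
  tot_c <- tot_c[keep]; tot_d <- tot_d[keep]
  if (ncol(combs) == 0) return(tibble())
  # element sums
  C <- 3 + tot_c; H <- 8 - 2 * n_chains + (2 * tot_c - 2 * tot_d)
  O <- 3 - n_chains + 2 * n_chains
  chains_txt <- apply(combs, 2, function(ix) {
    ord <- ix[order(fa$c_[ix], fa$d[ix])]
    paste0(.chain_token(fa$c_[ord], fa$d[ord], 0), collapse = "–")
  })
  tibble(
    class = cls,
    species = paste0(cls, " ", tot_c, ":", tot_d, ";0"),
    subspecies = paste0(cls, " ", chains_txt),
    formula = .formula_string(C, H, 0, O),
    neutral_mass = .mass_from_elements(C, H, 0, O)
  )
}

#' Enumerate candidate lipid species under constraints
#'
#' Builds the combinatorial candidate space: for each ceramide subclass the
#' Cartesian product of allowed LCB and FA (and, for EO classes, ester FA)
#' chains; FA combinations for CE/DAG/TAG; cholesterol as its acetate
#' derivative. Each candidate carries its neutral formula, monoisotopic mass
#' and adduct m/z.
#'
#' @param constraints An [default_constraints()] list.
#' @param classes Class codes to enumerate (default: all 16).
#' @return A tibble with columns `class`, `species`, `subspecies`, `formula`,
#'   `neutral_mass`, `adduct`, `polarity`, `mz`, deduplicated on
#'   (`class`, `subspecies`).
#' @export
enumerate_species <- function(constraints = default_constraints(),
                              classes = lipid_classes()$code) {
  cons <- constraints
  tbl <- lipid_classes()
  bad <- setdiff(classes, tbl$code)
  if (length(bad) > 0) abort(paste0("unknown class code(s): ", paste(bad, collapse = ", ")))

  pieces <- list()
  cer_classes <- intersect(classes, tbl$code[tbl$category == "ceramide"])
  if (length(cer_classes) > 0) {
    sub_tbl <- tbl[match(cer_classes, tbl$code), ]
    cons_cer <- cons
    cons_cer$linkages <- intersect(cons$linkages, unique(sub_tbl$linkage))
    cons_cer$bases <- intersect(cons$bases, unique(sub_tbl$base))
    cer <- .enumerate_ceramides(cons_cer)
    if (nrow(cer) > 0) cer <- cer[cer$class %in% cer_classes, ]
    pieces <- c(pieces, list(cer))
  }
  if ("CE" %in% classes) {
    pieces <- c(pieces, list(
      .enumerate_single_chain("CE", cons$ce_fa_c, cons$ce_fa_db, .F_CHOLESTEROL())
    ))
  }
  if ("DAG" %in% classes) {
    pieces <- c(pieces, list(
      .enumerate_glycerides("DAG", cons$dag_fa_c, cons$dag_fa_db, 2L, cons$dag_total_c)
    ))
  }
  if ("TAG" %in% classes) {
    pieces <- c(pieces, list(
      .enumerate_glycerides("TAG", cons$tag_fa_c, cons$tag_fa_db, 3L,
                            cons$tag_total_c, cons$tag_total_db)
    ))
  }
  if ("Chol" %in% classes) {
    f <- species_formula("Chol")
    pieces <- c(pieces, list(tibble(
      class = "Chol", species = "Chol", subspecies = "Chol",
      formula = format(f), neutral_mass = monoisotopic_mass(f)
    )))
  }
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    return(tibble(class = character(), species = character(), subspecies = character(),
                  formula = character(), neutral_mass = numeric(), adduct = character(),
                  polarity = character(), mz = numeric()))
  }
  out <- dplyr::distinct(out, .data$class, .data$subspecies, .keep_all = TRUE)
  out$adduct <- tbl$adduct[match(out$class, tbl$code)]
  out$polarity <- tbl$ion_mode[match(out$class, tbl$code)]
  out$mz <- ifelse(
    out$adduct == "acetate",
    adduct_mz(out$neutral_mass, "acetate"),
    adduct_mz(out$neutral_mass, "ammonium")
  )
  dplyr::arrange(out, .data$polarity, .data$mz)
}

#' Build a precursor inclusion (target) list
#'
#' One m/z window of half-width `window_halfwidth` per candidate precursor;
#' overlapping windows of the same polarity are merged, preserving coverage.
#'
#' @param species Tibble from [enumerate_species()] (needs `mz`, `polarity`,
#'   `subspecies`).
#' @param window_halfwidth Half-width in Da (> 0).
#' @return A tibble `mz_low`, `mz_high`, `polarity`, `n_species`, `species`
#'   (list-column of covered subspecies names), sorted by polarity and m/z.
#' @export
build_target_list <- function(species, window_halfwidth = 0.5) {
  if (window_halfwidth <= 0) abort("window_halfwidth must be positive")
  stopifnot(all(c("mz", "polarity") %in% names(species)))
  key <- if ("subspecies" %in% names(species)) species$subspecies else as.character(seq_len(nrow(species)))
  df <- tibble(mz = species$mz, polarity = species$polarity, key = key)
  df <- dplyr::arrange(df, .data$polarity, .data$mz)
  out <- df |>
    dplyr::group_by(.data$polarity) |>
    dplyr::group_modify(function(g, ...) {
      lo <- g$mz - window_halfwidth
      hi <- g$mz + window_halfwidth
      grp <- cumsum(c(1, as.integer(lo[-1] > cummax(hi[-length(hi)]))))
      tibble(
        mz_low = tapply(lo, grp, min),
        mz_high = tapply(hi, grp, max),
        n_species = as.integer(table(grp)),
        species = unname(split(g$key, grp))
      )
    }) |>
    dplyr::ungroup()
  dplyr::arrange(out, .data$polarity, .data$mz_low)
}

.rules_env <- new.env(parent = emptyenv())
.frag_cache <- new.env(parent = emptyenv())

#' The MSMS fragment-rule table
#'
#' Per-class diagnostic fragment templates shipped as editable delimited text
#' (`inst/extdata/fragment_rules.tsv`). These are package-authored defaults
#' following standard shotgun fragmentation chemistry: deprotonated,
#' dehydrated sphingoid base (LCB-diagnostic; separates the NP/AdS and NH/AS
#' isobaric pairs), fatty-acid carboxylate anions (FA- and esterFA-
#' diagnostic), ammonium-adduct fatty-acid neutral losses for DAG/TAG, and
#' the cholestadienyl cation for CE and derivatized cholesterol.
#'
#' Template semantics: `mode = chain_ion` applies the signed element `delta`
#' to the free-chain formula of `chain_role` and charges it per `polarity`;
#' `mode = neutral_loss` subtracts (chain formula + `delta`) from the
#' precursor m/z; `mode = fixed_ion` charges the composition in `delta`
#' directly.
#'
#' @param path Optional path to an alternative rule table.
#' @return A tibble.
#' @export
fragment_rules <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.rules_env$tbl)) {
      p <- system.file("extdata", "fragment_rules.tsv", package = "skinlipidr")
      .rules_env$tbl <- readr::read_tsv(p, col_types = readr::cols(
        cls = "c", kind = "c", chain_role = "c", mode = "c", delta = "c",
        polarity = "c", required = "i", quant = "i"
      ), progress = FALSE)
    }
    return(.rules_env$tbl)
  }
  readr::read_tsv(path, col_types = readr::cols(
    cls = "c", kind = "c", chain_role = "c", mode = "c", delta = "c",
    polarity = "c", required = "i", quant = "i"
  ), progress = FALSE)
}

#' Expected diagnostic fragments of a chain-resolved species
#'
#' @param subspecies A chain-resolved name (e.g. `"NS 18:1;2-24:0;0"`) or the
#'   result of [parse_subspecies_name()].
#' @param rules Fragment-rule table ([fragment_rules()]).
#' @param precursor_mz Precursor m/z (required for neutral-loss rules; when
#'   omitted it is computed from the class adduct).
#' @return A tibble `kind`, `chain_role`, `chain`, `mz`, `polarity`,
#'   `required`, `quant`; one row per (rule, chain) instance, deduplicated on
#'   identical m/z within a kind.
#' @export
expected_fragments <- function(subspecies, rules = fragment_rules(), precursor_mz = NULL) {
  # memoize on the default rule table (fragments are pure in the species)
  cache_key <- NULL
  if (is.character(subspecies) && identical(rules, .rules_env$tbl)) {
    cache_key <- paste0(subspecies, "@",
                        if (is.null(precursor_mz)) "t" else sprintf("%.6f", precursor_mz))
    hit <- .frag_cache[[cache_key]]
    if (!is.null(hit)) return(hit)
  }
  sub <- if (is.character(subspecies)) parse_subspecies_name(subspecies) else subspecies
  r <- rules[rules$cls == sub$cls, ]
  if (nrow(r) == 0) abort(paste0("no fragment rules for class '", sub$cls, "'"))
  if (is.null(precursor_mz)) {
    row <- .class_row(sub$cls)
    precursor_mz <- adduct_mz(monoisotopic_mass(species_formula(sub$cls, sub$chains)), row$adduct)
  }
  out <- purrr::pmap(r, function(cls, kind, chain_role, mode, delta, polarity, required, quant) {
    dl <- .parse_delta(delta)
    if (mode == "fixed_ion") {
      f <- .formula_shift(el_formula(), dl)
      mz <- monoisotopic_mass(f) + ifelse(polarity == "-", .ELECTRON_MASS, -.ELECTRON_MASS)
      return(tibble(kind = kind, chain_role = chain_role, chain = NA_character_,
                    mz = mz, polarity = polarity,
                    required = required == 1, quant = quant == 1))
    }
    ch <- sub$chains[sub$chains$role == chain_role, , drop = FALSE]
    if (nrow(ch) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(ch)), function(i) {
      cf <- chain_formula(ch[i, ])
      if (mode == "chain_ion") {
        f <- .formula_shift(cf, dl)
        mz <- monoisotopic_mass(f) + ifelse(polarity == "-", .ELECTRON_MASS, -.ELECTRON_MASS)
      } else if (mode == "neutral_loss") {
        loss <- monoisotopic_mass(cf) + monoisotopic_mass(.formula_shift(el_formula(), dl))
        mz <- precursor_mz - loss
      } else {
        abort(paste0("unknown fragment rule mode: '", mode, "'"))
      }
      tibble(kind = kind, chain_role = chain_role,
             chain = .chain_token(ch$C[i], ch$DB[i], ch$OH[i]),
             mz = mz, polarity = polarity,
             required = required == 1, quant = quant == 1)
    })
  })
  out <- dplyr::bind_rows(out)
  out <- dplyr::distinct(out, .data$kind, .data$chain, .data$mz, .keep_all = TRUE)
  if (!is.null(cache_key)) .frag_cache[[cache_key]] <- out
  out
}

#' Audit precursor ambiguity within a ppm window
#'
#' Groups candidates whose precursor m/z fall within `ppm` of each other
#' (same polarity) and checks whether every co-falling pair is separable by
#' at least one diagnostic fragment; inseparable pairs are returned as the
#' ambiguity log.
#'
#' @param db Tibble from [enumerate_species()].
#' @param ppm Window in ppm (default 3, the lock-mass MS gate).
#' @param rules Fragment-rule table.
#' @return A tibble of inseparable pairs (empty when all pairs separable).
#' @export
audit_ambiguity <- function(db, ppm = 3, rules = fragment_rules()) {
  db <- dplyr::arrange(db, .data$polarity, .data$mz)
  frag_key <- function(sub) {
    fr <- expected_fragments(sub, rules)
    paste(sort(round(fr$mz, 4)), collapse = "|")
  }
  out <- list()
  for (pol in unique(db$polarity)) {
    d <- db[db$polarity == pol, ]
    if (nrow(d) < 2) next
    grp <- cumsum(c(1, as.integer(diff(d$mz) / d$mz[-1] * 1e6 > ppm)))
    for (g in unique(grp[duplicated(grp)])) {
      members <- d[grp == g, ]
      keys <- vapply(members$subspecies, frag_key, character(1))
      for (i in seq_len(nrow(members) - 1)) {
        for (j in seq(i + 1, nrow(members))) {
          if (keys[i] == keys[j]) {
            out[[length(out) + 1]] <- tibble(
              subspecies_a = members$subspecies[i],
              subspecies_b = members$subspecies[j],
              mz = members$mz[i], polarity = pol
            )
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(subspecies_a = character(), subspecies_b = character(),
                  mz = numeric(), polarity = character()))
  }
  dplyr::bind_rows(out)
}
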