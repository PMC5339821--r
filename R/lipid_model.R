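# Lipid identity grammar and chain chemistry.
#
# Species are written "<class> <C>:<DB>;<OH>" (sum composition over all
# chains); subspecies append the chain-resolved composition, LCB first for
# ceramides, e.g. "NS 18:1;2-24:0;0". Twelve ceramide subclasses arise from
# linkage {N, A, EO} x sphingoid base {dS, S, P, H}; the remaining classes
# are CE, DAG, TAG and cholesterol (measured as its acetate derivative).

# Sphingoid-base convention: the base type fixes the LCB's (double bonds,
# hydroxyls). This table is the single place that convention lives.
.BASE_TABLE <- c(dS = "0,2", S = "1,2", P = "0,3", H = "1,3")

.base_db <- function(base) as.integer(sub(",.*", "", .BASE_TABLE[base]))
.base_oh <- function(base) as.integer(sub(".*,", "", .BASE_TABLE[base]))

# FA hydroxylation fixed by ceramide linkage: non-hydroxy N = 0,
# alpha-hydroxy A = 1. EO amide FAs are omega-hydroxylated, but that hydroxyl
# is consumed by the ester bond and by convention NOT counted in the written
# ";OH" sum ("EOS 68:3;2" has OH = 2 from the base alone); the chemistry adds
# the extra oxygen in species_formula().
.LINKAGE_FA_OH <- c(N = 0, A = 1, EO = 0)

.class_table_env <- new.env(parent = emptyenv())

#' The lipid class definition table
#'
#' One row per covered class: code, category (ceramide/neutral/sterol),
#' number of chains, adduct and ion mode, and for ceramides the linkage/base
#' decomposition of the code. Shipped as editable delimited text in
#' `inst/extdata/class_definitions.tsv`.
#'
#' @return A tibble with 16 rows.
#' @export
lipid_classes <- function() {
  if (is.null(.class_table_env$tbl)) {
    path <- system.file("extdata", "class_definitions.tsv", package = "skinlipidr")
    tbl <- readr::read_tsv(path, col_types = readr::cols(
      code = "c", category = "c", n_chains = "i", adduct = "c",
      ion_mode = "c", linkage = "c", base = "c"
    ), na = "NA", progress = FALSE)
    .class_table_env$tbl <- tbl
  }
  .class_table_env$tbl
}

.class_row <- function(cls) {
  tbl <- lipid_classes()
  i <- match(cls, tbl$code)
  if (is.na(i)) abort(paste0("unknown lipid class code: '", cls, "'"))
  tbl[i, ]
}

#' Is a class code a ceramide subclass?
#' @param cls Class code(s).
#' @return Logical vector.
#' @export
is_ceramide <- function(cls) {
  cls %in% lipid_classes()$code[lipid_classes()$category == "ceramide"]
}

# ---- chains -----------------------------------------------------------------

#' Construct a chain record
#'
#' @param role `"LCB"` (sphingoid base, carries the nitrogen), `"FA"`
#'   (amide-linked or glycero-linked fatty acid) or `"esterFA"` (the
#'   ester-linked FA of EO ceramides).
#' @param C,DB,OH Carbons (>= 2), double bonds, hydroxyls.
#' @return A one-row tibble.
#' @export
chain <- function(role, C, DB, OH) {
  role <- match.arg(role, c("LCB", "FA", "esterFA"))
  if (C < 2) abort("chain must have at least 2 carbons")
  if (DB < 0 || OH < 0) abort("DB and OH must be non-negative")
  tibble(role = role, C = as.integer(C), DB = as.integer(DB), OH = as.integer(OH))
}

#' Elemental formula of a free chain
#'
#' Free fatty acid c:d;h gives C_c H_(2c-2d) O_(2+h); a sphingoid base c:d;h
#' gives C_c H_(2c+3-2d) N O_h (h counts all hydroxyls on the base).
#' Chains whose unsaturation cannot be accommodated by the carbon skeleton
#' are rejected.
#'
#' @param ch A chain tibble row from [chain()].
#' @return An `el_formula` (of the free acid / free base).
#' @examples
#' chain_formula(chain("FA", 16, 0, 0))  # palmitic acid, C16H32O2
#' chain_formula(chain("LCB", 18, 1, 2)) # sphingosine, C18H37NO2
#' @export
chain_formula <- function(ch) {
  stopifnot(nrow(ch) == 1)
  c_ <- ch$C; d <- ch$DB; h <- ch$OH
  # a linear chain of c carbons (one being the carboxyl/C1) can host at most
  # floor((c-1)/2) C=C double bonds
  if (d > floor((c_ - 1) / 2)) {
    abort(paste0("over-unsaturated chain: ", c_, ":", d, " is chemically impossible"))
  }
  if (ch$role == "LCB") {
    n_h <- 2 * c_ + 3 - 2 * d
    if (n_h < 0) abort("over-unsaturated chain: negative hydrogen count")
    el_formula(C = c_, H = n_h, N = 1, O = h)
  } else {
    n_h <- 2 * c_ - 2 * d
    if (n_h < 0) abort("over-unsaturated chain: negative hydrogen count")
    el_formula(C = c_, H = n_h, O = 2 + h)
  }
}

.F_H2O <- function() el_formula(H = 2, O = 1)
.F_GLYCEROL <- function() el_formula(C = 3, H = 8, O = 3)
.F_CHOLESTEROL <- function() el_formula(C = 27, H = 46, O = 1)

#' Neutral elemental formula of a (sub)species
#'
#' Condensation chemistry per class: ceramide = LCB + FA - H2O (amide bond);
#' EO ceramide additionally gains the esterified omega-hydroxyl oxygen (not
#' counted in the written OH sum) and loses one more H2O for the ester bond;
#' CE = cholesterol + FA - H2O; DAG/TAG = glycerol + 2/3 FA - 2/3 H2O;
#' cholesterol is modelled as its acetate derivative (cholesterol + C2H2O),
#' the form in which it is acquired.
#'
#' @param cls Class code.
#' @param chains Tibble of chains (rows from [chain()]), LCB first for
#'   ceramides. Ignored for `Chol`.
#' @return An `el_formula` of the neutral species.
#' @export
species_formula <- function(cls, chains = NULL) {
  row <- .class_row(cls)
  if (cls == "Chol") {
    return(formula_add(.F_CHOLESTEROL(), el_formula(C = 2, H = 2, O = 1)))
  }
  if (is.null(chains) || nrow(chains) != row$n_chains) {
    abort(paste0(cls, " requires exactly ", row$n_chains, " chains"))
  }
  if (row$category == "ceramide") {
    if (chains$role[1] != "LCB") abort("first chain of a ceramide must be the LCB")
    f <- formula_subtract(
      formula_add(chain_formula(chains[1, ]), chain_formula(chains[2, ])),
      .F_H2O()
    )
    if (row$linkage == "EO") {
      if (chains$role[3] != "esterFA") abort("third chain of an EO ceramide must be the esterFA")
      # omega-hydroxyl oxygen of the amide FA, unnamed in the OH sum
      f <- formula_add(f, el_formula(O = 1))
      f <- formula_subtract(formula_add(f, chain_formula(chains[3, ])), .F_H2O())
    }
    return(f)
  }
  if (cls == "CE") {
    return(formula_subtract(formula_add(.F_CHOLESTEROL(), chain_formula(chains[1, ])), .F_H2O()))
  }
  # DAG / TAG
  f <- .F_GLYCEROL()
  for (i in seq_len(nrow(chains))) {
    f <- formula_subtract(formula_add(f, chain_formula(chains[i, ])), .F_H2O())
  }
  f
}

# ---- name grammar -----------------------------------------------------------

.CHAIN_RE <- "([0-9]+):([0-9]+)(?:;([0-9]+))?"

#' Parse a species name, e.g. "EOS 70:3;2"
#'
#' The grammar is `<class> <C>:<DB>;<OH>`; the `;OH` part may be omitted for
#' classes where hydroxylation is structurally fixed (CE, DAG, TAG). The bare
#' class code `"Chol"` names cholesterol.
#'
#' @param name Character scalar.
#' @return A one-row tibble: `cls`, `C`, `DB`, `OH`.
#' @export
parse_species_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  name <- trimws(name)
  if (name %in% lipid_classes()$code[lipid_classes()$n_chains == 0]) {
    return(tibble(cls = name, C = 0L, DB = 0L, OH = 0L))
  }
  m <- regexec(paste0("^(\\S+)\\s+", .CHAIN_RE, "$"), name)
  parts <- regmatches(name, m)[[1]]
  if (length(parts) == 0) {
    abort(paste0("malformed species name: '", name, "' (expected '<class> <C>:<DB>;<OH>')"))
  }
  cls <- parts[2]
  if (!cls %in% lipid_classes()$code) {
    abort(paste0("unknown lipid class code: '", cls, "'"))
  }
  oh <- if (parts[5] == "") {
    if (is_ceramide(cls)) abort(paste0("species name '", name, "' is missing the ';<OH>' field"))
    0L
  } else {
    as.integer(parts[5])
  }
  tibble(cls = cls, C = as.integer(parts[3]), DB = as.integer(parts[4]), OH = oh)
}

#' Format a species key as its canonical name
#' @param cls,C,DB,OH Species key fields.
#' @return Character scalar, e.g. `"NS 36:1;2"`.
#' @export
format_species_name <- function(cls, C, DB, OH) {
  zero_chain <- lipid_classes()$n_chains[match(cls, lipid_classes()$code)] == 0
  ifelse(zero_chain, cls, paste0(cls, " ", C, ":", DB, ";", OH))
}

.split_chain_tokens <- function(x) {
  # accept en-dash (paper's separator) and ASCII hyphen
  strsplit(x, "–|-", fixed = FALSE)[[1]]
}

.parse_chain_token <- function(tok, role) {
  m <- regexec(paste0("^", .CHAIN_RE, "$"), trimws(tok))
  parts <- regmatches(tok, m)[[1]]
  if (length(parts) == 0) abort(paste0("malformed chain token: '", tok, "'"))
  oh <- if (parts[4] == "") 0L else as.integer(parts[4])
  chain(role, as.integer(parts[2]), as.integer(parts[3]), oh)
}

#' Parse a chain-resolved (subspecies) name
#'
#' Accepts either a full name (`"NS 18:1;2-24:0;0"`) or a bare chain list
#' (`"18:1;2-24:0;0"`) plus the class. Chain tokens may be separated by an
#' en-dash (as printed) or an ASCII hyphen. For ceramides the first token is
#' the LCB, then the amide FA, then (EO classes) the ester FA.
#'
#' @param name Character scalar.
#' @param cls Class code; required when `name` is a bare chain list.
#' @return A list with `cls`, `chains` (tibble), `species` (parent name) and
#'   `subspecies` (canonical chain-resolved name).
#' @export
parse_subspecies_name <- function(name, cls = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  name <- trimws(name)
  if (grepl("^[A-Za-z]", name)) {
    cls <- sub("\\s.*$", "", name)
    name <- trimws(sub("^\\S+\\s*", "", name))
  }
  if (is.null(cls)) abort("class code required to parse a bare chain list")
  row <- .class_row(cls)
  if (row$n_chains == 0) {
    return(list(cls = cls, chains = chain("FA", 2, 0, 0)[0, ],
                species = cls, subspecies = cls))
  }
  toks <- .split_chain_tokens(name)
  if (length(toks) != row$n_chains) {
    abort(paste0(cls, " requires ", row$n_chains, " chains, got ", length(toks)))
  }
  roles <- if (row$category == "ceramide") {
    c("LCB", "FA", "esterFA")[seq_len(row$n_chains)]
  } else {
    rep("FA", row$n_chains)
  }
  chains <- dplyr::bind_rows(purrr::map2(toks, roles, .parse_chain_token))
  list(
    cls = cls,
    chains = chains,
    species = format_species_name(cls, sum(chains$C), sum(chains$DB), sum(chains$OH)),
    subspecies = format_subspecies_name(cls, chains)
  )
}

#' Format a chain-resolved name canonically (en-dash separated)
#' @param cls Class code.
#' @param chains Chain tibble.
#' @return Character scalar, e.g. `"NS 18:1;2–24:0;0"`.
#' @export
format_subspecies_name <- function(cls, chains) {
  if (nrow(chains) == 0) return(cls)
  paste0(cls, " ", paste0(chains$C, ":", chains$DB, ";", chains$OH, collapse = "–"))
}
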