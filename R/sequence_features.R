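#' @name sequence_features
#' @title Residue-level polarity and charge scoring
#'
#' @description
#' Sequence-only scoring of missense changes. Polarity is a three-level
#' hydrophobicity scale over the 20 standard residues — group 0
#' (hydrophobic: L I F W C M V Y), group 1 (intermediate: P A T G S) and
#' group 2 (polar: H Q R K N E D) — and charge a three-class scheme:
#' positive (R K), negative (E D) and non-charged (everything else,
#' histidine deliberately included among the non-charged). A change of
#' group or class flags a potentially destabilizing substitution.
NULL

.polarity_sets <- list(`0` = strsplit("LIFWCMVY", "")[[1]],
                       `1` = strsplit("PATGS", "")[[1]],
                       `2` = strsplit("HQRKNED", "")[[1]])

.charge_sets <- list(`+` = c("R", "K"), `-` = c("E", "D"),
                     `0` = strsplit("LIFWCMVYPATGSHQN", "")[[1]])

.aa_lookup <- function(sets, aa) {
  out <- rep(NA_character_, length(aa))
  for (lbl in names(sets)) out[aa %in% sets[[lbl]]] <- lbl
  if (anyNA(out)) {
    stop("non-standard residue(s): ", paste(unique(aa[is.na(out)]),
                                            collapse = ", "))
  }
  out
}

#' Parse residue changes written as "E372G"
#'
#' @param x Character vector like `"E372G"` (wild-type residue, 1-based
#'   position, mutant residue).
#' @return Data frame `wild`, `position`, `mutant`.
#' @export
parse_residue_change <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) stop("unparseable residue change: ",
                     paste(x[bad], collapse = ", "))
  data.frame(
    wild = toupper(vapply(m, `[`, character(1), 2)),
    position = as.integer(vapply(m, `[`, character(1), 3)),
    mutant = toupper(vapply(m, `[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
}

#' Polarity groups of a residue change
#'
#' @param wild,mutant One-letter amino acid codes (vectorized), or `wild`
#'   may be a vector of changes like `"E372G"` with `mutant` missing.
#' @return Data frame `wild_group`, `mutant_group` (each in `0`/`1`/`2` as
#'   character) and logical `changed`.
#' @export
polarity_groups <- function(wild, mutant = NULL) {
  if (is.null(mutant)) {
    rc <- parse_residue_change(wild)
    wild <- rc$wild; mutant <- rc$mutant
  }
  wg <- .aa_lookup(.polarity_sets, toupper(wild))
  mg <- .aa_lookup(.polarity_sets, toupper(mutant))
  data.frame(wild_group = wg, mutant_group = mg, changed = wg != mg,
             stringsAsFactors = FALSE)
}

#' Charge classes of a residue change
#'
#' @inheritParams polarity_groups
#' @return Data frame `wild_charge`, `mutant_charge` (each `+`, `-` or `0`)
#'   and logical `changed`.
#' @export
charge_classes <- function(wild, mutant = NULL) {
  if (is.null(mutant)) {
    rc <- parse_residue_change(wild)
    wild <- rc$wild; mutant <- rc$mutant
  }
  wc <- .aa_lookup(.charge_sets, toupper(wild))
  mc <- .aa_lookup(.charge_sets, toupper(mutant))
  data.frame(wild_charge = wc, mutant_charge = mc, changed = wc != mc,
             stringsAsFactors = FALSE)
}

#' Benchmark set of 20 published missense variants
#'
#' Loads the bundled reference set of 20 missense variants with published
#' SIFT and PolyPhen scores, their damaging/non-damaging consensus call and
#' the expected polarity-group and charge-class transitions — useful for
#' validating [classify_variants()], [polarity_groups()] and
#' [charge_classes()] against independent calls.
#'
#' @return Data frame with columns `mutation`, `gene`, `sift`, `polyphen`,
#'   `prediction` (`D`/`ND`), `polarity` (e.g. `"2/1"`), `charge`
#'   (e.g. `"+/-"`).
#' @export
reference_variants <- function() {
  path <- system.file("extdata", "reference_variants_20.tsv",
                      package = "netload")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
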