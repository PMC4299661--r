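#' Parse protein-protein interaction evidence
#'
#' Reads interaction evidence rows from a PSI-MI TAB 2.5 ("MITAB") file or a
#' plain edge-list TSV and returns one record per usable row. Identifiers are
#' treated as opaque accession strings; rows without a usable accession pair
#' are dropped and counted in the attached parse report.
#'
#' For `dialect = "mitab25"` the file must have at least 15 tab-separated
#' columns. Accessions are taken from columns 1-2 (the part after the first
#' `:` of the first identifier, e.g. `uniprotkb:P12345` -> `P12345`), the
#' interaction detection method from column 7, the interaction type from
#' column 12 and the source database from column 13. PSI-MI controlled
#' vocabulary terms written as `psi-mi:MI:0915(physical association)` are
#' reduced to their label; the method *identity* used downstream is the MI
#' identifier when present, else the lowercased free-text label.
#'
#' For `dialect = "edgelist_tsv"` the file has a header row and columns
#' `protein_a`, `protein_b`, `type`, `methods` (semicolon-separated).
#'
#' @param path Path to the input file.
#' @param dialect One of `"mitab25"`, `"edgelist_tsv"`.
#' @param strict If `TRUE`, malformed rows raise an error instead of being
#'   skipped.
#' @return A data frame with columns `protein_a`, `protein_b`,
#'   `interaction_type`, `detection_methods` (list column of character sets)
#'   and `source_db`, with a `parse_report` attribute giving row counts.
#' @export
parse_mitab <- function(path, dialect = c("mitab25", "edgelist_tsv"),
                        strict = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (dialect == "mitab25") {
    lines <- lines[!startsWith(lines, "#")]
    n_rows <- length(lines)
    recs <- lapply(lines, .parse_mitab_row, strict = strict)
  } else {
    if (length(lines) == 0) {
      n_rows <- 0L
      recs <- list()
    } else {
      header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
      body <- lines[-1]
      n_rows <- length(body)
      recs <- lapply(body, .parse_edgelist_row, header = header,
                     strict = strict)
    }
  }
  keep <- !vapply(recs, is.null, logical(1))
  out <- if (any(keep)) do.call(rbind, recs[keep]) else .empty_records()
  out$detection_methods <- lapply(out$detection_methods, unique)
  attr(out, "parse_report") <- list(
    n_rows = n_rows, n_records = sum(keep), n_skipped = sum(!keep)
  )
  out
}

.empty_records <- function() {
  data.frame(
    protein_a = character(), protein_b = character(),
    interaction_type = character(),
    detection_methods = I(list()), source_db = character(),
    stringsAsFactors = FALSE
  )
}

# "psi-mi:MI:0915(physical association)" -> label; bare text passes through
.psimi_label <- function(x) {
  m <- regmatches(x, regexec("\\(([^)]*)\\)", x))[[1]]
  if (length(m) == 2) m[2] else x
}

# method identity: MI accession when present, else lowercased label
.psimi_method_id <- function(x) {
  m <- regmatches(x, regexec("(MI:[0-9]+)", x))[[1]]
  if (length(m) == 2) m[2] else tolower(.psimi_label(x))
}

.first_accession <- function(field) {
  id <- strsplit(field, "|", fixed = TRUE)[[1]][1]
  if (is.na(id) || !nzchar(id) || id == "-") return(NA_character_)
  sub("^[^:]*:", "", id)
}

.parse_mitab_row <- function(line, strict) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 15) {
    if (strict) stop("malformed MITAB row: fewer than 15 columns")
    return(NULL)
  }
  a <- .first_accession(f[1])
  b <- .first_accession(f[2])
  if (is.na(a) || is.na(b)) {
    if (strict) stop("MITAB row without a usable accession pair")
    return(NULL)
  }
  methods <- vapply(strsplit(f[7], "|", fixed = TRUE)[[1]],
                    .psimi_method_id, character(1), USE.NAMES = FALSE)
  data.frame(
    protein_a = a, protein_b = b,
    interaction_type = .psimi_label(f[12]),
    detection_methods = I(list(unique(methods))),
    source_db = .psimi_label(f[13]),
    stringsAsFactors = FALSE
  )
}

.parse_edgelist_row <- function(line, header, strict) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  get <- function(col, default = NA_character_) {
    i <- match(col, header)
    if (is.na(i) || i > length(f)) default else f[i]
  }
  a <- get("protein_a"); b <- get("protein_b")
  if (is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) {
    if (strict) stop("edge-list row without a usable accession pair")
    return(NULL)
  }
  methods <- strsplit(get("methods", ""), ";", fixed = TRUE)[[1]]
  if (length(methods) == 0) methods <- "unspecified"
  data.frame(
    protein_a = a, protein_b = b,
    interaction_type = get("type", "physical association"),
    detection_methods = I(list(unique(tolower(methods)))),
    source_db = get("source_db", "edgelist"),
    stringsAsFactors = FALSE
  )
}

#' Curate interaction evidence into an interactome graph
#'
#' Pools evidence for each unordered protein pair across records (and source
#' databases), then keeps an edge iff the pooled distinct detection methods
#' number at least `min_methods`, at least one pooled record carries an
#' allowed interaction type, and (when a whitelist is given) both accessions
#' are whitelisted. Self-loops are removed. Because methods are pooled as
#' sets, curation is idempotent under record duplication, and raising
#' `min_methods` can only remove edges.
#'
#' @param records Data frame of interaction records as from [parse_mitab()].
#' @param min_methods Minimum number of distinct detection methods per pair.
#' @param allowed_types Character vector of acceptable interaction types; an
#'   edge needs at least one record of an allowed type.
#' @param accession_whitelist Optional character vector; both endpoints must
#'   be members (stands in for restricting to a reviewed accession namespace).
#' @return An undirected, simple `igraph` object whose vertex names are
#'   accessions, with a `curation_report` graph attribute recording kept and
#'   dropped pair counts by reason and the settings used.
#' @export
curate <- function(records, min_methods = 2,
                   allowed_types = "physical association",
                   accession_whitelist = NULL) {
  stopifnot(min_methods >= 1)
  if (nrow(records) == 0) {
    warning("no interaction records supplied; returning empty interactome")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_graph_attr(g, "curation_report", list(
      n_pairs = 0L, kept = 0L, dropped_methods = 0L, dropped_type = 0L,
      dropped_whitelist = 0L, dropped_self_loop = 0L,
      min_methods = min_methods, allowed_types = allowed_types
    ))
    return(g)
  }
  a <- pmin(records$protein_a, records$protein_b)
  b <- pmax(records$protein_a, records$protein_b)
  key <- paste(a, b, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)

  pair_a <- a[match(names(groups), key)]
  pair_b <- b[match(names(groups), key)]
  n_methods <- vapply(groups, function(i) {
    length(unique(unlist(records$detection_methods[i])))
  }, integer(1))
  type_ok <- vapply(groups, function(i) {
    any(records$interaction_type[i] %in% allowed_types)
  }, logical(1))
  self_loop <- pair_a == pair_b
  wl_ok <- if (is.null(accession_whitelist)) rep(TRUE, length(groups)) else {
    pair_a %in% accession_whitelist & pair_b %in% accession_whitelist
  }
  keep <- !self_loop & wl_ok & type_ok & n_methods >= min_methods

  report <- list(
    n_pairs = length(groups),
    kept = sum(keep),
    dropped_self_loop = sum(self_loop),
    dropped_whitelist = sum(!self_loop & !wl_ok),
    dropped_type = sum(!self_loop & wl_ok & !type_ok),
    dropped_methods = sum(!self_loop & wl_ok & type_ok &
                            n_methods < min_methods),
    min_methods = min_methods, allowed_types = allowed_types
  )
  el <- cbind(pair_a[keep], pair_b[keep])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::set_graph_attr(g, "curation_report", report)
}

#' Write an interactome graph to disk
#'
#' `edgelist_tsv` writes a header (`protein_a`, `protein_b`) plus one row per
#' edge; isolated vertices are preserved in a trailing comment-free block by
#' listing them with an empty partner (none are produced by [curate()], which
#' only creates vertices incident to kept edges). `graphml` delegates to
#' igraph's GraphML writer. Files written as `edgelist_tsv` round-trip through
#' [read_graph_tsv()].
#'
#' @param g An `igraph` interactome.
#' @param path Output file path.
#' @param format One of `"edgelist_tsv"`, `"graphml"`.
#' @export
write_graph_file <- function(g, path, format = c("edgelist_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("protein_a\tprotein_b", con)
  if (nrow(el) > 0) {
    writeLines(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read an interactome written as an edge-list TSV
#'
#' @param path File written by [write_graph_file()] with
#'   `format = "edgelist_tsv"`.
#' @return An undirected simple `igraph`.
#' @export
read_graph_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (nrow(df) == 0) return(igraph::make_empty_graph(0, directed = FALSE))
  igraph::simplify(igraph::graph_from_edgelist(
    as.matrix(df[, c("protein_a", "protein_b")]), directed = FALSE))
}
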