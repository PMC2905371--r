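# Readers and writers for the plain-TSV interchange formats: '#'-prefixed
# comment lines, tab separators, no quoting. Parsing is strict on purpose —
# a malformed row is a hard error naming the offending line, never a silent
# drop — because upstream exports (BioGrid-style PPI tables, iPfam/InterDom
# style DDI lists) are easy to truncate or mangle.

# Split a TSV file into fields, keeping 1-based source line numbers so
# errors can point at the file. Blank and '#' lines are skipped.
read_tsv_rows <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

check_ncol <- function(rows, path, min, max = min) {
  nc <- lengths(rows$fields)
  bad <- which(nc < min | nc > max)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d has %d field(s); expected %s.",
                  path, rows$lineno[bad[1]], nc[bad[1]],
                  if (min == max) min else paste(min, "to", max)))
  }
}

#' Read a PPI network from a tab-separated edge list
#'
#' Expects two protein-id columns plus an optional third column carrying the
#' experiment-system label (BioGrid-style). Self loops are dropped, duplicate
#' and reversed edges are collapsed, and rows can be restricted to physical
#' evidence by passing the allowed system labels (e.g. keep only two-hybrid
#' and mass-spectrometry derived interactions).
#'
#' @param path Path to the TSV file; `#` lines are comments.
#' @param experiment_systems Optional character vector; when given, only rows
#'   whose third column is one of these labels are kept.
#'
#' @return A [ppi_network()].
#' @export
read_ppi_network <- function(path, experiment_systems = NULL) {
  rows <- read_tsv_rows(path)
  check_ncol(rows, path, 2, 3)
  a <- map_chr(rows$fields, 1)
  b <- map_chr(rows$fields, 2)
  n_raw <- length(a)
  if (!is.null(experiment_systems)) {
    sys <- map_chr(rows$fields, function(f) if (length(f) >= 3) f[3] else NA_character_)
    keep <- !is.na(sys) & sys %in% experiment_systems
    inform(sprintf("read_ppi_network: %d of %d rows pass the experiment-system filter.",
                   sum(keep), n_raw))
    a <- a[keep]
    b <- b[keep]
  }
  self <- a == b
  if (any(self)) {
    inform(sprintf("read_ppi_network: dropped %d self-loop row(s).", sum(self)))
  }
  if (sum(!self) == 0) {
    abort(paste0(path, ": no usable PPI rows after filtering."))
  }
  net <- ppi_network(tibble(a = a[!self], b = b[!self]))
  dup <- sum(!self) - nrow(net)
  if (dup > 0) {
    inform(sprintf("read_ppi_network: collapsed %d duplicate edge row(s).", dup))
  }
  net
}

#' Read a protein-to-domain annotation table
#'
#' Rows are `(protein id, domain-type id, copy count)`; the count column is
#' optional and defaults to 1. Counts are expanded into copy-indexed domain
#' instances — the units that carry the binding-interface exclusivity
#' constraint — so a protein with `(PF00001, 2)` owns instances
#' `(PF00001, 1)` and `(PF00001, 2)`. Repeated `(protein, type)` rows have
#' their counts summed.
#'
#' @param path Path to the TSV file.
#' @return A `domain_annotation` tibble with columns `protein`,
#'   `domain_type`, `copy`.
#' @export
read_domain_annotation <- function(path) {
  rows <- read_tsv_rows(path)
  if (length(rows$fields) == 0) {
    warn(paste0(path, ": empty domain annotation."))
    return(domain_annotation(tibble(protein = character(),
                                    domain_type = character(),
                                    count = integer())))
  }
  check_ncol(rows, path, 2, 3)
  cnt <- map_chr(rows$fields, function(f) if (length(f) >= 3) f[3] else "1")
  cnt_num <- suppressWarnings(as.integer(cnt))
  bad <- which(is.na(cnt_num) | cnt_num < 1)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d has invalid copy count '%s' (must be an integer >= 1).",
                  path, rows$lineno[bad[1]], cnt[bad[1]]))
  }
  domain_annotation(tibble(protein = map_chr(rows$fields, 1),
                           domain_type = map_chr(rows$fields, 2),
                           count = cnt_num))
}

#' Construct a domain annotation from (protein, domain type, count) rows
#'
#' @param df Data frame with columns `protein`, `domain_type` and optionally
#'   `count` (default 1). Counts for repeated rows are summed, then expanded
#'   into copy indices `1..n`.
#' @return A `domain_annotation` tibble (`protein`, `domain_type`, `copy`).
#' @export
domain_annotation <- function(df) {
  df <- as_tibble(df)
  if (!"count" %in% names(df)) df$count <- 1L
  agg <- df |>
    mutate(protein = as.character(.data$protein),
           domain_type = as.character(.data$domain_type),
           count = as.integer(.data$count)) |>
    group_by(.data$protein, .data$domain_type) |>
    summarise(count = sum(.data$count), .groups = "drop")
  out <- tidyr::uncount(agg, .data$count) |>
    group_by(.data$protein, .data$domain_type) |>
    mutate(copy = row_number()) |>
    ungroup() |>
    arrange(.data$protein, .data$domain_type, .data$copy)
  new_tibble(out, class = "domain_annotation")
}

#' Read or construct a DDI catalog of interacting domain-type pairs
#'
#' The catalog is the universe of potential domain-domain interactions
#' (iPfam/InterDom style): unordered domain-type pairs, homotypic pairs
#' `(d, d)` allowed. Pairs are stored canonically (smaller id first) with
#' duplicates collapsed. An optional third column is kept as a source label.
#'
#' @param path Path to the TSV file.
#' @return A `ddi_catalog` tibble with columns `domain_a`, `domain_b`,
#'   `source`.
#' @export
read_ddi_catalog <- function(path) {
  rows <- read_tsv_rows(path)
  check_ncol(rows, path, 2, 3)
  ddi_catalog(tibble(
    domain_a = map_chr(rows$fields, 1),
    domain_b = map_chr(rows$fields, 2),
    source = map_chr(rows$fields, function(f) if (length(f) >= 3) f[3] else NA_character_)
  ))
}

#' @rdname read_ddi_catalog
#' @param df Data frame with two domain-type columns and an optional
#'   `source` column.
#' @export
ddi_catalog <- function(df) {
  df <- as_tibble(df)
  if (ncol(df) < 2) abort("A DDI catalog needs two domain-type columns.")
  a <- as.character(df[[1]])
  b <- as.character(df[[2]])
  src <- if ("source" %in% names(df)) as.character(df$source) else NA_character_
  out <- tibble(domain_a = pmin(a, b), domain_b = pmax(a, b), source = src) |>
    distinct(.data$domain_a, .data$domain_b, .keep_all = TRUE) |>
    arrange(.data$domain_a, .data$domain_b)
  new_tibble(out, class = "ddi_catalog")
}

#' Read a known-complex catalog
#'
#' One complex per row: a complex id, a tab, then the member proteins as a
#' comma-separated list.
#'
#' @param path Path to the TSV file.
#' @return A `complex_catalog` tibble with columns `complex_id` and
#'   `members` (list of character vectors).
#' @export
read_complex_catalog <- function(path) {
  rows <- read_tsv_rows(path)
  check_ncol(rows, path, 2)
  ids <- map_chr(rows$fields, 1)
  members <- map(strsplit(map_chr(rows$fields, 2), ",", fixed = TRUE),
                 function(m) sort(unique(trimws(m))))
  empty <- which(lengths(members) == 0 | map_lgl(members, function(m) all(m == "")))
  if (length(empty) > 0) {
    abort(sprintf("%s: line %d defines a complex with no members.",
                  path, rows$lineno[empty[1]]))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("%s: duplicated complex id '%s'.", path, ids[duplicated(ids)][1]))
  }
  complex_catalog(tibble(complex_id = ids, members = members))
}

#' @rdname read_complex_catalog
#' @param df Data frame with `complex_id` and a `members` list column.
#' @export
complex_catalog <- function(df) {
  df <- as_tibble(df)
  stopifnot(all(c("complex_id", "members") %in% names(df)))
  df$members <- lapply(df$members, function(m) sort(unique(as.character(m))))
  if (any(lengths(df$members) == 0)) abort("Complexes must have at least one member.")
  if (anyDuplicated(df$complex_id)) abort("Complex ids must be unique.")
  new_tibble(df, class = "complex_catalog")
}

go_unknown_terms <- c("GO:0003674", "GO:0005554")

#' Read a molecular-function GO annotation table
#'
#' Rows are `(gene id, GO term id, aspect)`. Only molecular-function rows
#' (aspect `F`, `MF`, `Function` or `molecular_function`) are kept; when the
#' aspect column is absent every row is treated as molecular function. Term
#' ids must look like `GO:` followed by seven digits. The terms GO:0003674
#' and GO:0005554 denote "molecular function unknown" and mark a protein as
#' uncharacterized.
#'
#' @param path Path to the TSV file.
#' @return A `go_annotation` tibble with columns `gene`, `term`.
#' @export
read_go_annotation <- function(path) {
  rows <- read_tsv_rows(path)
  if (length(rows$fields) == 0) {
    warn(paste0(path, ": empty GO annotation."))
    return(go_annotation(tibble(gene = character(), term = character())))
  }
  check_ncol(rows, path, 2, 3)
  term <- map_chr(rows$fields, 2)
  bad <- which(!grepl("^GO:\\d{7}$", term))
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d has malformed GO term id '%s'.",
                  path, rows$lineno[bad[1]], term[bad[1]]))
  }
  aspect <- map_chr(rows$fields, function(f) if (length(f) >= 3) f[3] else "F")
  keep <- aspect %in% c("F", "MF", "Function", "molecular_function")
  go_annotation(tibble(gene = map_chr(rows$fields, 1)[keep], term = term[keep]))
}

#' @rdname read_go_annotation
#' @param df Data frame with columns `gene` and `term`.
#' @export
go_annotation <- function(df) {
  df <- as_tibble(df)
  out <- tibble(gene = as.character(df$gene), term = as.character(df$term)) |>
    distinct() |>
    arrange(.data$gene, .data$term)
  new_tibble(out, class = "go_annotation")
}

#' Write and re-read verified complexes
#'
#' Serializes verified complexes — members, active PPI edges, and active DDI
#' edges with their domain instances — as a line-typed TSV that round-trips
#' exactly through [read_verified_complexes()]. Line types: `C` (complex id,
#' solver objective, source candidate), `M` (member), `P` (active PPI), `D`
#' (active DDI with both domain instances).
#'
#' @param complexes A verified-complex tibble as produced by [verify_all()]
#'   or [extract_verified()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_verified_complexes <- function(complexes, path) {
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(paste0("Cannot open for writing: ", path))
  })
  on.exit(close(con))
  writeLines("# ddicomplex verified complexes v1", con)
  for (i in seq_len(nrow(complexes))) {
    r <- complexes[i, ]
    writeLines(sprintf("C\t%s\t%d\t%s", r$complex_id, r$objective,
                       r$source_candidate), con)
    writeLines(sprintf("M\t%s\t%s", r$complex_id, sort(r$members[[1]])), con)
    p <- r$ppi_edges[[1]]
    if (nrow(p) > 0) {
      writeLines(sprintf("P\t%s\t%s\t%s", r$complex_id, p$protein_a, p$protein_b), con)
    }
    d <- r$ddi_edges[[1]]
    if (nrow(d) > 0) {
      writeLines(sprintf("D\t%s\t%s\t%s\t%d\t%s\t%s\t%d", r$complex_id,
                         d$protein_i, d$domain_i, d$copy_i,
                         d$protein_j, d$domain_j, d$copy_j), con)
    }
  }
  invisible(path)
}

#' @rdname write_verified_complexes
#' @export
read_verified_complexes <- function(path) {
  rows <- read_tsv_rows(path)
  tag <- map_chr(rows$fields, 1)
  bad <- which(!tag %in% c("C", "M", "P", "D"))
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d has unknown record type '%s'.",
                  path, rows$lineno[bad[1]], tag[bad[1]]))
  }
  cx <- rows$fields[tag == "C"]
  ids <- map_chr(cx, 2)
  get_for <- function(type, id) {
    Filter(function(f) f[2] == id, rows$fields[tag == type])
  }
  out <- map(seq_along(ids), function(k) {
    id <- ids[k]
    mem <- sort(map_chr(get_for("M", id), 3))
    pp <- get_for("P", id)
    dd <- get_for("D", id)
    tibble(
      complex_id = id,
      members = list(mem),
      n_proteins = length(mem),
      objective = as.integer(cx[[k]][3]),
      source_candidate = cx[[k]][4],
      ppi_edges = list(tibble(protein_a = map_chr(pp, 3),
                              protein_b = map_chr(pp, 4))),
      ddi_edges = list(tibble(protein_i = map_chr(dd, 3),
                              domain_i = map_chr(dd, 4),
                              copy_i = as.integer(map_chr(dd, 5)),
                              protein_j = map_chr(dd, 6),
                              domain_j = map_chr(dd, 7),
                              copy_j = as.integer(map_chr(dd, 8)))))
  })
  if (length(out) == 0) empty_verified() else bind_rows(out)
}

empty_verified <- function() {
  tibble(complex_id = character(), members = list(), n_proteins = integer(),
         objective = integer(), source_candidate = character(),
         ppi_edges = list(), ddi_edges = list())
}
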