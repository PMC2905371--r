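#' Pipeline configuration
#'
#' Collects every knob of the two-step pipeline in one validated object.
#' Defaults follow the tuned values for yeast BioGrid data: MCL inflation
#' 3.6, clustering-coefficient threshold 0.4, minimum complex size 3, and
#' overlap-match threshold 0.25.
#'
#' @param ppi Path to the PPI edge-list TSV (required).
#' @param domains Path to the protein-domain annotation TSV (required).
#' @param ddis Path to the DDI catalog TSV (required).
#' @param known Optional path to a known-complex catalog; enables the
#'   precision/recall report.
#' @param go Optional path to a GO molecular-function table; enables the
#'   same-function ratio and function suggestions.
#' @param method Candidate generation: `"mcl"`, `"cc"`, or `"import"`.
#' @param clusters Cluster file path (required for `method = "import"`).
#' @param inflation MCL inflation. Default 3.6.
#' @param cc_threshold Clustering-coefficient threshold. Default 0.4.
#' @param min_size Minimum verified complex size. Default 3.
#' @param v_threshold Overlap-score match threshold (strict). Default 0.25.
#' @param out_dir Output directory.
#' @param experiment_systems Optional allowed experiment-system labels for
#'   the PPI reader.
#' @param seed Integer seed (the pipeline itself is deterministic; the seed
#'   is recorded and forwarded to anything stochastic). Default 1.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ppi, domains, ddis, known = NULL, go = NULL,
                            method = c("mcl", "cc", "import"),
                            clusters = NULL, inflation = 3.6,
                            cc_threshold = 0.4, min_size = 3,
                            v_threshold = 0.25, out_dir = "ddicomplex_out",
                            experiment_systems = NULL, seed = 1) {
  method <- match.arg(method)
  if (method == "import" && is.null(clusters)) {
    abort("method = \"import\" needs a `clusters` file.")
  }
  if (inflation <= 1) abort("`inflation` must be > 1.")
  if (cc_threshold < 0 || cc_threshold > 1) abort("`cc_threshold` must be in [0, 1].")
  if (min_size < 1) abort("`min_size` must be >= 1.")
  structure(list(ppi = ppi, domains = domains, ddis = ddis, known = known,
                 go = go, method = method, clusters = clusters,
                 inflation = inflation, cc_threshold = cc_threshold,
                 min_size = min_size, v_threshold = v_threshold,
                 out_dir = out_dir, experiment_systems = experiment_systems,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a flat key-value configuration file
#'
#' `key = value` lines mirroring the [pipeline_config()] arguments;
#' `#` lines are comments. Values given in `...` (e.g. from command-line
#' flags) override the file.
#'
#' @param path Config file path.
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2)
  if (length(bad) > 0) {
    abort(sprintf("%s: cannot parse config line %d.", path, bad[1]))
  }
  vals <- as.list(map_chr(kv, 2))
  names(vals) <- trimws(map_chr(kv, 1))
  numeric_keys <- c("inflation", "cc_threshold", "min_size", "v_threshold", "seed")
  for (k in intersect(names(vals), numeric_keys)) {
    vals[[k]] <- as.numeric(vals[[k]])
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full prediction pipeline
#'
#' Reads the inputs, extracts candidate complexes (step 1), verifies them by
#' DDI binding-model optimization (step 2), and — when a known-complex
#' catalog or GO table is supplied — evaluates the output. All artifacts are
#' written under `config$out_dir`: `candidates.txt` (importable cluster
#' file), `verified_complexes.tsv`, `per_candidate.tsv`, `summary.tsv`, and
#' optionally `evaluation.tsv`, `same_function.tsv` and `suggestions.tsv`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`candidates`,
#'   `verification`, `evaluation`, `same_function_ratio`, `suggestions`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  network <- read_ppi_network(config$ppi, config$experiment_systems)
  domains <- read_domain_annotation(config$domains)
  ddis <- read_ddi_catalog(config$ddis)
  inform(sprintf("pipeline: %d proteins, %d PPIs, %d domain instances, %d DDI type pairs",
                 length(network_proteins(network)), nrow(network),
                 nrow(domains), nrow(ddis)))

  candidates <- switch(config$method,
    mcl = mcl_cluster(network, inflation = config$inflation),
    cc = cc_cluster(network, threshold = config$cc_threshold),
    import = import_clusters(config$clusters, network)
  )
  inform(sprintf("pipeline: %d candidate clusters (%s)", nrow(candidates),
                 config$method))

  res <- verify_all(candidates, network, domains, ddis,
                    min_size = config$min_size)
  inform(sprintf("pipeline: %d verified complexes (reduction %.1f%%)",
                 res$summary$n_verified, 100 * res$summary$reduction_rate))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(map_chr(candidates$members, paste, collapse = "\t"),
             file.path(config$out_dir, "candidates.txt"))
  write_verified_complexes(res$verified,
                           file.path(config$out_dir, "verified_complexes.tsv"))
  write_tsv_table(res$per_candidate, file.path(config$out_dir, "per_candidate.tsv"))
  write_tsv_table(res$summary, file.path(config$out_dir, "summary.tsv"))

  evaluation <- NULL
  sfr <- NULL
  suggestions <- NULL
  if (!is.null(config$known)) {
    known <- read_complex_catalog(config$known)
    evaluation <- precision_recall(res$verified, known,
                                   threshold = config$v_threshold)
    write_tsv_table(glance(evaluation), file.path(config$out_dir, "evaluation.tsv"))
    print(evaluation)
  }
  if (!is.null(config$go)) {
    go <- read_go_annotation(config$go)
    sfr <- same_function_ratio(res$verified, go)
    write_tsv_table(tibble(same_function_ratio = sfr),
                    file.path(config$out_dir, "same_function.tsv"))
    suggestions <- suggest_functions(res$verified, go)
    write_tsv_table(
      tibble(complex = suggestions$complex,
             members = map_chr(suggestions$members, paste, collapse = ","),
             uncharacterized = suggestions$uncharacterized,
             suggested_terms = map_chr(suggestions$suggested_terms, paste,
                                       collapse = ",")),
      file.path(config$out_dir, "suggestions.tsv"))
  }
  invisible(list(candidates = candidates, verification = res,
                 evaluation = evaluation, same_function_ratio = sfr,
                 suggestions = suggestions))
}

# plain deterministic TSV writer for flat tables
write_tsv_table <- function(df, path) {
  df <- as.data.frame(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
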