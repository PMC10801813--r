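# Pipeline composition: configuration, per-pair scoring, screen assembly,
# and deterministic TSV output. The command-line wrapper in
# inst/cli/afmscreen.R is a thin shell over these functions.

#' Pipeline run configuration
#'
#' Bundles the contact thresholds, pDockQ parameters and screen options.
#' Defaults reproduce the standard screen settings (pLDDT > 50, min PAE
#' < 15 Angstrom, heavy-atom distance < 8 Angstrom; published pDockQ
#' calibration; best-model pair reduction).
#'
#' @param thresholds a [contact_thresholds()].
#' @param pdockq a [pdockq_params()].
#' @param pair_reduction `"best"` or `"mean"`; see [pair_row()].
#' @param M_expected optional expected model count per pair; a pair with a
#'   different number of models gets a warning.
#' @param seed optional RNG seed recorded with the run.
#' @param provenance free-text block describing how the predictions were
#'   generated (model weights, recycles, MSA pipeline); stored verbatim.
#' @return A `run_config` list.
#' @export
run_config <- function(thresholds = contact_thresholds(),
                       pdockq = pdockq_params(),
                       pair_reduction = c("best", "mean"),
                       M_expected = NULL, seed = NULL, provenance = "") {
  stopifnot(inherits(thresholds, "contact_thresholds"),
            inherits(pdockq, "pdockq_params"))
  pair_reduction <- match.arg(pair_reduction)
  structure(list(thresholds = thresholds, pdockq = pdockq,
                 pair_reduction = pair_reduction, M_expected = M_expected,
                 seed = seed, provenance = provenance),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognized keys: `min_avg_plddt`, `max_min_pae`, `max_heavy_dist`,
#' `pdockq_L`, `pdockq_x0`, `pdockq_k`, `pdockq_b`, `pair_reduction`,
#' `M_expected`, `seed`, `provenance`. Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  y <- yaml::read_yaml(path)
  g <- function(key, default) y[[key]] %||% default
  run_config(
    thresholds = contact_thresholds(
      min_avg_plddt = g("min_avg_plddt", 50),
      max_min_pae = g("max_min_pae", 15),
      max_heavy_dist = g("max_heavy_dist", 8)),
    pdockq = pdockq_params(L = g("pdockq_L", 0.724),
                           x0 = g("pdockq_x0", 152.611),
                           k = g("pdockq_k", 0.052),
                           b = g("pdockq_b", 0.018)),
    pair_reduction = g("pair_reduction", "best"),
    M_expected = y$M_expected, seed = y$seed,
    provenance = g("provenance", "")
  )
}

#' Score one prediction
#'
#' Reads a structure and its PAE matrix, detects the contacts between one
#' chain pair, and returns the interface summary.
#'
#' @param structure_path coordinate file (PDB/mmCIF).
#' @param pae_path PAE JSON file.
#' @param chain_pair two chain ids; `NULL` (default) uses the first two
#'   chains of the file.
#' @param config a [run_config()].
#' @param model_id optional model identifier.
#' @return List with `summary` (an `interface_summary`) and `contacts`
#'   (the `contact_set`).
#' @export
score_prediction <- function(structure_path, pae_path, chain_pair = NULL,
                             config = run_config(), model_id = NULL) {
  model <- read_structure(structure_path, model_id = model_id)
  pae <- read_pae(pae_path)
  pred <- bind_prediction(model, pae)
  if (is.null(chain_pair)) chain_pair <- model$chains[1:2]
  cs <- find_contacts(pred, chain_pair, config$thresholds)
  list(summary = interface_stats(cs, config$pdockq), contacts = cs)
}

#' Score and aggregate the model ensemble of one pair
#'
#' @param pair_id identifier of the candidate pair.
#' @param structure_paths,pae_paths parallel vectors of per-model files.
#' @param chain_pair two chain ids; `NULL` uses the first two chains.
#' @param config a [run_config()].
#' @return A `pair_aggregate`.
#' @export
score_pair <- function(pair_id, structure_paths, pae_paths,
                       chain_pair = NULL, config = run_config()) {
  stopifnot(length(structure_paths) == length(pae_paths),
            length(structure_paths) >= 1L)
  if (!is.null(config$M_expected) &&
      length(structure_paths) != config$M_expected)
    warning("pair ", pair_id, ": ", length(structure_paths),
            " models, expected ", config$M_expected)
  css <- lapply(seq_along(structure_paths), function(i) {
    model <- read_structure(structure_paths[i])
    pred <- bind_prediction(model, read_pae(pae_paths[i]))
    cp <- if (is.null(chain_pair)) model$chains[1:2] else chain_pair
    find_contacts(pred, cp, config$thresholds)
  })
  aggregate_models(css, pair_id = pair_id, params = config$pdockq)
}

#' Run a candidate screen from a pair manifest
#'
#' The manifest is a TSV with columns `pair_id`, `structure_path`,
#' `pae_path` and one row per model; rows sharing a `pair_id` form that
#' pair's ensemble. Each pair is scored, reduced to one table row
#' ([pair_row()]) and the rows are ranked ([rank_candidates()]). A pair
#' whose files cannot be read is kept in the output with empty metrics and
#' `status = "error"` (it sinks to the bottom), with a warning.
#'
#' @param manifest_path path to the pair manifest TSV.
#' @param config a [run_config()].
#' @param annotated_ids optional character vector (or path to a
#'   one-identifier-per-line file) of annotated partners; when given, the
#'   re-ranked table ([rerank_with_annotation()]) is returned as well.
#' @return List with `ranked` (a `ranked_table`) and, when annotation was
#'   supplied, `reranked`.
#' @export
run_screen <- function(manifest_path, config = run_config(),
                       annotated_ids = NULL) {
  man <- utils::read.delim(manifest_path, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("pair_id", "structure_path", "pae_path")
  if (nrow(man) == 0L || !all(need %in% names(man))) {
    if (!all(need %in% names(man)))
      stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  rows <- lapply(split(man, man$pair_id)[unique(man$pair_id)], function(mm) {
    pid <- mm$pair_id[1L]
    res <- tryCatch({
      agg <- score_pair(pid, mm$structure_path, mm$pae_path,
                        config = config)
      r <- pair_row(agg, reduction = config$pair_reduction)
      r$status <- "ok"
      r
    }, error = function(e) {
      warning("pair ", pid, " skipped: ", conditionMessage(e),
              call. = FALSE)
      data.frame(pair_id = pid, n_models = nrow(mm),
                 avg_n_models = NA_real_, max_n_models = NA_integer_,
                 pdockq = NA_real_, avg_interface_pae = NA_real_,
                 avg_interface_plddt = NA_real_,
                 n_unique_contacts = NA_integer_, status = "error",
                 stringsAsFactors = FALSE)
    })
    res
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(pair_id = character(0), n_models = integer(0),
                      avg_n_models = numeric(0), max_n_models = integer(0),
                      pdockq = numeric(0), avg_interface_pae = numeric(0),
                      avg_interface_plddt = numeric(0),
                      n_unique_contacts = integer(0), status = character(0),
                      stringsAsFactors = FALSE)
  names(tab)[names(tab) == "pair_id"] <- "partner_id"
  ranked <- rank_candidates(tab)
  out <- list(ranked = ranked)
  if (!is.null(annotated_ids)) {
    if (length(annotated_ids) == 1L && file.exists(annotated_ids))
      annotated_ids <- readLines(annotated_ids, warn = FALSE)
    annotated_ids <- trimws(annotated_ids)
    annotated_ids <- annotated_ids[annotated_ids != ""]
    out$reranked <- rerank_with_annotation(ranked, annotated_ids)
  }
  out
}

#' Write a metrics table as a deterministic TSV
#'
#' Real-valued metric columns are fixed at 3 decimal places, integers are
#' written unpadded and missing values as `NA`, so re-running a pipeline
#' on the same inputs produces a byte-identical file.
#'
#' @param df data frame to write.
#' @param path output path (or `""` for standard output).
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(df, path) {
  out <- as.data.frame(df)
  for (nm in names(out)) {
    v <- out[[nm]]
    if (is.double(v))
      out[[nm]] <- ifelse(is.na(v), "NA", sprintf("%.3f", v))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
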