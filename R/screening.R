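# Proteome-screen assembly: candidate filtering, ranking, annotation
# re-ranking, and membership reports.

#' Filter a candidate proteome by length and redundancy
#'
#' Removes exact-duplicate amino-acid sequences (first occurrence kept;
#' comparison on the uppercased full-length sequence) and sequences shorter
#' than `min_len` or longer than `max_len` residues. The defaults are the
#' bounds used for GPU-feasible proteome-wide folding.
#'
#' @param sequences a FASTA file path, a `Biostrings::AAStringSet`, or a
#'   named character vector of sequences.
#' @param min_len minimum length in residues kept (default 15).
#' @param max_len maximum length in residues kept (default 3034).
#' @return List with `kept` (named character vector of sequences) and
#'   `removed` (data frame with `id`, `length`, `reason`).
#' @export
filter_proteome <- function(sequences, min_len = 15, max_len = 3034) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences) && is.null(names(sequences))) {
    aa <- Biostrings::readAAStringSet(sequences)
    seqs <- as.character(aa)
    names(seqs) <- sub("\\s.*$", "", names(aa))
  } else if (methods::is(sequences, "AAStringSet")) {
    seqs <- as.character(sequences)
    names(seqs) <- sub("\\s.*$", "", names(sequences))
  } else {
    seqs <- as.character(sequences)
    names(seqs) <- names(sequences)
  }
  removed <- data.frame(id = character(0), length = integer(0),
                        reason = character(0), stringsAsFactors = FALSE)
  if (length(seqs) == 0L) {
    warning("empty sequence input: nothing to filter")
    return(list(kept = seqs, removed = removed))
  }
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("every sequence needs an identifier")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence identifier: ",
         names(seqs)[duplicated(names(seqs))][1L])

  len <- nchar(seqs)
  norm <- toupper(seqs)
  reason <- rep(NA_character_, length(seqs))
  reason[len < min_len] <- "too short"
  reason[len > max_len] <- "too long"
  dup <- duplicated(norm) & is.na(reason)
  reason[dup] <- "redundant sequence"
  drop <- !is.na(reason)
  list(
    kept = seqs[!drop],
    removed = data.frame(id = names(seqs)[drop], length = len[drop],
                         reason = reason[drop], stringsAsFactors = FALSE)
  )
}

.sort_spec <- c("avg_n_models (desc)", "pdockq (desc)",
                "avg_interface_pae (asc)", "partner_id (asc)")

# Ordering permutation for the screen sort protocol. Missing metrics sink:
# NA avg_n_models/pdockq act as -Inf, NA pae as +Inf.
.rank_order <- function(rows, string_first = FALSE) {
  avg_n <- ifelse(is.na(rows$avg_n_models), -Inf, rows$avg_n_models)
  pd <- ifelse(is.na(rows$pdockq), -Inf, rows$pdockq)
  pae <- ifelse(is.na(rows$avg_interface_pae), Inf, rows$avg_interface_pae)
  if (string_first)
    order(-rows$in_STRING_db, -avg_n, -pd, pae, rows$partner_id)
  else
    order(-avg_n, -pd, pae, rows$partner_id)
}

#' Rank candidate interactors
#'
#' Sorts candidate rows by `avg_n_models` (descending), then `pdockq`
#' (descending), then `avg_interface_pae` (ascending), and assigns ranks
#' 1..N. Remaining ties are broken by `partner_id` so the ordering is a
#' deterministic function of the row set, independent of input order. Rows
#' whose metrics are absent (no contacts in any model) sink below all rows
#' with metrics.
#'
#' @param rows data frame with columns `partner_id`, `avg_n_models`,
#'   `pdockq`, `avg_interface_pae` (further columns are carried through).
#' @return A `ranked_table`: the input rows reordered with a leading
#'   `rank` column; the applied key sequence is in `attr(, "sort_spec")`.
#' @export
rank_candidates <- function(rows) {
  stopifnot(is.data.frame(rows))
  need <- c("partner_id", "avg_n_models", "pdockq", "avg_interface_pae")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(rows$partner_id))
    stop("duplicate partner_id: ",
         rows$partner_id[duplicated(rows$partner_id)][1L])
  rows$rank <- NULL
  out <- rows[.rank_order(rows), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, sort_spec = .sort_spec,
            class = c("ranked_table", "data.frame"))
}

#' Re-rank a candidate table by annotation membership
#'
#' Flags each row by membership of its `partner_id` in an annotation set
#' (e.g. known STRING associations of the bait), writes the flag to an
#' `in_STRING_db` column (1 = annotated, 0 = not), and re-sorts with the
#' flag as the primary key followed by the usual metric keys. Annotated ids
#' absent from the table are reported with a message, not an error.
#'
#' @param table a `ranked_table` (or compatible data frame).
#' @param annotated_ids character vector of annotated partner identifiers.
#' @return A `ranked_table` with the `in_STRING_db` column and fresh ranks.
#' @export
rerank_with_annotation <- function(table, annotated_ids) {
  stopifnot(is.data.frame(table))
  annotated_ids <- unique(as.character(annotated_ids))
  unknown <- setdiff(annotated_ids, table$partner_id)
  if (length(unknown) > 0L)
    message(length(unknown), " annotated id(s) not in table: ",
            paste(utils::head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ...")
  rows <- as.data.frame(table)
  rows$rank <- NULL
  rows$in_STRING_db <- as.integer(rows$partner_id %in% annotated_ids)
  out <- rows[.rank_order(rows, string_first = TRUE), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, sort_spec = c("in_STRING_db (desc)", .sort_spec),
            class = c("ranked_table", "data.frame"))
}

#' @export
print.ranked_table <- function(x, ...) {
  cat("<ranked_table> ", nrow(x), " candidate(s), sorted by ",
      paste(attr(x, "sort_spec"), collapse = ", "), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("  ... ", nrow(x) - 10L, " more row(s)\n", sep = "")
  invisible(x)
}

#' Top-k membership report
#'
#' Returns the top `k` rows of a ranked table and, for each identifier of
#' interest, whether it appears within the top k and at what rank.
#'
#' @param table a `ranked_table`.
#' @param k number of top rows (1..N).
#' @param must_include character vector of partner identifiers to query.
#' @return List with `top` (the first k rows) and `membership` (data frame
#'   with `id`, `found`, `rank`, `within_k`). Unknown ids get
#'   `found = FALSE`.
#' @export
top_k_report <- function(table, k, must_include = character(0)) {
  stopifnot(is.data.frame(table), k >= 1L, k <= nrow(table))
  must_include <- as.character(must_include)
  idx <- match(must_include, table$partner_id)
  membership <- data.frame(
    id = must_include,
    found = !is.na(idx),
    rank = table$rank[idx],
    within_k = !is.na(idx) & table$rank[idx] <= k,
    stringsAsFactors = FALSE
  )
  list(top = utils::head(as.data.frame(table), k), membership = membership)
}
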