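# Cross-model aggregation: agreement metrics over the model ensemble of one
# candidate pair.

#' Aggregate the per-model interfaces of one candidate pair
#'
#' Collects the unique contacts across all models of an ensemble, counts
#' for each unique contact how many models predicted it, and summarizes the
#' agreement as `avg_n_models` (mean of the counts over unique contacts)
#' and `max_n_models` (maximum count). Both lie between 1 and the number of
#' models run whenever at least one contact was predicted; higher values
#' mean stronger cross-model agreement. Models with an empty interface
#' contribute no contacts but still count toward `M`.
#'
#' @param contact_sets list of `contact_set` objects, one per model, all
#'   for the same chain pair and computed with identical thresholds.
#' @param pair_id identifier of the candidate pair (e.g. bait+partner).
#' @param M number of models run; defaults to `length(contact_sets)`.
#' @param params [pdockq_params()] used for the per-model summaries.
#' @return A `pair_aggregate`: list with `pair_id`, `M`, `chain_pair`,
#'   `n_unique_contacts`, `avg_n_models`, `max_n_models` (the latter two
#'   `NA` when no model has any contact), `contact_counts` (data frame of
#'   unique contact keys and their model counts), `per_model` (data frame
#'   of [interface_stats()] rows), `best_pdockq` and
#'   `best_avg_interface_pae`.
#' @export
aggregate_models <- function(contact_sets, pair_id,
                             M = length(contact_sets),
                             params = pdockq_params()) {
  stopifnot(length(contact_sets) >= 1L, M >= length(contact_sets))
  if (!all(vapply(contact_sets, inherits, logical(1), "contact_set")))
    stop("contact_sets must be a list of contact_set objects")
  model_ids <- vapply(contact_sets, `[[`, character(1), "model_id")
  if (anyDuplicated(model_ids))
    stop("duplicate model_id in ensemble: ",
         model_ids[duplicated(model_ids)][1L])
  cps <- unique(lapply(contact_sets, `[[`, "chain_pair"))
  if (length(cps) != 1L)
    stop("inconsistent chain_pair across models: ",
         paste(vapply(cps, paste, character(1), collapse = "-"),
               collapse = " vs "))

  keys <- unlist(lapply(contact_sets, function(cs) unique(cs$contacts$key)),
                 use.names = FALSE)
  if (length(keys) > 0L) {
    counts <- table(keys)
    contact_counts <- data.frame(key = names(counts),
                                 n_models = as.integer(counts),
                                 stringsAsFactors = FALSE)
    contact_counts <- contact_counts[order(contact_counts$key), , drop = FALSE]
    rownames(contact_counts) <- NULL
    avg_n_models <- mean(contact_counts$n_models)
    max_n_models <- max(contact_counts$n_models)
  } else {
    contact_counts <- data.frame(key = character(0), n_models = integer(0),
                                 stringsAsFactors = FALSE)
    avg_n_models <- NA_real_
    max_n_models <- NA_integer_
  }

  per_model <- do.call(rbind, lapply(contact_sets, function(cs)
    as.data.frame(interface_stats(cs, params))))
  rownames(per_model) <- NULL
  with_contacts <- per_model$n_contacts > 0L

  structure(list(
    pair_id = pair_id, M = M, chain_pair = cps[[1L]],
    n_unique_contacts = nrow(contact_counts),
    avg_n_models = avg_n_models, max_n_models = max_n_models,
    contact_counts = contact_counts,
    per_model = per_model,
    best_pdockq = if (any(with_contacts)) max(per_model$pdockq[with_contacts])
                  else NA_real_,
    best_avg_interface_pae = if (any(with_contacts))
      min(per_model$avg_interface_pae[with_contacts]) else NA_real_
  ), class = "pair_aggregate")
}

#' @export
print.pair_aggregate <- function(x, ...) {
  cat("<pair_aggregate> ", x$pair_id, " (", x$M, " models)\n", sep = "")
  cat(sprintf("  unique contacts %d, avg_n_models %s, max_n_models %s\n",
              x$n_unique_contacts,
              ifelse(is.na(x$avg_n_models), "NA",
                     sprintf("%.3f", x$avg_n_models)),
              ifelse(is.na(x$max_n_models), "NA",
                     as.character(x$max_n_models))))
  invisible(x)
}

#' Best model of an ensemble for one metric
#'
#' Picks the optimal model of the ensemble for a metric: the maximum over
#' models for `pdockq` and `avg_interface_plddt`, the minimum for
#' `avg_interface_pae`. Only models with at least one contact are eligible;
#' ties are broken deterministically by the lexicographically lowest
#' `model_id`.
#'
#' @param agg a `pair_aggregate`.
#' @param metric one of `"pdockq"`, `"avg_interface_pae"`,
#'   `"avg_interface_plddt"`.
#' @return List with `model_id` and `value`, or `NULL` when every model is
#'   contactless.
#' @export
best_of <- function(agg, metric = c("pdockq", "avg_interface_pae",
                                    "avg_interface_plddt")) {
  stopifnot(inherits(agg, "pair_aggregate"))
  metric <- match.arg(metric)
  pm <- agg$per_model[agg$per_model$n_contacts > 0L, , drop = FALSE]
  if (nrow(pm) == 0L) return(NULL)
  v <- pm[[metric]]
  best <- if (metric == "avg_interface_pae") v == min(v) else v == max(v)
  cand <- pm[best, , drop = FALSE]
  pick <- which.min(rank(cand$model_id, ties.method = "first"))
  list(model_id = cand$model_id[pick], value = cand[[metric]][pick])
}

#' One representative table row per candidate pair
#'
#' Reduces a `pair_aggregate` to the single row used in the ranked screen
#' table. With `reduction = "best"` the representative `pdockq` is the
#' maximum over models and `avg_interface_pae`/`avg_interface_plddt` come
#' from the most confident side (minimum PAE, maximum pLDDT); with
#' `"mean"` each is the mean over models that predicted at least one
#' contact.
#'
#' @param agg a `pair_aggregate`.
#' @param reduction `"best"` (default) or `"mean"`.
#' @return One-row data frame with columns `pair_id`, `n_models`,
#'   `avg_n_models`, `max_n_models`, `pdockq`, `avg_interface_pae`,
#'   `avg_interface_plddt`, `n_unique_contacts`.
#' @export
pair_row <- function(agg, reduction = c("best", "mean")) {
  stopifnot(inherits(agg, "pair_aggregate"))
  reduction <- match.arg(reduction)
  pm <- agg$per_model[agg$per_model$n_contacts > 0L, , drop = FALSE]
  if (nrow(pm) == 0L) {
    pd <- NA_real_; pae <- NA_real_; pl <- NA_real_
  } else if (reduction == "best") {
    pd <- max(pm$pdockq); pae <- min(pm$avg_interface_pae)
    pl <- max(pm$avg_interface_plddt)
  } else {
    pd <- mean(pm$pdockq); pae <- mean(pm$avg_interface_pae)
    pl <- mean(pm$avg_interface_plddt)
  }
  data.frame(pair_id = agg$pair_id, n_models = agg$M,
             avg_n_models = agg$avg_n_models,
             max_n_models = as.integer(agg$max_n_models),
             pdockq = pd, avg_interface_pae = pae,
             avg_interface_plddt = pl,
             n_unique_contacts = agg$n_unique_contacts,
             stringsAsFactors = FALSE)
}
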