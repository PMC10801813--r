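# Per-prediction interface statistics and the pDockQ interface-quality score.

#' pDockQ sigmoid parameters
#'
#' Parameters of the logistic curve mapping interface confidence to a
#' predicted DockQ score: `L / (1 + exp(-k * (x - x0))) + b`, where
#' `x = avg_interface_plddt * ln(n_contacts)`. Defaults are the published
#' calibration of the score.
#'
#' @param L sigmoid ceiling (default 0.724).
#' @param x0 sigmoid midpoint (default 152.611).
#' @param k steepness (default 0.052).
#' @param b floor offset (default 0.018).
#' @return A `pdockq_params` list.
#' @export
pdockq_params <- function(L = 0.724, x0 = 152.611, k = 0.052, b = 0.018) {
  stopifnot(k > 0, L + b <= 1, L > 0, b >= 0)
  structure(list(L = L, x0 = x0, k = k, b = b), class = "pdockq_params")
}

#' pDockQ from interface pLDDT and contact count
#'
#' Direct evaluation of the pDockQ sigmoid. Returns 0 when `n_contacts` is
#' 0: an empty interface must never outrank a predicted one, so the floor
#' offset is not applied to it.
#'
#' @param avg_plddt mean interface pLDDT (0-100 scale).
#' @param n_contacts number of interface contacts.
#' @param params a [pdockq_params()] object.
#' @return pDockQ score in `[0, 1]` (vectorized over the inputs).
#' @export
pdockq_score <- function(avg_plddt, n_contacts,
                         params = pdockq_params()) {
  x <- avg_plddt * log(pmax(n_contacts, 1))
  s <- params$L / (1 + exp(-params$k * (x - params$x0))) + params$b
  ifelse(n_contacts == 0, 0, s)
}

#' pDockQ of a contact set
#'
#' Computes pDockQ from the interface defined by this pipeline's own
#' contact set: `x` is the mean over contacts of the per-contact pLDDT
#' (itself the mean of the two residues) multiplied by the natural log of
#' the contact count.
#'
#' @param cs a `contact_set`.
#' @param params a [pdockq_params()] object.
#' @return pDockQ score in `[0, 1]`; 0 for an empty contact set.
#' @export
pdockq <- function(cs, params = pdockq_params()) {
  stopifnot(inherits(cs, "contact_set"))
  n <- n_contacts(cs)
  if (n == 0L) return(0)
  pdockq_score(mean(cs$contacts$avg_plddt), n, params)
}

#' Interface summary statistics of one prediction
#'
#' Averages the per-contact statistics across all contacts of the
#' interface: `avg_interface_pae` is the mean of the contacts' minimum
#' directional PAE, `avg_interface_plddt` the mean of the contacts'
#' pair-average pLDDT. For an empty interface the averages are `NA` and
#' pDockQ is 0.
#'
#' @param cs a `contact_set`.
#' @param params a [pdockq_params()] object used for the pDockQ column.
#' @return An `interface_summary` list with `model_id`, `chain_pair`,
#'   `n_contacts`, `avg_interface_pae`, `avg_interface_plddt`, `pdockq`.
#' @export
interface_stats <- function(cs, params = pdockq_params()) {
  stopifnot(inherits(cs, "contact_set"))
  n <- n_contacts(cs)
  structure(list(
    model_id = cs$model_id,
    chain_pair = cs$chain_pair,
    n_contacts = n,
    avg_interface_pae = if (n > 0L) mean(cs$contacts$min_pae) else NA_real_,
    avg_interface_plddt = if (n > 0L) mean(cs$contacts$avg_plddt) else NA_real_,
    pdockq = pdockq(cs, params)
  ), class = "interface_summary")
}

#' @export
print.interface_summary <- function(x, ...) {
  cat("<interface_summary> model ", x$model_id, ", chains ",
      paste(x$chain_pair, collapse = "-"), "\n", sep = "")
  cat(sprintf("  n_contacts %d, avg_pae %s, avg_plddt %s, pdockq %.3f\n",
              x$n_contacts,
              ifelse(is.na(x$avg_interface_pae), "NA",
                     sprintf("%.2f", x$avg_interface_pae)),
              ifelse(is.na(x$avg_interface_plddt), "NA",
                     sprintf("%.2f", x$avg_interface_plddt)),
              x$pdockq))
  invisible(x)
}

#' @export
as.data.frame.interface_summary <- function(x, ...) {
  data.frame(model_id = x$model_id,
             chain_a = x$chain_pair[1L], chain_b = x$chain_pair[2L],
             n_contacts = x$n_contacts,
             avg_interface_pae = x$avg_interface_pae,
             avg_interface_plddt = x$avg_interface_plddt,
             pdockq = x$pdockq,
             stringsAsFactors = FALSE)
}
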