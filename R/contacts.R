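# Inter-chain contact detection: pair-average pLDDT, minimum directional
# PAE, and minimum heavy-atom distance filters.

#' Contact detection thresholds
#'
#' The three filters that define an inter-chain residue contact. All
#' comparisons are strict: a pair is a contact when its pair-average pLDDT
#' exceeds `min_avg_plddt`, its minimum directional PAE is below
#' `max_min_pae`, and at least one heavy-atom pair (one atom from each
#' residue) lies closer than `max_heavy_dist`.
#'
#' @param min_avg_plddt pLDDT threshold on the 0-100 scale (default 50).
#' @param max_min_pae PAE threshold in Angstrom (default 15).
#' @param max_heavy_dist heavy-atom distance threshold in Angstrom
#'   (default 8).
#' @return A `contact_thresholds` list.
#' @export
contact_thresholds <- function(min_avg_plddt = 50, max_min_pae = 15,
                               max_heavy_dist = 8) {
  stopifnot(min_avg_plddt > 0, max_min_pae > 0, max_heavy_dist > 0)
  structure(list(min_avg_plddt = min_avg_plddt, max_min_pae = max_min_pae,
                 max_heavy_dist = max_heavy_dist),
            class = "contact_thresholds")
}

# Heavy-atom pairs of two coordinate sets closer than cutoff (strict),
# via a cell list at cutoff-width bins; only the 27 neighbouring cells of
# each occupied cell need scanning.
.close_atom_pairs <- function(xyz_a, xyz_b, cutoff) {
  na <- nrow(xyz_a); nb <- nrow(xyz_b)
  out <- list(ia = integer(0), ib = integer(0), d = numeric(0))
  if (na == 0L || nb == 0L) return(out)
  if (na * nb <= 40000L) {
    d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
      2 * tcrossprod(xyz_a, xyz_b)
    d2[d2 < 0] <- 0
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    return(list(ia = hit[, 1L], ib = hit[, 2L],
                d = sqrt(d2[hit])))
  }
  cell_key <- function(xyz) {
    g <- floor(xyz / cutoff)
    paste(g[, 1L], g[, 2L], g[, 3L], sep = ",")
  }
  ka <- cell_key(xyz_a)
  b_cells <- split(seq_len(nb), cell_key(xyz_b))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ia_all <- integer(0); ib_all <- integer(0); d_all <- numeric(0)
  for (cell in unique(ka)) {
    ia <- which(ka == cell)
    g <- as.integer(strsplit(cell, ",", fixed = TRUE)[[1L]])
    neigh <- paste(g[1L] + offs[, 1L], g[2L] + offs[, 2L], g[3L] + offs[, 3L],
                   sep = ",")
    ib <- unlist(b_cells[neigh], use.names = FALSE)
    if (is.null(ib) || length(ib) == 0L) next
    d2 <- outer(rowSums(xyz_a[ia, , drop = FALSE]^2),
                rowSums(xyz_b[ib, , drop = FALSE]^2), "+") -
      2 * tcrossprod(xyz_a[ia, , drop = FALSE], xyz_b[ib, , drop = FALSE])
    d2[d2 < 0] <- 0
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    ia_all <- c(ia_all, ia[hit[, 1L]])
    ib_all <- c(ib_all, ib[hit[, 2L]])
    d_all <- c(d_all, sqrt(d2[hit]))
  }
  list(ia = ia_all, ib = ib_all, d = d_all)
}

#' Find inter-chain residue contacts
#'
#' Applies the three-filter contact definition between two chains of one
#' bound prediction: a unique residue pair is a contact when the arithmetic
#' mean of the two residues' pLDDT exceeds the pLDDT threshold, the minimum
#' of the two directional PAE values is below the PAE threshold, and the
#' minimum inter-residue heavy-atom distance is below the distance
#' threshold. The result is independent of the order in which the two
#' chains are given.
#'
#' @param pred a `bound_prediction` from [bind_prediction()].
#' @param chain_pair character vector of two chain ids.
#' @param thresholds a [contact_thresholds()] object.
#' @return A `contact_set`: list with `chain_pair` (sorted), `model_id`,
#'   `thresholds`, and `contacts`, a data frame with one row per contact
#'   (`chain_a`, `res_a`, `chain_b`, `res_b`, `avg_plddt`, `min_pae`,
#'   `min_heavy_dist`, `key`).
#' @export
find_contacts <- function(pred, chain_pair,
                          thresholds = contact_thresholds()) {
  stopifnot(inherits(pred, "bound_prediction"),
            inherits(thresholds, "contact_thresholds"),
            length(chain_pair) == 2L)
  model <- pred$structure
  missing_ch <- setdiff(chain_pair, model$chains)
  if (length(missing_ch) > 0L)
    stop("chain '", missing_ch[1L], "' not present in model ",
         model$model_id)
  if (chain_pair[1L] == chain_pair[2L])
    stop("contacts are inter-chain: chain ids must differ")
  cp <- sort(chain_pair)

  res <- model$residues
  at <- model$atoms[model$atoms$heavy, , drop = FALSE]
  at_a <- at[at$chain == cp[1L], , drop = FALSE]
  at_b <- at[at$chain == cp[2L], , drop = FALSE]

  empty <- data.frame(chain_a = character(0), res_a = character(0),
                      chain_b = character(0), res_b = character(0),
                      avg_plddt = numeric(0), min_pae = numeric(0),
                      min_heavy_dist = numeric(0), key = character(0),
                      stringsAsFactors = FALSE)
  cs <- structure(list(chain_pair = cp, model_id = model$model_id,
                       thresholds = thresholds, contacts = empty),
                  class = "contact_set")
  if (nrow(at_a) == 0L || nrow(at_b) == 0L) return(cs)

  hits <- .close_atom_pairs(as.matrix(at_a[, c("x", "y", "z")]),
                            as.matrix(at_b[, c("x", "y", "z")]),
                            thresholds$max_heavy_dist)
  if (length(hits$ia) == 0L) return(cs)

  ci <- at_a$concat_idx[hits$ia]
  cj <- at_b$concat_idx[hits$ib]
  pk <- paste(ci, cj, sep = "_")
  min_d <- tapply(hits$d, pk, min)
  pair_idx <- do.call(rbind, strsplit(names(min_d), "_", fixed = TRUE))
  i <- as.integer(pair_idx[, 1L]); j <- as.integer(pair_idx[, 2L])

  plddt <- res$plddt[order(res$concat_idx)]
  avg_plddt <- (plddt[i] + plddt[j]) / 2
  min_pae <- pmin(pred$pae[cbind(i, j)], pred$pae[cbind(j, i)])

  pass <- avg_plddt > thresholds$min_avg_plddt &
    min_pae < thresholds$max_min_pae &
    as.numeric(min_d) < thresholds$max_heavy_dist
  if (!any(pass)) return(cs)

  i <- i[pass]; j <- j[pass]
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]
  ridx <- order(res$concat_idx)
  ra <- res[ridx, ][i, ]; rb <- res[ridx, ][j, ]
  contacts <- data.frame(
    chain_a = ra$chain, res_a = ra$res_id,
    chain_b = rb$chain, res_b = rb$res_id,
    avg_plddt = avg_plddt[pass][ord],
    min_pae = min_pae[pass][ord],
    min_heavy_dist = as.numeric(min_d)[pass][ord],
    stringsAsFactors = FALSE
  )
  contacts$key <- contact_key(contacts$chain_a, contacts$res_a,
                              contacts$chain_b, contacts$res_b)
  cs$contacts <- contacts
  cs
}

#' Canonical, order-independent contact key
#'
#' @param chain_a,res_a,chain_b,res_b residue identities of the two sides.
#' @return Character key `"chain:res--chain:res"` with the lower chain id
#'   first, so the key does not depend on which residue is called a or b.
#' @export
contact_key <- function(chain_a, res_a, chain_b, res_b) {
  a <- paste0(chain_a, ":", res_a)
  b <- paste0(chain_b, ":", res_b)
  swap <- chain_b < chain_a
  ifelse(swap, paste0(b, "--", a), paste0(a, "--", b))
}

#' @export
print.contact_set <- function(x, ...) {
  cat("<contact_set> model ", x$model_id, ", chains ",
      paste(x$chain_pair, collapse = "-"), ": ", nrow(x$contacts),
      " contact(s)\n", sep = "")
  invisible(x)
}

#' Number of contacts in a contact set
#' @param cs a `contact_set`.
#' @return integer contact count.
#' @export
n_contacts <- function(cs) nrow(cs$contacts)

#' Per-residue adjacency listing of an interface
#'
#' @param cs a `contact_set`.
#' @return Named list: for each interface residue (`"chain:resno"`), the
#'   sorted character vector of its partner residues. The total number of
#'   entries over all residues is twice the number of contacts.
#' @export
contact_map <- function(cs) {
  stopifnot(inherits(cs, "contact_set"))
  ct <- cs$contacts
  if (nrow(ct) == 0L) return(list())
  a <- paste0(ct$chain_a, ":", ct$res_a)
  b <- paste0(ct$chain_b, ":", ct$res_b)
  m <- split(c(b, a), c(a, b))
  lapply(m[order(names(m))], function(v) sort(unique(v)))
}

#' Contacts as a plain table
#'
#' @param cs a `contact_set`.
#' @return Data frame with columns `chain_a`, `res_a`, `chain_b`, `res_b`,
#'   `avg_plddt`, `min_pae`, `min_heavy_dist`.
#' @export
contacts_table <- function(cs) {
  stopifnot(inherits(cs, "contact_set"))
  cs$contacts[, c("chain_a", "res_a", "chain_b", "res_b",
                  "avg_plddt", "min_pae", "min_heavy_dist")]
}
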