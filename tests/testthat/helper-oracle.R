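# Independent brute-force contact oracle: plain double loops over residue
# pairs and heavy-atom pairs, no neighbor search, no shared code with
# find_contacts beyond the input objects.
brute_force_contact_keys <- function(pred, chain_pair,
                                     thresholds = contact_thresholds()) {
  model <- pred$structure
  cp <- sort(chain_pair)
  res <- model$residues
  ra <- res[res$chain == cp[1L], , drop = FALSE]
  rb <- res[res$chain == cp[2L], , drop = FALSE]
  at <- model$atoms[model$atoms$heavy, , drop = FALSE]
  keys <- character(0)
  for (i in seq_len(nrow(ra))) {
    ai <- at[at$concat_idx == ra$concat_idx[i], , drop = FALSE]
    for (j in seq_len(nrow(rb))) {
      aj <- at[at$concat_idx == rb$concat_idx[j], , drop = FALSE]
      dmin <- Inf
      for (p in seq_len(nrow(ai))) for (q in seq_len(nrow(aj))) {
        d <- sqrt((ai$x[p] - aj$x[q])^2 + (ai$y[p] - aj$y[q])^2 +
                    (ai$z[p] - aj$z[q])^2)
        if (d < dmin) dmin <- d
      }
      avg_plddt <- (ra$plddt[i] + rb$plddt[j]) / 2
      mp <- min(pred$pae[ra$concat_idx[i], rb$concat_idx[j]],
                pred$pae[rb$concat_idx[j], ra$concat_idx[i]])
      if (avg_plddt > thresholds$min_avg_plddt &&
          mp < thresholds$max_min_pae &&
          dmin < thresholds$max_heavy_dist) {
        keys <- c(keys, contact_key(ra$chain[i], ra$res_id[i],
                                    rb$chain[j], rb$res_id[j]))
      }
    }
  }
  sort(keys)
}

# Read a generated fixture back through the pipeline and return the bound
# prediction.
read_fixture <- function(fx) {
  bind_prediction(read_structure(fx$structure_path), read_pae(fx$pae_path))
}

# Run contact detection + aggregation over a generated ensemble.
score_generated_ensemble <- function(en, thresholds = contact_thresholds()) {
  css <- lapply(seq_along(en$models), function(i) {
    pred <- bind_prediction(
      read_structure(en$models[[i]]$structure_path,
                     model_id = sprintf("m%02d", i)),
      read_pae(en$models[[i]]$pae_path))
    find_contacts(pred, pred$structure$chains[1:2], thresholds)
  })
  aggregate_models(css, pair_id = "pair", M = length(css))
}
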