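# Construct contact sets and candidate rows directly, for unit tests of
# metrics, aggregation and ranking that need no geometry.
make_contact_set <- function(model_id, res_a = character(0),
                             res_b = character(0),
                             avg_plddt = numeric(0), min_pae = numeric(0),
                             min_heavy_dist = rep(5, length(res_a)),
                             chain_pair = c("A", "B")) {
  contacts <- if (length(res_a) == 0L) {
    data.frame(chain_a = character(0), res_a = character(0),
               chain_b = character(0), res_b = character(0),
               avg_plddt = numeric(0), min_pae = numeric(0),
               min_heavy_dist = numeric(0), stringsAsFactors = FALSE)
  } else {
    data.frame(
      chain_a = chain_pair[1L], res_a = as.character(res_a),
      chain_b = chain_pair[2L], res_b = as.character(res_b),
      avg_plddt = avg_plddt, min_pae = min_pae,
      min_heavy_dist = min_heavy_dist, stringsAsFactors = FALSE)
  }
  contacts$key <- contact_key(contacts$chain_a, contacts$res_a,
                              contacts$chain_b, contacts$res_b)
  structure(list(chain_pair = sort(chain_pair), model_id = model_id,
                 thresholds = contact_thresholds(), contacts = contacts),
            class = "contact_set")
}

make_candidate_rows <- function(ids, avg_n_models, pdockq,
                                avg_interface_pae) {
  data.frame(partner_id = ids, avg_n_models = avg_n_models,
             pdockq = pdockq, avg_interface_pae = avg_interface_pae,
             stringsAsFactors = FALSE)
}
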