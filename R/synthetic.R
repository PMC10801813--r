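# Synthetic prediction fixtures with planted, analytically known
# interfaces. Chains are laid out on well-separated lattices; each planted
# contact is realized by translating one designated residue toward its
# partner, so the expected contact set at any threshold is known exactly
# before any file is written. No attempt is made at realistic protein
# geometry: analytic control is the point.

#' Specification of one synthetic prediction fixture
#'
#' @param chains named integer vector of residues per chain, e.g.
#'   `c(A = 5, B = 5)`; at least two chains of at least one residue.
#' @param planted data frame of planted contacts with columns `res_a`,
#'   `res_b` (`"chain:resno"` strings on different chains), `dist` (target
#'   minimum heavy-atom distance, must be < 8 so planted truth is
#'   unambiguous at the default thresholds), `plddt_a`, `plddt_b` (0-100),
#'   `pae_ab`, `pae_ba` (Angstrom). `NULL` for no planted contacts. Each
#'   residue may take part in at most one planted contact.
#' @param background_min_dist lattice separation between chains, Angstrom
#'   (default 20; must exceed 8 so background pairs can never be contacts).
#' @param background_pae PAE for all non-planted entries (default 30).
#' @param background_plddt pLDDT of non-planted residues (default 40; must
#'   be at most 50 so background pairs fail the pLDDT filter too).
#' @param atoms_per_residue 1 (CA only, default) or 3 (N, CA, C), to
#'   exercise the minimum-over-atoms rule.
#' @param add_hydrogens also write one hydrogen per residue (default
#'   FALSE); hydrogens must never affect contact detection.
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(chains, planted = NULL,
                         background_min_dist = 20, background_pae = 30,
                         background_plddt = 40, atoms_per_residue = 1,
                         add_hydrogens = FALSE) {
  stopifnot(length(chains) >= 2L, all(chains >= 1L),
            !is.null(names(chains)), !anyDuplicated(names(chains)),
            background_min_dist > 8, background_pae > 0,
            background_plddt <= 50, background_plddt >= 0,
            atoms_per_residue %in% c(1L, 3L))
  if (is.null(planted)) {
    planted <- data.frame(res_a = character(0), res_b = character(0),
                          dist = numeric(0), plddt_a = numeric(0),
                          plddt_b = numeric(0), pae_ab = numeric(0),
                          pae_ba = numeric(0), stringsAsFactors = FALSE)
  }
  need <- c("res_a", "res_b", "dist", "plddt_a", "plddt_b", "pae_ab", "pae_ba")
  stopifnot(all(need %in% names(planted)))
  if (nrow(planted) > 0L) {
    split_id <- function(v) do.call(rbind, strsplit(v, ":", fixed = TRUE))
    pa <- split_id(planted$res_a); pb <- split_id(planted$res_b)
    if (!all(pa[, 1L] %in% names(chains)) || !all(pb[, 1L] %in% names(chains)))
      stop("planted contact references an unknown chain")
    if (any(pa[, 1L] == pb[, 1L]))
      stop("planted contacts must join two different chains")
    if (any(as.integer(pa[, 2L]) > chains[pa[, 1L]]) ||
        any(as.integer(pb[, 2L]) > chains[pb[, 1L]]) ||
        any(as.integer(pa[, 2L]) < 1L) || any(as.integer(pb[, 2L]) < 1L))
      stop("planted contact references a residue outside its chain")
    if (anyDuplicated(c(planted$res_a, planted$res_b)))
      stop("infeasible geometry: a residue takes part in more than one ",
           "planted contact")
    if (any(planted$dist >= 8))
      stop("planted target_heavy_dist must be < 8 Angstrom")
    if (any(planted$dist <= 0))
      stop("planted target_heavy_dist must be positive")
    stopifnot(all(planted$plddt_a >= 0 & planted$plddt_a <= 100),
              all(planted$plddt_b >= 0 & planted$plddt_b <= 100),
              all(planted$pae_ab >= 0), all(planted$pae_ba >= 0))
  }
  structure(list(chains = chains, planted = planted,
                 background_min_dist = background_min_dist,
                 background_pae = background_pae,
                 background_plddt = background_plddt,
                 atoms_per_residue = as.integer(atoms_per_residue),
                 add_hydrogens = add_hydrogens),
            class = "fixture_spec")
}

# Residue lattice: residue r of chain k has its CA at
# x = (r-1)*20, y = (k-1)*background_min_dist. A planted contact moves the
# res_b residue to sit at the planted distance directly "above" res_a.
.fixture_atoms <- function(spec) {
  spacing <- 20
  chain_ids <- names(spec$chains)
  res <- do.call(rbind, lapply(seq_along(chain_ids), function(k) {
    n <- spec$chains[[k]]
    data.frame(chain = chain_ids[k], resno = seq_len(n),
               cx = (seq_len(n) - 1) * spacing,
               cy = (k - 1) * spec$background_min_dist, cz = 0,
               plddt = spec$background_plddt, stringsAsFactors = FALSE)
  }))
  res$id <- paste0(res$chain, ":", res$resno)
  pl <- spec$planted
  for (i in seq_len(nrow(pl))) {
    ia <- match(pl$res_a[i], res$id); ib <- match(pl$res_b[i], res$id)
    # translate the b residue next to a, offset along y toward b's own side
    sgn <- if (res$cy[ib] >= res$cy[ia]) 1 else -1
    res$cx[ib] <- res$cx[ia]
    res$cy[ib] <- res$cy[ia] + sgn * pl$dist[i]
    res$cz[ib] <- res$cz[ia]
    res$plddt[ia] <- pl$plddt_a[i]
    res$plddt[ib] <- pl$plddt_b[i]
  }
  # expand to atoms; all residues share the same intra-residue offsets, so
  # the minimum heavy-atom distance of a planted pair equals the CA offset
  offs <- if (spec$atoms_per_residue == 1L) {
    data.frame(atom = "CA", element = "C", dx = 0)
  } else {
    data.frame(atom = c("N", "CA", "C"), element = c("N", "C", "C"),
               dx = c(-1.3, 0, 1.3))
  }
  atoms <- merge(res, offs, by = NULL, sort = FALSE)
  atoms <- atoms[order(match(atoms$chain, chain_ids), atoms$resno,
                       match(atoms$atom, offs$atom)), , drop = FALSE]
  atoms <- data.frame(chain = atoms$chain, resno = atoms$resno,
                      resname = "ALA", atom = atoms$atom,
                      element = atoms$element,
                      x = atoms$cx + atoms$dx, y = atoms$cy, z = atoms$cz,
                      plddt = atoms$plddt, stringsAsFactors = FALSE)
  if (spec$add_hydrogens) {
    h <- atoms[atoms$atom == "CA", , drop = FALSE]
    h$atom <- "HA"; h$element <- "H"; h$z <- h$z + 1.0
    atoms <- rbind(atoms, h)
    atoms <- atoms[order(match(atoms$chain, chain_ids), atoms$resno), ,
                   drop = FALSE]
  }
  rownames(atoms) <- NULL
  atoms
}

# Verify the realized geometry: every planted pair at its target distance
# (within 0.01 A), every other inter-chain residue pair farther than 8 A.
.check_fixture_geometry <- function(spec, atoms) {
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  id <- paste0(heavy$chain, ":", heavy$resno)
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  ids <- unique(id)
  n <- length(ids)
  planted_key <- if (nrow(spec$planted) > 0L)
    paste(pmin(spec$planted$res_a, spec$planted$res_b),
          pmax(spec$planted$res_a, spec$planted$res_b)) else character(0)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ci <- sub(":.*", "", ids[i]); cj <- sub(":.*", "", ids[j])
    if (ci == cj) next
    ai <- xyz[id == ids[i], , drop = FALSE]
    aj <- xyz[id == ids[j], , drop = FALSE]
    d2 <- outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * tcrossprod(ai, aj)
    dmin <- sqrt(max(min(d2), 0))
    key <- paste(min(ids[i], ids[j]), max(ids[i], ids[j]))
    hit <- match(key, planted_key)
    if (!is.na(hit)) {
      if (abs(dmin - spec$planted$dist[hit]) > 0.01)
        stop("infeasible geometry: planted pair ", key, " realized at ",
             format(dmin, digits = 4), " A, target ",
             spec$planted$dist[hit])
    } else if (dmin <= 8) {
      stop("infeasible geometry: background pair ", key, " at ",
           format(dmin, digits = 4), " A (must exceed 8)")
    }
  }
  invisible(TRUE)
}

.fixture_pae <- function(spec) {
  chain_ids <- names(spec$chains)
  total <- sum(spec$chains)
  concat <- function(resid) {
    p <- strsplit(resid, ":", fixed = TRUE)[[1L]]
    k <- match(p[1L], chain_ids)
    sum(spec$chains[seq_len(k - 1L)]) + as.integer(p[2L])
  }
  m <- matrix(spec$background_pae, total, total)
  diag(m) <- 0
  for (i in seq_len(nrow(spec$planted))) {
    ia <- concat(spec$planted$res_a[i]); ib <- concat(spec$planted$res_b[i])
    m[ia, ib] <- spec$planted$pae_ab[i]
    m[ib, ia] <- spec$planted$pae_ba[i]
  }
  m
}

# Analytic truth at given thresholds. pLDDT compared at the 0.01 precision
# the PDB B-factor field carries.
.fixture_truth <- function(spec, thresholds = contact_thresholds()) {
  pl <- spec$planted
  if (nrow(pl) == 0L) {
    return(data.frame(key = character(0), dist = numeric(0),
                      avg_plddt = numeric(0), min_pae = numeric(0),
                      detected = logical(0), failed_filters = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- mapply(function(a, b) {
    pa <- strsplit(a, ":", fixed = TRUE)[[1L]]
    pb <- strsplit(b, ":", fixed = TRUE)[[1L]]
    contact_key(pa[1L], pa[2L], pb[1L], pb[2L])
  }, pl$res_a, pl$res_b, USE.NAMES = FALSE)
  avg_plddt <- (round(pl$plddt_a, 2) + round(pl$plddt_b, 2)) / 2
  min_pae <- pmin(pl$pae_ab, pl$pae_ba)
  fail <- cbind(plddt = !(avg_plddt > thresholds$min_avg_plddt),
                pae = !(min_pae < thresholds$max_min_pae),
                dist = !(pl$dist < thresholds$max_heavy_dist))
  failed <- apply(fail, 1L, function(f)
    paste(colnames(fail)[f], collapse = "+"))
  data.frame(key = key, dist = pl$dist, avg_plddt = avg_plddt,
             min_pae = min_pae, detected = failed == "",
             failed_filters = failed, stringsAsFactors = FALSE)
}

#' Write atoms as a PDB file
#'
#' Writes an atom table in fixed-width PDB format with pLDDT in the
#' B-factor field (AlphaFold convention), a TER record per chain and a
#' final END. Output is byte-deterministic for a given input.
#'
#' @param atoms data frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`, `plddt`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_file <- function(atoms, path) {
  name4 <- ifelse(nchar(atoms$atom) < 4L,
                  sprintf(" %-3s", atoms$atom), atoms$atom)
  lines <- character(0)
  serial <- 0L
  for (ch in unique(atoms$chain)) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    n4 <- name4[atoms$chain == ch]
    rec <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial + seq_len(nrow(a)), n4, a$resname, ch, a$resno,
      a$x, a$y, a$z, 1.00, a$plddt, a$element)
    serial <- serial + nrow(a)
    lines <- c(lines, rec, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write atoms as a minimal mmCIF file
#'
#' @inheritParams write_pdb_file
#' @return `path`, invisibly.
#' @export
write_mmcif_file <- function(atoms, path) {
  tags <- c("group_PDB", "id", "type_symbol", "label_atom_id",
            "label_alt_id", "label_comp_id", "label_asym_id",
            "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
            "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
            "B_iso_or_equiv", "auth_seq_id", "auth_asym_id",
            "pdbx_PDB_model_num")
  rows <- sprintf(
    "ATOM %d %s %s . %s %s %d %d ? %.3f %.3f %.3f 1.00 %.2f %d %s 1",
    seq_len(nrow(atoms)), atoms$element, atoms$atom, atoms$resname,
    atoms$chain, match(atoms$chain, unique(atoms$chain)), atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$plddt, atoms$resno, atoms$chain)
  writeLines(c("data_synthetic", "#", "loop_",
               paste0("_atom_site.", tags), rows, "#"), path)
  invisible(path)
}

#' Write a PAE matrix as JSON
#'
#' @param values square numeric matrix of PAE values, Angstrom.
#' @param path output path.
#' @param dialect `"colabfold"` (top-level `"pae"` key, default) or
#'   `"afdb"` (`"predicted_aligned_error"`, wrapped in a 1-element list).
#' @param max_pae value for the `max_pae` metadata field; default the
#'   larger of 31.75 and the matrix maximum.
#' @return `path`, invisibly.
#' @export
write_pae_json <- function(values, path, dialect = c("colabfold", "afdb"),
                           max_pae = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(max_pae)) max_pae <- max(31.75, max(values))
  obj <- if (dialect == "colabfold") {
    list(pae = values, max_pae = max_pae)
  } else {
    list(list(predicted_aligned_error = values,
              max_predicted_aligned_error = max_pae))
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Generate one synthetic prediction fixture
#'
#' Writes a coordinate file (pLDDT in B-factors), a PAE JSON and a truth
#' manifest realizing a [fixture_spec()]. The planted heavy-atom distances
#' are realized to within 0.01 Angstrom; the manifest lists every planted
#' contact, whether it passes the default thresholds, and the exact
#' expected contact keys. Geometry that cannot realize the spec (e.g.
#' contradictory placements) raises an error before any file is written.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @param basename stem for the output file names.
#' @param format coordinate format, `"pdb"` (default) or `"mmcif"`.
#' @return List with `structure_path`, `pae_path`, `manifest_path`,
#'   `manifest` (the truth, also written as JSON), and `spec`.
#' @export
generate_fixture <- function(spec, dir, basename = "fixture",
                             format = c("pdb", "mmcif")) {
  stopifnot(inherits(spec, "fixture_spec"))
  format <- match.arg(format)
  atoms <- .fixture_atoms(spec)
  .check_fixture_geometry(spec, atoms)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "pdb") ".pdb" else ".cif"
  structure_path <- file.path(dir, paste0(basename, ext))
  pae_path <- file.path(dir, paste0(basename, "_pae.json"))
  manifest_path <- file.path(dir, paste0(basename, "_manifest.json"))
  if (format == "pdb") write_pdb_file(atoms, structure_path)
  else write_mmcif_file(atoms, structure_path)
  write_pae_json(.fixture_pae(spec), pae_path)
  truth <- .fixture_truth(spec)
  manifest <- list(
    chains = as.list(spec$chains),
    n_residues = sum(spec$chains),
    planted = truth,
    expected_contacts = truth$key[truth$detected],
    n_expected = sum(truth$detected)
  )
  jsonlite::write_json(manifest, manifest_path, digits = NA,
                       auto_unbox = TRUE)
  list(structure_path = structure_path, pae_path = pae_path,
       manifest_path = manifest_path, manifest = manifest, spec = spec)
}

#' Specification of a synthetic multi-model ensemble
#'
#' @param M number of models in the ensemble.
#' @param membership list of integer vectors, one per planted contact of
#'   `base`, giving the (non-empty) subset of models 1..M whose prediction
#'   contains that contact.
#' @param base a [fixture_spec()] whose planted contacts carry the
#'   geometry and confidence values.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(M, membership, base) {
  stopifnot(inherits(base, "fixture_spec"), M >= 1L,
            length(membership) == nrow(base$planted))
  for (m in membership) {
    stopifnot(length(m) >= 1L, all(m %in% seq_len(M)),
              !anyDuplicated(m))
  }
  structure(list(M = as.integer(M), membership = membership, base = base),
            class = "ensemble_spec")
}

#' Generate a synthetic multi-model ensemble
#'
#' Writes `M` coordinate/PAE file pairs in which model `m` contains
#' exactly the planted contacts whose membership set includes `m`, plus a
#' truth manifest carrying the analytic cross-model agreement: over the
#' detectable planted contacts, `avg_n_models` is the mean of the
#' membership sizes and `max_n_models` their maximum.
#'
#' @param spec an [ensemble_spec()].
#' @param dir output directory.
#' @param basename stem for the model file names (`<basename>_m1.pdb`, ...).
#' @param format coordinate format passed to [generate_fixture()].
#' @return List with `models` (list of per-model file path lists),
#'   `manifest_path` and `manifest`.
#' @export
generate_ensemble <- function(spec, dir, basename = "model",
                              format = c("pdb", "mmcif")) {
  stopifnot(inherits(spec, "ensemble_spec"))
  format <- match.arg(format)
  base <- spec$base
  truth <- .fixture_truth(base)
  models <- lapply(seq_len(spec$M), function(m) {
    keep <- vapply(spec$membership, function(mm) m %in% mm, logical(1))
    pl <- base$planted[keep, , drop = FALSE]
    mspec <- fixture_spec(base$chains, planted = pl,
                          background_min_dist = base$background_min_dist,
                          background_pae = base$background_pae,
                          background_plddt = base$background_plddt,
                          atoms_per_residue = base$atoms_per_residue,
                          add_hydrogens = base$add_hydrogens)
    fx <- generate_fixture(mspec, dir, basename = paste0(basename, "_m", m),
                           format = format)
    fx[c("structure_path", "pae_path", "manifest_path")]
  })
  sizes <- lengths(spec$membership)[truth$detected]
  manifest <- list(
    M = spec$M,
    membership = lapply(spec$membership, as.integer),
    planted = truth,
    expected_contacts = truth$key[truth$detected],
    n_unique_contacts = sum(truth$detected),
    avg_n_models = if (length(sizes) > 0L) mean(sizes) else NA_real_,
    max_n_models = if (length(sizes) > 0L) max(sizes) else NA_integer_
  )
  manifest_path <- file.path(dir, paste0(basename, "_ensemble_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, digits = NA,
                       auto_unbox = TRUE)
  list(models = models, manifest_path = manifest_path, manifest = manifest)
}

#' Random fixture specification
#'
#' Draws a two-chain [fixture_spec()] with random chain lengths, random
#' planted contact geometry, random pLDDT over the full 0-100 range and
#' random PAE values. Values are rounded to the precision the output file
#' formats carry so the analytic truth matches the files exactly.
#'
#' @param seed RNG seed; the spec is a deterministic function of it.
#' @param min_res,max_res range of residues per chain (defaults 4 and 12).
#' @param max_planted maximum number of planted contacts (default 4; the
#'   draw may also yield 0).
#' @param atoms_per_residue passed to [fixture_spec()]; 0 (default) draws
#'   1 or 3 at random.
#' @return A `fixture_spec`.
#' @export
random_fixture_spec <- function(seed, min_res = 4, max_res = 12,
                                max_planted = 4, atoms_per_residue = 0) {
  set.seed(seed)
  nA <- sample(min_res:max_res, 1L)
  nB <- sample(min_res:max_res, 1L)
  k <- sample(0:min(max_planted, nA, nB), 1L)
  planted <- NULL
  if (k > 0L) {
    ra <- sample(nA, k); rb <- sample(nB, k)
    planted <- data.frame(
      res_a = paste0("A:", ra), res_b = paste0("B:", rb),
      dist = round(runif(k, 3, 7.9), 3),
      plddt_a = round(runif(k, 0, 100), 2),
      plddt_b = round(runif(k, 0, 100), 2),
      pae_ab = round(runif(k, 0, 30), 2),
      pae_ba = round(runif(k, 0, 30), 2),
      stringsAsFactors = FALSE)
  }
  if (atoms_per_residue == 0) atoms_per_residue <- sample(c(1L, 3L), 1L)
  fixture_spec(c(A = nA, B = nB), planted = planted,
               atoms_per_residue = atoms_per_residue)
}

#' Random ensemble specification
#'
#' Draws an [ensemble_spec()] whose planted contacts all pass the default
#' contact filters (pLDDT 55-95 per residue, PAE 1-14 Angstrom, distance
#' 3-7.5 Angstrom) and whose per-contact model membership is a uniformly
#' drawn non-empty subset of the M models.
#'
#' @param seed RNG seed; the spec is a deterministic function of it.
#' @param M number of models (default 5).
#' @param min_res,max_res range of residues per chain (defaults 4 and 10).
#' @param max_contacts maximum number of planted contacts (default 5, at
#'   least 1).
#' @return An `ensemble_spec`.
#' @export
random_ensemble_spec <- function(seed, M = 5, min_res = 4, max_res = 10,
                                 max_contacts = 5) {
  set.seed(seed)
  nA <- sample(min_res:max_res, 1L)
  nB <- sample(min_res:max_res, 1L)
  k <- sample(seq_len(min(max_contacts, nA, nB)), 1L)
  ra <- sample(nA, k); rb <- sample(nB, k)
  planted <- data.frame(
    res_a = paste0("A:", ra), res_b = paste0("B:", rb),
    dist = round(runif(k, 3, 7.5), 3),
    plddt_a = round(runif(k, 55, 95), 2),
    plddt_b = round(runif(k, 55, 95), 2),
    pae_ab = round(runif(k, 1, 14), 2),
    pae_ba = round(runif(k, 1, 14), 2),
    stringsAsFactors = FALSE)
  membership <- lapply(seq_len(k), function(i) {
    sz <- sample(M, 1L)
    sort(sample(M, sz))
  })
  base <- fixture_spec(c(A = nA, B = nB), planted = planted)
  ensemble_spec(M, membership, base)
}
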