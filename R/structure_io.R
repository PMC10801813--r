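# Reading predicted structures and PAE matrices; shared residue indexing.

#' Read a predicted multimer structure
#'
#' Parses a coordinate file produced by an AlphaFold-Multimer style pipeline
#' and returns the chains, residues and heavy atoms together with the
#' per-residue pLDDT confidence stored, by AlphaFold convention, in the
#' temperature-factor (B-factor) field.
#'
#' Chain and residue order is preserved exactly as written in the file; the
#' concatenated residue index that all downstream stages (PAE lookup, contact
#' keys) share is assigned in that order. HETATM ligands and waters are
#' skipped with a message. Hydrogen and deuterium atoms are retained but
#' flagged non-heavy so they never enter distance calculations. Files whose
#' B-factors are all at most 1 are assumed to carry pLDDT on a 0-1 scale and
#' are rescaled to 0-100 with a warning. For alternate-location atoms the
#' highest-occupancy conformer is kept (ties by first occurrence).
#'
#' @param path path to a PDB or mmCIF file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (default; decided by file
#'   extension, falling back to content sniffing).
#' @param model_id identifier attached to the model; defaults to the file
#'   name without extension.
#' @return An object of class `afm_structure`: a list with elements
#'   `model_id`, `chains` (chain ids in file order), `residues` (data frame
#'   with `chain`, `resno`, `insert`, `res_id`, `resname`, `plddt`,
#'   `concat_idx`), and `atoms` (data frame of atom records with coordinates,
#'   element, heavy flag and the owning residue's `concat_idx`).
#' @seealso [read_pae()], [bind_prediction()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else if (ext %in% c("pdb", "ent")) "pdb" else {
      head1 <- readLines(path, n = 50L, warn = FALSE)
      if (any(grepl("^(data_|loop_|_atom_site\\.)", head1))) "mmcif" else "pdb"
    }
  }
  atoms <- switch(format,
    pdb   = .read_atoms_pdb(path),
    mmcif = .read_atoms_mmcif(path)
  )
  if (is.null(model_id)) model_id <- tools::file_path_sans_ext(basename(path))
  .build_structure(atoms, model_id = model_id, source = path)
}

.read_atoms_pdb <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atom records in ", path)
  data.frame(
    record   = at$type,
    chain    = ifelse(is.na(at$chain), "", at$chain),
    resno    = at$resno,
    insert   = ifelse(is.na(at$insert), "", at$insert),
    resname  = at$resid,
    atom     = at$elety,
    altloc   = ifelse(is.na(at$alt), "", at$alt),
    occ      = ifelse(is.na(at$o), 1, at$o),
    x = at$x, y = at$y, z = at$z,
    b        = at$b,
    element  = ifelse(is.na(at$elesy), "", at$elesy),
    stringsAsFactors = FALSE
  )
}

# Minimal tag-aware parser for the mmCIF _atom_site loop. Quoted values are
# not expected in atom rows; rows are whitespace-delimited per the format.
.read_atoms_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag_idx <- grep("^_atom_site\\.", lines)
  if (length(tag_idx) == 0L)
    stop("no _atom_site loop found in ", path)
  if (any(diff(tag_idx) != 1L))
    stop("malformed _atom_site loop (non-contiguous tags) in ", path)
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  body <- lines[seq(max(tag_idx) + 1L, length(lines))]
  rows <- grep("^(ATOM|HETATM)\\s", body, value = TRUE)
  end <- grep("^(loop_|#|_\\w)", body)
  if (length(end) > 0L) {
    keep <- grep("^(ATOM|HETATM)\\s", body[seq_len(min(end) - 1L)], value = TRUE)
    rows <- keep
  }
  if (length(rows) == 0L) stop("empty _atom_site loop in ", path)
  fields <- strsplit(trimws(rows), "\\s+")
  nf <- lengths(fields)
  if (any(nf != length(tags)))
    stop("mmCIF _atom_site row has ", nf[which(nf != length(tags))[1L]],
         " fields, expected ", length(tags), " (line: ",
         rows[which(nf != length(tags))[1L]], ")")
  m <- do.call(rbind, fields)
  colnames(m) <- tags
  col <- function(nm, default = NA_character_) {
    for (n in nm) if (n %in% tags) return(m[, n])
    rep(default, nrow(m))
  }
  dot_na <- function(v) ifelse(v %in% c(".", "?"), "", v)
  # restrict to the first model block, mirroring single-MODEL PDB handling
  modnum <- col("pdbx_PDB_model_num", "1")
  first <- modnum == modnum[1L]
  sel <- function(v) v[first]
  num <- function(v) suppressWarnings(as.numeric(v))
  data.frame(
    record  = sel(m[, "group_PDB"]),
    chain   = sel(dot_na(col(c("auth_asym_id", "label_asym_id")))),
    resno   = as.integer(num(sel(col(c("auth_seq_id", "label_seq_id"))))),
    insert  = sel(dot_na(col("pdbx_PDB_ins_code"))),
    resname = sel(col(c("auth_comp_id", "label_comp_id"))),
    atom    = sel(col(c("auth_atom_id", "label_atom_id"))),
    altloc  = sel(dot_na(col("label_alt_id"))),
    occ     = ifelse(is.na(num(sel(col("occupancy")))), 1,
                     num(sel(col("occupancy")))),
    x = num(sel(col("Cartn_x"))), y = num(sel(col("Cartn_y"))),
    z = num(sel(col("Cartn_z"))),
    b = num(sel(col("B_iso_or_equiv"))),
    element = sel(dot_na(col("type_symbol"))),
    stringsAsFactors = FALSE
  )
}

.is_hydrogen <- function(element, atom_name) {
  el <- toupper(trimws(element))
  known <- el %in% c("H", "D")
  # element field absent: infer from atom name, digits stripped
  miss <- el == "" | is.na(el)
  if (any(miss)) {
    nm <- toupper(gsub("[0-9]", "", trimws(atom_name[miss])))
    known[miss] <- substr(nm, 1L, 1L) %in% c("H", "D")
  }
  known
}

.build_structure <- function(atoms, model_id, source) {
  het <- atoms$record != "ATOM"
  if (any(het)) {
    message("skipping ", sum(het), " HETATM record(s) (ligands/waters) in ",
            basename(source))
    atoms <- atoms[!het, , drop = FALSE]
  }
  if (nrow(atoms) == 0L) stop("no ATOM records in ", source)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates in ", source)
  if (any(is.na(atoms$b)))
    stop("missing B-factors (pLDDT) in ", source)

  # altloc resolution: highest occupancy per (chain, resno, insert, atom name)
  if (any(atoms$altloc != "")) {
    akey <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom, sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), akey), function(i) {
      i[which.max(atoms$occ[i])]
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
  }

  atoms$heavy <- !.is_hydrogen(atoms$element, atoms$atom)
  atoms$element <- ifelse(atoms$element == "" | is.na(atoms$element),
                          toupper(substr(gsub("[0-9]", "", trimws(atoms$atom)), 1L, 1L)),
                          toupper(trimws(atoms$element)))

  rkey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  first_seen <- !duplicated(rkey)
  res <- atoms[first_seen, c("chain", "resno", "insert", "resname")]
  res$res_id <- paste0(res$resno, res$insert)
  res$key <- rkey[first_seen]

  # per-residue pLDDT: all atoms of a residue carry the same value (tol 0.01)
  b_by_res <- split(atoms$b, factor(rkey, levels = res$key))
  spread <- vapply(b_by_res, function(v) diff(range(v)), numeric(1))
  if (any(spread > 0.01)) {
    bad <- res$key[which(spread > 0.01)[1L]]
    warning("atoms of residue ", gsub("\r", ":", bad),
            " carry differing B-factors (max spread ",
            format(max(spread), digits = 3),
            "); using the first atom's value per residue")
  }
  res$plddt <- vapply(b_by_res, `[`, numeric(1), 1L)

  # pLDDT scale: 0-1 files rescaled to the 0-100 convention
  if (all(res$plddt <= 1)) {
    warning("all B-factors <= 1: assuming pLDDT on a 0-1 scale, rescaling x100")
    res$plddt <- res$plddt * 100
  }
  if (any(res$plddt < 0 | res$plddt > 100))
    stop("pLDDT outside [0, 100] in ", source)

  heavy_per_res <- vapply(split(atoms$heavy, factor(rkey, levels = res$key)),
                          any, logical(1))
  if (!all(heavy_per_res))
    stop("residue ", gsub("\r", ":", res$key[!heavy_per_res][1L]),
         " has no heavy atom")

  chains <- unique(res$chain)
  if (length(chains) < 2L)
    stop("interface requires >= 2 chains (found ", length(chains),
         " in ", source, ")")
  for (ch in chains) {
    ids <- res$res_id[res$chain == ch]
    if (anyDuplicated(ids))
      stop("duplicate residue number ", ids[duplicated(ids)][1L],
           " in chain ", ch)
  }

  # concatenated index: chain order of first appearance, residue file order
  res$concat_idx <- NA_integer_
  k <- 0L
  for (ch in chains) {
    i <- which(res$chain == ch)
    res$concat_idx[i] <- k + seq_along(i)
    k <- k + length(i)
  }
  res <- res[order(res$concat_idx), , drop = FALSE]
  rownames(res) <- NULL
  atoms$concat_idx <- res$concat_idx[match(rkey, res$key)]
  res$key <- NULL
  rownames(atoms) <- NULL

  structure(
    list(model_id = model_id, chains = chains,
         residues = res,
         atoms = atoms[, c("chain", "resno", "insert", "resname", "atom",
                           "element", "heavy", "x", "y", "z", "concat_idx")],
         source = source),
    class = "afm_structure"
  )
}

#' @export
print.afm_structure <- function(x, ...) {
  cat("<afm_structure> model", x$model_id, "\n")
  for (ch in x$chains)
    cat("  chain ", ch, ": ", sum(x$residues$chain == ch), " residues\n",
        sep = "")
  cat("  ", nrow(x$atoms), " atoms (", sum(x$atoms$heavy), " heavy), pLDDT ",
      sprintf("%.1f-%.1f", min(x$residues$plddt), max(x$residues$plddt)),
      "\n", sep = "")
  invisible(x)
}

#' Total residue count of a structure
#' @param model an `afm_structure`.
#' @return integer residue count over all chains.
#' @export
n_residues <- function(model) nrow(model$residues)

#' Read a predicted aligned error (PAE) matrix
#'
#' Reads the square PAE matrix from JSON in either the ColabFold dialect
#' (top-level `"pae"` 2-D array) or the AFDB dialect
#' (`"predicted_aligned_error"`), optionally wrapped in a one-element list.
#' PAE is directional, so the matrix is not symmetrized.
#'
#' @param path path to the JSON file.
#' @return A `pae_matrix`: a numeric matrix with attributes `size` and
#'   (when present in the file) `max_pae`.
#' @export
read_pae <- function(path) {
  if (!file.exists(path)) stop("PAE file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  # one-element list wrapper (AFDB download convention)
  if (is.list(obj) && is.null(names(obj)) && length(obj) == 1L) obj <- obj[[1L]]
  key <- intersect(c("pae", "predicted_aligned_error"), names(obj))
  if (length(key) == 0L)
    stop("no PAE field in ", path, ": expected 'pae' or ",
         "'predicted_aligned_error', found keys {",
         paste(names(obj), collapse = ", "), "}")
  values <- obj[[key[1L]]]
  if (is.list(values)) {
    lens <- lengths(values)
    if (length(unique(lens)) != 1L)
      stop("ragged PAE array in ", path, " (row lengths ",
           paste(unique(lens), collapse = ", "), ")")
    values <- do.call(rbind, values)
  }
  if (!is.matrix(values) || !is.numeric(values))
    stop("PAE field in ", path, " is not a 2-D numeric array")
  if (nrow(values) != ncol(values))
    stop("PAE matrix is not square: ", nrow(values), " x ", ncol(values))
  if (any(!is.finite(values)) || any(values < 0))
    stop("PAE entries must be finite and >= 0")
  max_pae <- NULL
  for (mk in c("max_pae", "max_predicted_aligned_error"))
    if (mk %in% names(obj)) max_pae <- as.numeric(obj[[mk]])[1L]
  if (!is.null(max_pae) && any(values > max_pae))
    stop("PAE entries exceed declared max_pae = ", max_pae)
  structure(unname(values), size = nrow(values), max_pae = max_pae,
            class = c("pae_matrix", "matrix", "array"))
}

#' @export
print.pae_matrix <- function(x, ...) {
  cat("<pae_matrix> ", attr(x, "size"), " x ", attr(x, "size"),
      if (!is.null(attr(x, "max_pae")))
        paste0(", max_pae ", attr(x, "max_pae")), "\n", sep = "")
  invisible(x)
}

#' Bind a structure to its PAE matrix
#'
#' Pairs one predicted model with its PAE matrix so that residue-pair PAE can
#' be looked up in both directions through the structure's concatenated
#' residue index.
#'
#' @param model an `afm_structure`.
#' @param pae a `pae_matrix` whose size equals the model's residue count.
#' @return A `bound_prediction` list with elements `structure` and `pae`.
#' @export
bind_prediction <- function(model, pae) {
  stopifnot(inherits(model, "afm_structure"))
  n <- n_residues(model)
  sz <- attr(pae, "size") %||% nrow(pae)
  if (sz != n)
    stop("PAE size ", sz, " != ", n, " residues")
  structure(list(structure = model, pae = pae), class = "bound_prediction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Directional PAE between two residues
#'
#' @param pred a `bound_prediction`.
#' @param res_a,res_b residue identifiers, either `"chain:resno"` strings
#'   (e.g. `"A:12"`) or length-2 vectors `c(chain, resno)`.
#' @return The PAE (Angstrom) for the ordered pair (res_a aligned, res_b
#'   measured); swap arguments for the other direction.
#' @export
pae_of <- function(pred, res_a, res_b) {
  stopifnot(inherits(pred, "bound_prediction"))
  i <- .resolve_residue(pred$structure, res_a)
  j <- .resolve_residue(pred$structure, res_b)
  pred$pae[i, j]
}

.resolve_residue <- function(model, res) {
  if (length(res) == 1L) res <- strsplit(res, ":", fixed = TRUE)[[1L]]
  if (length(res) != 2L)
    stop("residue must be 'chain:resno' or c(chain, resno)")
  r <- model$residues
  i <- which(r$chain == res[1L] & r$res_id == as.character(res[2L]))
  if (length(i) != 1L)
    stop("residue ", res[1L], ":", res[2L], " not found in model ",
         model$model_id)
  r$concat_idx[i]
}

#' @export
print.bound_prediction <- function(x, ...) {
  cat("<bound_prediction> model ", x$structure$model_id, ", ",
      n_residues(x$structure), " residues + PAE\n", sep = "")
  invisible(x)
}
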