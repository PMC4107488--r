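#' Parse a PDB structure into an atom table
#'
#' Reads ATOM records from a PDB file (or a character vector of PDB lines)
#' into a single-conformer atom table suitable for distance and
#' solvent-accessibility calculations. Only the first MODEL of a multi-model
#' file is kept, HETATM records and waters are dropped, and alternate
#' locations are resolved to the highest-occupancy conformer (ties broken by
#' first occurrence).
#'
#' @param source Path to a PDB file, or a character vector of PDB-format
#'   lines.
#' @param id Identifier stored on the returned object; defaults to the file
#'   name (or `"structure"` for in-memory text).
#' @return An object of class `pdb_structure`: a list with elements `id` and
#'   `atoms`, the latter a data frame with columns `chain`, `resno`, `icode`,
#'   `resname`, `atom`, `element`, `x`, `y`, `z`, `occupancy`.
#' @export
read_structure <- function(source, id = NULL) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(source))
  } else {
    lines <- unlist(strsplit(as.character(source), "\n", fixed = TRUE))
    if (is.null(id)) id <- "structure"
  }
  # first MODEL only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]

  is_atom <- grepl("^ATOM  ", lines)
  if (!any(is_atom)) stop("no ATOM records found in PDB input")

  # validate coordinate fields before handing off to the parser
  atom_idx <- which(is_atom)
  for (i in atom_idx) {
    coords <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    vals <- suppressWarnings(as.numeric(coords))
    if (anyNA(vals) || any(!is.finite(vals))) {
      stop(sprintf("malformed coordinate field in ATOM record at line %d", i))
    }
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records found in PDB input")

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1

  # altloc: keep the highest-occupancy record per (chain, resno, icode, atom)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, icode = at$insert,
    resname = at$resid, atom = at$elety,
    element = guess_element(at$elesy, at$elety),
    x = at$x, y = at$y, z = at$z, occupancy = pmin(pmax(at$o, 0), 1),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                       atoms$resno, atoms$icode), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "pdb_structure")
}

guess_element <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy) | trimws(elesy) == "",
                              substr(gsub("[0-9]", "", trimws(elety)), 1, 1),
                              elesy)))
  el[el == ""] <- "C"
  el
}

#' @export
print.pdb_structure <- function(x, ...) {
  ch <- table(unique(x$atoms[c("chain", "resno", "icode")])$chain)
  cat(sprintf("PDB structure '%s': %d atoms, %d chain(s)\n",
              x$id, nrow(x$atoms), length(ch)))
  for (nm in names(ch)) cat(sprintf("  chain %s: %d residues\n", nm, ch[[nm]]))
  invisible(x)
}

#' Positively charged residues of a chain
#'
#' Under acidic conditions histidine is protonated and counts as positively
#' charged alongside lysine and arginine; at neutral pH only Lys and Arg do.
#'
#' @param model A `pdb_structure`.
#' @param chain_id Chain identifier.
#' @param mode `"acidic"` (His, Lys, Arg) or `"neutral"` (Lys, Arg).
#' @return Data frame with one row per charged residue (`chain`, `resno`,
#'   `icode`, `resname`).
#' @export
charged_residue_set <- function(model, chain_id, mode = c("acidic", "neutral")) {
  mode <- match.arg(mode)
  at <- chain_atoms(model, chain_id)
  want <- if (mode == "acidic") c("HIS", "LYS", "ARG") else c("LYS", "ARG")
  res <- unique(at[at$resname %in% want, c("chain", "resno", "icode", "resname")])
  rownames(res) <- NULL
  res
}

chain_atoms <- function(model, chain_id) {
  stopifnot(inherits(model, "pdb_structure"))
  at <- model$atoms[model$atoms$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop(sprintf("chain '%s' not present in structure '%s'", chain_id, model$id))
  }
  at
}

residue_atoms <- function(model, chain_id, resno, icode = "") {
  at <- model$atoms
  at[at$chain == chain_id & at$resno == resno & at$icode == icode, ,
     drop = FALSE]
}

#' Minimum inter-residue atomic distance
#'
#' Minimum Euclidean distance over all atom pairs between two residues, the
#' convention of crystallographic contact programs. Accepts atom tables
#' (data frames with `x`, `y`, `z` columns).
#'
#' @param a,b Atom tables for the two residues.
#' @return Distance in Angstrom.
#' @export
min_residue_distance <- function(a, b) {
  if (NROW(a) == 0L || NROW(b) == 0L) stop("residue has no atoms")
  pa <- as.matrix(a[, c("x", "y", "z")])
  pb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  sqrt(max(0, min(d2)))
}

#' Per-residue minimum distances to the charged set of a target chain
#'
#' For every residue of the ligand chain, the minimum over all positively
#' charged residues of the target chain of the all-atom minimum distance.
#' This is the screen used to shortlist mutation positions near charge
#' centres of the binding partner.
#'
#' @param model A `pdb_structure`.
#' @param ligand_chain Chain whose residues are profiled.
#' @param target_chain Chain supplying the charged residues.
#' @inheritParams charged_residue_set
#' @return Data frame of class `distance_profile` with columns `resno`,
#'   `icode`, `resname`, `min_distance`, `nearest_charged` (e.g. `"HIS 435"`).
#' @export
distance_profile <- function(model, ligand_chain, target_chain,
                             mode = c("acidic", "neutral")) {
  mode <- match.arg(mode)
  lig <- chain_atoms(model, ligand_chain)
  charged <- charged_residue_set(model, target_chain, mode)
  if (nrow(charged) == 0L) {
    stop(sprintf(paste("no positively charged residues on chain '%s' in %s",
                       "mode; check the chain id and mode"),
                 target_chain, mode))
  }
  charged_atoms <- lapply(seq_len(nrow(charged)), function(i) {
    residue_atoms(model, target_chain, charged$resno[i], charged$icode[i])
  })
  key <- unique(lig[, c("resno", "icode", "resname")])
  out <- lapply(seq_len(nrow(key)), function(i) {
    ra <- residue_atoms(model, ligand_chain, key$resno[i], key$icode[i])
    d <- vapply(charged_atoms, function(ca) min_residue_distance(ra, ca),
                numeric(1))
    j <- which.min(d)
    data.frame(resno = key$resno[i], icode = key$icode[i],
               resname = key$resname[i], min_distance = d[j],
               nearest_charged = sprintf("%s %d%s", charged$resname[j],
                                         charged$resno[j], charged$icode[j]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("distance_profile", class(out))
  out
}

#' @export
print.distance_profile <- function(x, ...) {
  y <- as.data.frame(x)
  y$min_distance <- round(y$min_distance, 1)  # display convention; full
                                              # precision retained in object
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a distance profile as TSV
#'
#' @param profile A `distance_profile`.
#' @param path Output file path.
#' @export
write_distance_profile <- function(profile, path) {
  y <- as.data.frame(profile)
  y <- data.frame(residue_number = y$resno, res_name = y$resname,
                  min_distance_A = round(y$min_distance, 1),
                  nearest_charged = y$nearest_charged)
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
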