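# Toy-structure builders used across the structure and SASA tests.

pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     occ = 1, alt = " ", icode = " ",
                     record = "ATOM  ") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resn, chain, resno, icode,
          x, y, z, occ, 0, substr(name, 1, 1))
}

# build a pdb_structure object directly from an atom table
toy_model <- function(atoms, id = "toy") {
  atoms$icode <- if (is.null(atoms$icode)) "" else atoms$icode
  atoms$occupancy <- if (is.null(atoms$occupancy)) 1 else atoms$occupancy
  structure(list(id = id, atoms = atoms), class = "pdb_structure")
}

# random two-chain toy structure: chain B = ligand, chain A = target
random_model <- function(seed, n_lig = 4, n_tgt = 4, max_atoms = 3) {
  set.seed(seed)
  mk_chain <- function(chain, n_res, resnames) {
    do.call(rbind, lapply(seq_len(n_res), function(i) {
      k <- sample.int(max_atoms, 1)
      data.frame(chain = chain, resno = i, icode = "",
                 resname = sample(resnames, 1),
                 atom = paste0("C", seq_len(k)), element = "C",
                 x = stats::rnorm(k, 3 * i, 2), y = stats::rnorm(k, 0, 2),
                 z = stats::rnorm(k, 0, 2), occupancy = 1,
                 stringsAsFactors = FALSE)
    }))
  }
  lig <- mk_chain("B", n_lig, c("GLY", "ALA", "SER"))
  tgt <- mk_chain("A", n_tgt, c("HIS", "LYS", "ARG", "GLY", "ASP"))
  toy_model(rbind(lig, tgt))
}

# exhaustive double-loop oracle for the distance profile
brute_force_profile <- function(model, ligand_chain, target_chain, mode) {
  at <- model$atoms
  want <- if (mode == "acidic") c("HIS", "LYS", "ARG") else c("LYS", "ARG")
  tgt <- at[at$chain == target_chain & at$resname %in% want, ]
  lig <- at[at$chain == ligand_chain, ]
  vapply(unique(lig$resno), function(rn) {
    la <- lig[lig$resno == rn, ]
    best <- Inf
    for (trn in unique(tgt$resno)) {
      ta <- tgt[tgt$resno == trn, ]
      for (i in seq_len(nrow(la))) {
        for (j in seq_len(nrow(ta))) {
          d <- sqrt(sum((c(la$x[i], la$y[i], la$z[i]) -
                           c(ta$x[j], ta$y[j], ta$z[j]))^2))
          best <- min(best, d)
        }
      }
    }
    best
  }, numeric(1))
}

# analytic accessible area of sphere 1 (radius R1) occluded by sphere 2
# (radius R2) at centre distance d: full sphere minus the buried cap
two_sphere_accessible <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

single_atom_df <- function(x, y, z, resno = 1, resname = "ALA",
                           chain = "A", atom = "C1") {
  data.frame(chain = chain, resno = resno, icode = "", resname = resname,
             atom = atom, element = "C", x = x, y = y, z = z,
             occupancy = 1, stringsAsFactors = FALSE)
}
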