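#' Expand a degenerate (mixed) codon
#'
#' Expands a codon written in IUPAC nucleotide-ambiguity symbols to the full
#' set of plain codons it is synthesized as, and translates them under the
#' standard genetic code.
#'
#' @param codon A 3-character string of IUPAC symbols
#'   (A,C,G,T,R,Y,M,K,S,W,B,D,H,V,N).
#' @return List with `codons` (character vector of plain 3-mers, Cartesian
#'   product order) and `residues` (unique 1-letter amino-acid codes; `"*"`
#'   appears if a stop codon is encoded).
#' @examples
#' expand_degenerate_codon("YWT")$residues  # F, L, Y, H
#' @export
expand_degenerate_codon <- function(codon) {
  codon <- toupper(as.character(codon))
  if (length(codon) != 1L || nchar(codon) != 3L) {
    stop("codon must be a single 3-character string")
  }
  syms <- strsplit(codon, "")[[1L]]
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- setdiff(syms, names(map))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC symbol '%s' in codon '%s'", bad[1L], codon))
  }
  sets <- lapply(syms, function(s) strsplit(map[[s]], "")[[1L]])
  grid <- expand.grid(p3 = sets[[3L]], p2 = sets[[2L]], p1 = sets[[1L]],
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$p1, grid$p2, grid$p3)
  gc <- Biostrings::GENETIC_CODE
  list(codons = codons, residues = unique(unname(gc[codons])))
}

#' Default wild-type codon per amino acid
#'
#' The plain codon assumed to encode the wild-type residue in the gene being
#' scanned. For residues present in the scanned B-domain gene these are the
#' codons of that synthetic gene; the remainder are common E. coli codons.
#' Override per call in [design_mixed_codon()] when the actual gene sequence
#' is known.
#'
#' @return Named character vector keyed by 1-letter amino-acid code.
#' @export
default_wt_codons <- function() {
  c(A = "GCG", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGC",
    H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAC",
    P = "CCG", Q = "CAA", R = "CGC", S = "AGC", T = "ACC", V = "GTG",
    W = "TGG", Y = "TAT")
}

iupac_from_bases <- function(bases) {
  map <- Biostrings::IUPAC_CODE_MAP
  key <- paste(sort(unique(bases)), collapse = "")
  sym <- names(map)[vapply(map, function(m) {
    paste(sort(strsplit(m, "")[[1L]]), collapse = "") == key
  }, logical(1))]
  if (length(sym) == 0L) stop("no IUPAC symbol for base set ", key)
  sym[1L]
}

codon_union <- function(a, b) {
  paste(vapply(1:3, function(i) {
    iupac_from_bases(c(substr(a, i, i), substr(b, i, i)))
  }, character(1)), collapse = "")
}

codons_of <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == aa]
}

#' Design a wild-type-or-histidine mixed codon
#'
#' Builds the degenerate codon used at a scanned position: the positionwise
#' IUPAC union of the wild-type codon with a histidine codon, so that the
#' nucleotide mixture encodes at least the wild-type residue and histidine.
#' Because the mixture is a Cartesian product, some positions additionally
#' encode one or two bystander residues (e.g. TTT u CAT = YWT, which encodes
#' F, H, and also Y and L). Stop codons are never allowed: if the union with
#' the default codons encodes a stop, all wild-type codon / histidine codon
#' combinations are searched for a stop-free union minimizing first the
#' number of expanded codons, then the number of bystander residues.
#'
#' @param wt_residue 1-letter code of the wild-type residue. For histidine
#'   itself the two-codon mixture `"CAY"` is returned.
#' @param wt_codon Plain codon encoding the wild-type residue; defaults to
#'   [default_wt_codons()].
#' @param his_codon Histidine codon to mix in (`"CAT"` or `"CAC"`).
#' @return A 3-character IUPAC string.
#' @examples
#' design_mixed_codon("Q")  # "CAW"
#' design_mixed_codon("D")  # "SAT"
#' @export
design_mixed_codon <- function(wt_residue, wt_codon = NULL,
                               his_codon = "CAT") {
  wt_residue <- toupper(wt_residue)
  if (!wt_residue %in% names(default_wt_codons())) {
    stop(sprintf("'%s' is not a standard amino acid", wt_residue))
  }
  if (wt_residue == "H") return("CAY")
  if (is.null(wt_codon)) wt_codon <- default_wt_codons()[[wt_residue]]
  wt_codon <- toupper(wt_codon)
  his_codon <- toupper(his_codon)
  if (!wt_codon %in% codons_of(wt_residue)) {
    stop(sprintf("codon %s does not encode %s", wt_codon, wt_residue))
  }
  if (!his_codon %in% c("CAT", "CAC")) stop("his_codon must be CAT or CAC")

  cand <- codon_union(wt_codon, his_codon)
  if (!"*" %in% expand_degenerate_codon(cand)$residues) return(cand)

  # fallback: search all stop-free unions for this residue
  combos <- expand.grid(wt = codons_of(wt_residue), his = c("CAT", "CAC"),
                        stringsAsFactors = FALSE)
  best <- NULL
  best_score <- c(Inf, Inf)
  for (k in seq_len(nrow(combos))) {
    u <- codon_union(combos$wt[k], combos$his[k])
    ex <- expand_degenerate_codon(u)
    if ("*" %in% ex$residues) next
    score <- c(length(ex$codons),
               length(setdiff(ex$residues, c(wt_residue, "H"))))
    if (score[1] < best_score[1] ||
        (score[1] == best_score[1] && score[2] < best_score[2])) {
      best <- u
      best_score <- score
    }
  }
  if (is.null(best)) {
    stop(sprintf(
      "no stop-free degenerate codon covers %s and histidine", wt_residue))
  }
  best
}

#' Assemble a histidine-scanning library design
#'
#' @param position Integer vector of scanned positions (1-based residue
#'   numbering of the protein).
#' @param wt 1-letter wild-type residues at those positions.
#' @param codon Optional IUPAC mixed codons; computed with
#'   [design_mixed_codon()] when omitted.
#' @return Data frame of class `his_library_design` with columns `position`,
#'   `wt`, `codon`, `n_codons`, `encoded` (encoded residues as a string),
#'   `substituted` (encoded minus wild type).
#' @export
his_scan_design <- function(position, wt, codon = NULL) {
  stopifnot(length(position) == length(wt), length(position) >= 1L)
  wt <- toupper(wt)
  if (is.null(codon)) codon <- vapply(wt, design_mixed_codon, character(1))
  stopifnot(length(codon) == length(position))
  ex <- lapply(codon, expand_degenerate_codon)
  enc <- lapply(ex, `[[`, "residues")
  for (i in seq_along(position)) {
    if ("*" %in% enc[[i]]) {
      stop(sprintf("codon %s at position %d encodes a stop codon",
                   codon[i], position[i]))
    }
    if (!wt[i] %in% enc[[i]]) {
      stop(sprintf("codon %s at position %d does not encode wild type %s",
                   codon[i], position[i], wt[i]))
    }
    if (!"H" %in% enc[[i]]) {
      stop(sprintf("codon %s at position %d does not encode histidine",
                   codon[i], position[i]))
    }
  }
  out <- data.frame(
    position = as.integer(position), wt = wt, codon = toupper(codon),
    n_codons = vapply(ex, function(e) length(e$codons), integer(1)),
    encoded = vapply(enc, function(e) paste(sort(e), collapse = ""),
                     character(1)),
    substituted = mapply(function(e, w) {
      paste(sort(setdiff(e, w)), collapse = "")
    }, enc, wt),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("his_library_design", class(out))
  out
}

#' Encoded residue sets of a design
#' @param design A `his_library_design`.
#' @return List of character vectors, one per position.
#' @export
encoded_residues <- function(design) {
  stopifnot(inherits(design, "his_library_design"))
  strsplit(design$encoded, "")
}

#' Theoretical diversity of a mixed-codon library
#'
#' Exact products over positions of the number of distinct encoded amino
#' acids (protein-level diversity) and of the number of plain codons
#' (gene-level diversity).
#'
#' @param design A `his_library_design`.
#' @return List with `aa_diversity`, `codon_diversity`, and `aa_diversity_2sf`
#'   (2-significant-figure scientific rendering, e.g. `"2.5 x 10^7"`).
#' @export
library_diversity <- function(design) {
  stopifnot(inherits(design, "his_library_design"))
  if (nrow(design) == 0L) stop("empty design")
  aa <- prod(nchar(design$encoded))
  cod <- prod(design$n_codons)
  list(aa_diversity = aa, codon_diversity = cod,
       aa_diversity_2sf = format_sci2(aa))
}

format_sci2 <- function(x) {
  stopifnot(x > 0)
  e <- floor(log10(x))
  m <- signif(x / 10^e, 2)
  if (m >= 10) {
    m <- m / 10
    e <- e + 1
  }
  sprintf("%s x 10^%d", format(m), e)
}

#' Splice mixed codons into a coding sequence
#'
#' Replaces the codon at each designed position of a template CDS with the
#' design's degenerate symbols, yielding the degenerate oligonucleotide
#' ordered for library synthesis.
#'
#' @param design A `his_library_design`.
#' @param template_cds Nucleotide string, length divisible by 3; codon i
#'   encodes residue i.
#' @return Degenerate nucleotide string.
#' @export
emit_library_oligos <- function(design, template_cds) {
  template_cds <- toupper(as.character(template_cds))
  if (nchar(template_cds) %% 3 != 0) {
    stop("template length must be divisible by 3")
  }
  n_codons <- nchar(template_cds) / 3
  if (inherits(design, "his_library_design") && nrow(design)) {
    if (any(design$position < 1 | design$position > n_codons)) {
      stop("design position outside template")
    }
    for (i in seq_len(nrow(design))) {
      p <- design$position[i]
      substr(template_cds, 3 * p - 2, 3 * p) <- design$codon[i]
    }
  }
  template_cds
}

#' @export
print.his_library_design <- function(x, ...) {
  cat(sprintf("Histidine-scanning library design: %d positions\n", nrow(x)))
  print(as.data.frame(x), row.names = FALSE)
  div <- library_diversity(x)
  cat(sprintf("amino-acid diversity %s (%s); codon diversity %s\n",
              format(div$aa_diversity, big.mark = ","), div$aa_diversity_2sf,
              format(div$codon_diversity, big.mark = ",")))
  invisible(x)
}

#' Write a library design as TSV
#' @param design A `his_library_design`.
#' @param path Output file path.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a library design from TSV
#' @param path File written by [write_design()].
#' @return A `his_library_design`.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  his_scan_design(d$position, d$wt, d$codon)
}
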