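#' Deduplicate a round's sequences
#'
#' Order-preserving deduplication with the unique/total ratio used to track
#' library collapse.
#'
#' @param sequences Character vector of clone sequences over the designed
#'   positions (equal lengths required).
#' @return List with `unique` (character vector), `n_unique`, `n_total`,
#'   `ratio`.
#' @export
unique_sequences <- function(sequences) {
  if (length(sequences) == 0L) stop("empty sample")
  len <- nchar(sequences)
  if (length(unique(len)) != 1L) {
    stop(sprintf("sequence %d has inconsistent length",
                 which(len != len[1L])[1L]))
  }
  u <- unique(sequences)
  list(unique = u, n_unique = length(u), n_total = length(sequences),
       ratio = length(u) / length(sequences))
}

#' Per-position wild-type / histidine / other frequencies
#'
#' Tallies, at every designed position, the fraction of sequences carrying
#' the wild-type residue, a histidine, or anything else. By default the
#' tally runs over unique sequences (each distinct clone counted once), the
#' denominator used in the reference analysis; set `dedup = FALSE` to weight
#' by read counts. At a position whose wild type is histidine the His
#' category is folded into WT so the three categories stay disjoint.
#' Residues outside the position's encoded set (sequencing errors) are
#' counted as "other" with a warning.
#'
#' @param sequences Character vector of clone sequences.
#' @param design A `his_library_design`.
#' @param dedup Analyse unique sequences (default) or all reads.
#' @return Data frame of class `frequency_table` with columns `position`,
#'   `wt`, `freq_wt`, `freq_his`, `freq_other`, `n_sequences`.
#' @export
position_frequencies <- function(sequences, design, dedup = TRUE) {
  stopifnot(inherits(design, "his_library_design"))
  us <- unique_sequences(sequences)
  seqs <- if (dedup) us$unique else sequences
  if (nchar(seqs[1L]) != nrow(design)) {
    stop("sequence length does not match the number of designed positions")
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  sets <- encoded_residues(design)
  n <- length(seqs)
  out <- lapply(seq_len(nrow(design)), function(j) {
    col <- mat[, j]
    wt <- design$wt[j]
    stray <- setdiff(unique(col), sets[[j]])
    if (length(stray)) {
      warning(sprintf(
        "position %d: residue(s) %s outside the encoded set, counted as other",
        design$position[j], paste(stray, collapse = ",")), call. = FALSE)
    }
    f_wt <- mean(col == wt)
    f_his <- if (wt == "H") 0 else mean(col == "H")
    data.frame(position = design$position[j], wt = wt, freq_wt = f_wt,
               freq_his = f_his, freq_other = 1 - f_wt - f_his,
               n_sequences = n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("frequency_table", class(out))
  out
}

#' Call effective and essential histidine sites
#'
#' A position is called `effective` (a good histidine-mutation site) when
#' its histidine frequency after selection is strictly above the high
#' threshold, and `essential` (the wild-type residue is required for
#' binding) when strictly below the low threshold; boundary values are
#' `neutral`.
#'
#' @param freqs A `frequency_table`.
#' @param hi,lo Thresholds (defaults 0.70 and 0.20).
#' @return Data frame with columns `position`, `freq_his`, `call`.
#' @export
call_sites <- function(freqs, hi = 0.70, lo = 0.20) {
  stopifnot(inherits(freqs, "frequency_table"), lo <= hi)
  call <- ifelse(freqs$freq_his > hi, "effective",
                 ifelse(freqs$freq_his < lo, "essential", "neutral"))
  data.frame(position = freqs$position, freq_his = freqs$freq_his,
             call = call, stringsAsFactors = FALSE)
}

#' Frequency trajectories across panning rounds
#'
#' @param samples A `panning_run` or list of per-round sequence vectors
#'   (element 1 = round 0); at least two rounds.
#' @param design A `his_library_design`.
#' @param dedup Passed to [position_frequencies()].
#' @return Data frame: one `frequency_table` row per position per round,
#'   with a `round` column.
#' @export
enrichment_trajectory <- function(samples, design, dedup = TRUE) {
  if (inherits(samples, "panning_run")) samples <- samples$samples
  if (length(samples) < 2L) stop("need at least two rounds of samples")
  out <- lapply(seq_along(samples), function(i) {
    ft <- position_frequencies(samples[[i]], design, dedup = dedup)
    cbind(round = i - 1L, as.data.frame(ft))
  })
  do.call(rbind, out)
}

#' Write a frequency table (or trajectory) as TSV
#' @param freqs Data frame from [position_frequencies()] or
#'   [enrichment_trajectory()].
#' @param path Output file path.
#' @export
write_frequencies <- function(freqs, path) {
  utils::write.table(as.data.frame(freqs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
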