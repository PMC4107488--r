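#' Build a synthetic variant pool from a library design
#'
#' Draws variant sequences over the designed positions, each position
#' sampled uniformly from its encoded residue set, and assigns each variant
#' an additive log-affinity score from a per-position effect model. This is
#' the synthetic stand-in for the physical phage library.
#'
#' @param design A `his_library_design`.
#' @param n_variants Number of variants to draw.
#' @param effect_model Named list keyed by position (as character), each
#'   element a named numeric vector of per-residue log-affinity
#'   contributions; missing entries contribute 0. `NULL` means all zero.
#' @param seed Integer seed; fixed seed gives an identical pool.
#' @param unique If `TRUE`, variants are deduplicated and exactly
#'   `n_variants` distinct sequences are returned (error if `n_variants`
#'   exceeds the design's amino-acid diversity).
#' @return Data frame of class `variant_pool` with columns `sequence`,
#'   `log_affinity`, `count`.
#' @export
build_synthetic_library <- function(design, n_variants, effect_model = NULL,
                                    seed = 1L, unique = FALSE) {
  stopifnot(inherits(design, "his_library_design"), n_variants >= 1)
  sets <- encoded_residues(design)
  if (unique && n_variants > library_diversity(design)$aa_diversity) {
    stop("n_variants exceeds the design's amino-acid diversity")
  }
  set.seed(seed)
  draw <- function(k) {
    m <- vapply(sets, function(s) s[sample.int(length(s), k, replace = TRUE)],
                character(k))
    if (k == 1L) m <- matrix(m, nrow = 1L)
    apply(m, 1L, paste, collapse = "")
  }
  seqs <- draw(n_variants)
  if (unique) {
    seqs <- unique(seqs)
    guard <- 0L
    while (length(seqs) < n_variants && guard < 1000L) {
      seqs <- unique(c(seqs, draw(n_variants)))
      guard <- guard + 1L
    }
    seqs <- seqs[seq_len(n_variants)]
  }
  tab <- table(seqs)
  pool <- data.frame(sequence = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  pool$log_affinity <- variant_log_affinity(pool$sequence, design,
                                            effect_model)
  pool <- pool[, c("sequence", "log_affinity", "count")]
  rownames(pool) <- NULL
  class(pool) <- c("variant_pool", class(pool))
  pool
}

variant_log_affinity <- function(sequences, design, effect_model) {
  if (is.null(effect_model)) return(numeric(length(sequences)))
  mat <- do.call(rbind, strsplit(sequences, ""))
  score <- numeric(length(sequences))
  for (j in seq_len(nrow(design))) {
    eff <- effect_model[[as.character(design$position[j])]]
    if (is.null(eff)) next
    hit <- eff[mat[, j]]
    hit[is.na(hit)] <- 0
    score <- score + unname(hit)
  }
  score
}

#' Panning configuration
#'
#' @param rounds Number of selection rounds.
#' @param capture_capacity Per-round number of phage-capture sites; a
#'   decreasing vector models the increasing stringency of offering less
#'   immobilized antibody each round. Recycled/validated to `rounds`.
#' @param wash_survival Probability that a non-captured phage survives the
#'   washes into the eluate (background binding).
#' @param amplification_noise Standard deviation of the lognormal
#'   amplification bias applied per variant per round.
#' @param clones_sequenced Clones sequenced per round; length `rounds + 1`
#'   (element 1 samples the unselected library). Defaults to the reference
#'   screen's depths ([pab_round_depths()]).
#' @param pool_size Number of phage particles carried after amplification.
#' @param beta Selection sharpness multiplying log-affinities in the capture
#'   weights (softmax inverse temperature).
#' @param seed Integer seed for all random draws.
#' @return List of class `panning_config`.
#' @export
panning_config <- function(rounds = 5L,
                           capture_capacity = NULL,
                           wash_survival = 1e-3,
                           amplification_noise = 0.3,
                           clones_sequenced = pab_round_depths(),
                           pool_size = 1e5,
                           beta = 1,
                           seed = 1L) {
  rounds <- as.integer(rounds)
  stopifnot(rounds >= 1L, wash_survival >= 0, wash_survival <= 1,
            amplification_noise >= 0, pool_size >= 1)
  if (is.null(capture_capacity)) {
    capture_capacity <- round(0.2 * pool_size * 0.5^(seq_len(rounds) - 1L))
  }
  if (length(capture_capacity) == 1L) {
    capture_capacity <- rep(capture_capacity, rounds)
  }
  stopifnot(length(capture_capacity) == rounds, all(capture_capacity > 0))
  if (length(clones_sequenced) == rounds) {
    clones_sequenced <- c(clones_sequenced[1L], clones_sequenced)
  }
  stopifnot(length(clones_sequenced) == rounds + 1L)
  structure(list(rounds = rounds, capture_capacity = capture_capacity,
                 wash_survival = wash_survival,
                 amplification_noise = amplification_noise,
                 clones_sequenced = as.integer(clones_sequenced),
                 pool_size = pool_size, beta = beta, seed = as.integer(seed)),
            class = "panning_config")
}

draw_clones <- function(counts, k, sequences) {
  total <- sum(counts)
  k <- min(k, total)
  if (k == total) return(rep.int(sequences, counts))
  idx <- sample.int(total, k)  # without replacement over individual phages
  cum <- cumsum(counts)
  sequences[findInterval(idx - 1L, c(0L, cum), rightmost.closed = TRUE)]
}

#' Simulate multi-round affinity selection (panning)
#'
#' Each round: capacity-limited multinomial capture with weights
#' proportional to `count * exp(beta * log_affinity)`; non-captured phages
#' leak through the washes with probability `wash_survival`; the eluate is
#' amplified back to `pool_size` with per-variant lognormal bias; a fixed
#' number of clones is sequenced (drawn without replacement) from the
#' amplified pool. Pool extinction is flagged, not an error.
#'
#' @param pool A `variant_pool` (the initial library).
#' @param config A `panning_config`.
#' @return Object of class `panning_run`: list with `pools` (per-round count
#'   tables, element 1 = initial), `samples` (per-round sequenced clone
#'   vectors, element 1 = initial library), `extinct_at` (`NA` or the round
#'   at which the pool died), `config`.
#' @export
run_panning <- function(pool, config = panning_config()) {
  stopifnot(inherits(pool, "variant_pool"), inherits(config, "panning_config"))
  if (sum(pool$count) == 0) stop("initial pool is empty")
  set.seed(config$seed)
  seqs <- pool$sequence
  a <- pool$log_affinity
  w_sel <- exp(config$beta * (a - max(a)))  # stabilized softmax weights

  # amplify the library up to pool_size before the first sampling
  n <- as.vector(stats::rmultinom(1L, config$pool_size,
                                  prob = pool$count / sum(pool$count)))
  pools <- list(pool_table(seqs, n, a))
  samples <- list(sort_clone_sample(
    draw_clones(n, config$clones_sequenced[1L], seqs)))
  extinct_at <- NA_integer_

  for (r in seq_len(config$rounds)) {
    w <- n * w_sel
    if (sum(w) == 0) w <- n
    # per-phage capture probability: softmax weight scaled so the expected
    # number of captures equals the round's capacity
    p_cap <- pmin(1, config$capture_capacity[r] * w_sel / sum(w))
    captured <- stats::rbinom(length(n), n, p_cap)
    leak <- stats::rbinom(length(n), n - captured, config$wash_survival)
    eluate <- captured + leak
    if (sum(eluate) == 0) {
      extinct_at <- r
      break
    }
    bias <- exp(stats::rnorm(length(n), 0, config$amplification_noise))
    q <- eluate * bias
    n <- as.vector(stats::rmultinom(1L, config$pool_size, prob = q / sum(q)))
    pools[[r + 1L]] <- pool_table(seqs, n, a)
    samples[[r + 1L]] <- sort_clone_sample(
      draw_clones(n, config$clones_sequenced[r + 1L], seqs))
  }
  structure(list(pools = pools, samples = samples, extinct_at = extinct_at,
                 config = config),
            class = "panning_run")
}

pool_table <- function(seqs, n, a) {
  keep <- n > 0L
  data.frame(sequence = seqs[keep], count = n[keep],
             log_affinity = a[keep],
             frequency = n[keep] / sum(n),
             stringsAsFactors = FALSE)
}

# deterministic order within a sample (the draw itself is random)
sort_clone_sample <- function(x) sort(x)

#' @export
print.panning_run <- function(x, ...) {
  cat(sprintf("Panning run: %d round(s), pool size %g\n",
              x$config$rounds, x$config$pool_size))
  if (!is.na(x$extinct_at)) {
    cat(sprintf("  pool went extinct at round %d\n", x$extinct_at))
  }
  print(unique_ratio_trajectory(x), row.names = FALSE)
  invisible(x)
}

round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Unique-sequence ratio per sequenced round
#'
#' Diversity collapse under selection, tracked as the share of distinct
#' sequences among the clones sequenced after each round. Two renderings of
#' the percentage are reported: `percent` (round half up, 1 decimal) and
#' `percent_trunc` (truncated at 1 decimal), since published values have
#' used either convention (18/93 = 19.35...% prints as 19.4 or 19.3).
#'
#' @param samples A `panning_run` or a list of per-round character vectors
#'   of sequences (element 1 = round 0).
#' @return Data frame with columns `round`, `unique`, `total`, `percent`,
#'   `percent_trunc`.
#' @export
unique_ratio_trajectory <- function(samples) {
  if (inherits(samples, "panning_run")) samples <- samples$samples
  stopifnot(length(samples) >= 1L)
  out <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    if (length(s) == 0L) stop(sprintf("round %d sample is empty", i - 1L))
    u <- length(unique(s))
    t <- length(s)
    data.frame(round = i - 1L, unique = u, total = t,
               percent = round_half_up(100 * u / t, 1L),
               percent_trunc = floor(1000 * u / t) / 10)
  })
  do.call(rbind, out)
}

#' Write per-round sequenced clones as FASTA
#'
#' One file per round (`round_0.fasta` for the initial library, then
#' `round_1.fasta`, ...), sequences written over the designed positions.
#' Byte-identical output for a fixed simulation seed.
#'
#' @param run A `panning_run`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_round_fasta <- function(run, dir) {
  stopifnot(inherits(run, "panning_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(run$samples)) {
    path <- file.path(dir, sprintf("round_%d.fasta", i - 1L))
    s <- run$samples[[i]]
    writeLines(as.vector(rbind(
      sprintf(">round%d_clone%04d", i - 1L, seq_along(s)), s)), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read per-round clone sequences from FASTA files
#'
#' @param paths FASTA file paths in round order.
#' @return List of character vectors of sequences.
#' @export
read_round_fasta <- function(paths) {
  lapply(paths, function(p) {
    x <- Biostrings::readBStringSet(p)
    unname(as.character(x))
  })
}
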