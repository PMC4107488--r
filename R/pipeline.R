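#' Reference effect model for panning simulations
#'
#' Additive per-position log-affinity contributions emulating the selection
#' outcome of the reference screen: at the effective-site positions
#' histidine carries a bonus, and at the essential (interface) positions any
#' departure from wild type carries a penalty.
#'
#' @param design A `his_library_design` (default [pab_library_design()]).
#' @param effective Positions where His is advantaged.
#' @param essential Positions where non-wild-type residues are penalized.
#' @param delta Magnitude of the per-position contribution (log units).
#' @return Effect model in the format of [build_synthetic_library()].
#' @export
pab_effect_model <- function(design = pab_library_design(),
                             effective = c(9, 10, 27, 35, 36),
                             essential = c(13, 14, 17, 24, 31),
                             delta = 3) {
  model <- list()
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in seq_len(nrow(design))) {
    p <- design$position[i]
    eff <- stats::setNames(numeric(length(aas)), aas)
    if (p %in% effective) eff[["H"]] <- delta
    if (p %in% essential) eff[setdiff(aas, design$wt[i])] <- -delta
    model[[as.character(p)]] <- eff
  }
  model
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory for stage files.
#' @param seed Master seed; every random stage derives its own seed from it.
#' @param pdb Optional path to a PDB file of the ligand-target complex.
#' @param ligand_chain,target_chain Chain ids used for the structure stage.
#' @param mode Charge mode for the distance screen.
#' @param n_variants Synthetic library size for the panning stage.
#' @param delta Selection strength of the planted effect model.
#' @param panning A [panning_config()] (its seed is overridden).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("hisscan_run_"), seed = 1L,
                            pdb = NULL, ligand_chain = "B",
                            target_chain = "A", mode = "acidic",
                            n_variants = 20000L, delta = 3,
                            panning = panning_config()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), pdb = pdb,
                 ligand_chain = ligand_chain, target_chain = target_chain,
                 mode = mode, n_variants = as.integer(n_variants),
                 delta = delta, panning = panning),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any of the [pipeline_config()] fields (the
#'   `panning` block maps onto [panning_config()] arguments).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pan <- do.call(panning_config, if (is.null(y$panning)) list() else
    y$panning)
  y$panning <- NULL
  do.call(pipeline_config, c(y, list(panning = pan)))
}

#' Run the full histidine-scanning analysis pipeline on synthetic data
#'
#' Executes, deterministically for a given seed: the library design stage;
#' the structure stage (distance profile and fSASA) when a PDB file is
#' supplied, otherwise skipped with a warning; panning simulation on a
#' synthetic library with the planted effect model; enrichment analysis and
#' effective/essential site calling; two-state melting simulation and
#' refitting for every characterized variant; 1:1 sensorgram simulation and
#' global refitting; and elution simulation with peak-pH detection. Stage
#' tables are written as TSV under `config$out_dir`.
#'
#' @param config A `pipeline_config` or path to a YAML file.
#' @return Object of class `hisscan_report`: list of the five report tables
#'   (`design`, `calls`, `stability`, `affinity`, `elution`) plus
#'   `unique_ratios` and the echoed `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config[setdiff(names(config), "panning")]),
                   file.path(config$out_dir, "config_echo.yaml"))

  design <- pab_library_design()
  write_design(design, file.path(config$out_dir, "design.tsv"))

  if (!is.null(config$pdb) && file.exists(config$pdb)) {
    model <- read_structure(config$pdb)
    dp <- distance_profile(model, config$ligand_chain, config$target_chain,
                           config$mode)
    write_distance_profile(dp, file.path(config$out_dir, "distances.tsv"))
    fp <- compute_fsasa(model, config$ligand_chain)
    write_fsasa_profile(fp, file.path(config$out_dir, "fsasa.tsv"))
  } else {
    if (!is.null(config$pdb)) {
      warning("PDB file not found; structure stage skipped", call. = FALSE)
    }
    dp <- NULL
  }

  eff <- pab_effect_model(design, delta = config$delta)
  pool <- build_synthetic_library(design, config$n_variants, eff,
                                  seed = config$seed)
  pan_cfg <- config$panning
  pan_cfg$seed <- config$seed + 1L
  run <- run_panning(pool, pan_cfg)
  write_round_fasta(run, file.path(config$out_dir, "rounds"))
  ratios <- unique_ratio_trajectory(run)
  write_frequencies(ratios, file.path(config$out_dir, "unique_ratios.tsv"))

  traj <- enrichment_trajectory(run, design)
  write_frequencies(traj, file.path(config$out_dir, "frequencies.tsv"))
  final_freqs <- position_frequencies(run$samples[[length(run$samples)]],
                                      design)
  calls <- call_sites(final_freqs)
  utils::write.table(calls, file.path(config$out_dir, "site_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  variants <- pab_variants()
  stab <- variants[!is.na(variants$tm_K), c("protein", "mutations", "tm_K")]
  stab$tm_fit <- NA_real_
  for (i in seq_len(nrow(stab))) {
    cur <- simulate_melting_curve(tm = stab$tm_K[i], dHm = 230,
                                  noise_sd = 0.2,
                                  seed = config$seed + 100L + i)
    stab$tm_fit[i] <- coef(fit_two_state(cur))[["tm"]]
  }
  stab$delta_tm <- delta_tm(stab$tm_fit, stab$tm_fit[1L])
  utils::write.table(stab, file.path(config$out_dir, "stability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  aff <- variants[, c("protein", "mutations", "kD_pH7.4")]
  aff$kD_fit <- NA_real_
  for (i in seq_len(nrow(aff))) {
    kD <- aff$kD_pH7.4[i]
    concs <- kD * c(0.3, 1, 3, 10)
    sg <- simulate_sensorgram_set(ka = 1e5, kd = 1e5 * kD, rmax = 100,
                                  concs = concs, noise_sd = 0.5,
                                  seed = config$seed + 200L + 10L * i)
    f <- fit_one_to_one(sg)
    if (!f$censored) aff$kD_fit[i] <- f$kD
  }
  aff$kD_ratio <- kd_ratio(aff$kD_fit, aff$kD_fit[1L])
  utils::write.table(aff, file.path(config$out_dir, "affinity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  elu <- variants[!is.na(variants$elution_peak_pH),
                  c("protein", "mutations", "elution_peak_pH")]
  elu$peak_pH_detected <- NA_real_
  for (i in seq_len(nrow(elu))) {
    tr <- simulate_elution(elu$elution_peak_pH[i],
                           seed = config$seed + 300L + i)
    res <- detect_peak_ph(tr)
    if (!res$no_elution) elu$peak_pH_detected[i] <- res$peak_pH
  }
  elu$delta_pH <- delta_ph(elu$peak_pH_detected, elu$peak_pH_detected[1L])
  utils::write.table(elu, file.path(config$out_dir, "elution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  structure(list(design = design, unique_ratios = ratios, calls = calls,
                 stability = stab, affinity = aff, elution = elu,
                 distance_profile = dp, config = config),
            class = "hisscan_report")
}

#' @export
print.hisscan_report <- function(x, ...) {
  cat("== Histidine-scanning pipeline report ==\n\n")
  cat(sprintf("Library: %d positions, amino-acid diversity %s\n\n",
              nrow(x$design), library_diversity(x$design)$aa_diversity_2sf))
  cat("Unique-sequence ratios per round:\n")
  print(x$unique_ratios, row.names = FALSE)
  cat("\nSite calls (final round):\n")
  print(x$calls, row.names = FALSE)
  cat("\nStability (simulated and refit):\n")
  print(x$stability, row.names = FALSE)
  cat("\nAffinity (simulated and refit):\n")
  print(x$affinity, row.names = FALSE)
  cat("\nElution (simulated and redetected):\n")
  print(x$elution, row.names = FALSE)
  invisible(x)
}
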