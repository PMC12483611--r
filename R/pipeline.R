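#' Read and validate a pipeline configuration
#'
#' The YAML config either points at real input files or carries a
#' `synthetic` block (cohort / repertoire / serology / hto sub-blocks).
#' A seed is mandatory whenever the synthetic block is present.
#'
#' @param path YAML file.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a config list (already parsed).
#' @export
validate_pipeline_config <- function(cfg) {
  has_synth <- !is.null(cfg$synthetic)
  has_inputs <- !is.null(cfg$inputs)
  if (!has_synth && !has_inputs) {
    stop("pipeline config: need either `synthetic` block or `inputs` paths",
         call. = FALSE)
  }
  if (has_synth && is.null(cfg$seed)) {
    stop("pipeline config: `seed` is mandatory with a synthetic block",
         call. = FALSE)
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

default_pipeline_config <- function(seed = 1L) {
  validate_pipeline_config(list(
    seed = seed,
    synthetic = list(
      cohort = list(),
      repertoire = list(cells_per_subject = 40L),
      serology = list(),
      hto = list(n_cells = 500L, doublet_rate = 0.05)
    ),
    qc = list(mito_max = 10, feat_min = 200L, feat_max = 6500L, hto_margin = 2.0),
    clones = list(distance_threshold = 0.15),
    proportions = list(group_a = "healthy", group_b = "anti-TNF",
                       n_perm = 1000L, n_boot = 500L)
  ))
}

#' Run the full analysis pipeline from one configuration
#'
#' Stages, in dependency order: simulate (repertoire, serology plates, QC
#' and HTO matrices), qc (cell filtering + hashtag demultiplexing),
#' repertoire (clones, SHM profiles, diversity, gene usage, isotypes,
#' clone-size bins), proportions (subset permutation test), serology
#' (EC50 fits and avidity scores), association (SHM-TRAI model and group
#' comparisons). Every intermediate table is written as CSV/TSV under
#' `out_dir`, together with a JSON run manifest (config hash, seed,
#' package version, per-stage row counts). Identical config and seed
#' reproduce identical outputs.
#'
#' @param config a `pipeline_config` (see [read_pipeline_config()]) or a
#'   path to a YAML file.
#' @param out_dir output directory, created if missing.
#' @return invisibly, a list with all stage outputs and the manifest.
#' @export
run_pipeline <- function(config, out_dir = tempfile("gcoutput_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "gcoutput",
                   version = as.character(utils::packageVersion("gcoutput")),
                   seed = config$seed, stages = list())
  tmp_yaml <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), tmp_yaml)
  manifest$config_md5 <- unname(tools::md5sum(tmp_yaml))

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  # --- simulate ---------------------------------------------------------
  syn <- config$synthetic
  cohort <- do.call(cohort_config, c(syn$cohort, list(seed = config$seed)))
  repcfg <- do.call(repertoire_config, syn$repertoire %||% list())
  sercfg <- do.call(serology_config, syn$serology %||% list())
  hto_args <- syn$hto %||% list(n_cells = 500L, doublet_rate = 0.05)
  records <- stage("simulate", gen_repertoire(cohort, repcfg))
  sero <- stage("simulate", gen_serology_cohort(cohort, sercfg))
  htoqc <- stage("simulate", do.call(gen_hto_qc, c(
    list(cohort = cohort), hto_args, list(seed = config$seed + 13L))))
  write_airr(records, file.path(out_dir, "repertoire.tsv"))
  utils::write.csv(sero$chaotrope, file.path(out_dir, "chaotrope_plates.csv"),
                   row.names = FALSE)
  utils::write.csv(sero$dilution, file.path(out_dir, "dilution_plates.csv"),
                   row.names = FALSE)
  utils::write.csv(htoqc$qc, file.path(out_dir, "cell_qc.csv"), row.names = FALSE)
  write_hto_csv(htoqc$hto, file.path(out_dir, "hto_counts.csv"))
  manifest$stages$simulate <- list(n_records = nrow(records),
                                   n_chaotrope_rows = nrow(sero$chaotrope),
                                   n_cells = nrow(htoqc$qc))

  # --- qc ---------------------------------------------------------------
  qc_par <- do.call(cell_qc_params, config$qc %||% list())
  filt <- stage("qc", filter_cells(htoqc$qc, qc_par))
  demux <- stage("qc", demux_hashtags(htoqc$hto, margin = qc_par$hto_margin))
  utils::write.csv(filt$tally, file.path(out_dir, "qc_tally.csv"), row.names = FALSE)
  utils::write.csv(demux, file.path(out_dir, "demux.csv"), row.names = FALSE)
  manifest$stages$qc <- list(n_retained = length(filt$retained),
                             n_singlet = sum(demux$status == "singlet"))

  # --- repertoire -------------------------------------------------------
  records <- stage("repertoire", filter_contigs(records))
  heavy <- records[records$chain == "heavy", , drop = FALSE]
  clones <- stage("repertoire", assign_clones(
    heavy, distance_threshold = config$clones$distance_threshold %||% 0.15))
  shm <- stage("repertoire", shm_profiles(records, repcfg$region_layout))
  div <- stage("repertoire", do.call(rbind, lapply(cohort$groups, function(g) {
    ids <- clones$clones$clone_id[match(heavy$sequence_id[heavy$group == g],
                                        clones$clones$sequence_id)]
    diversity_profile(ids, n_boot = 100L, seed = config$seed, label = g)
  })))
  usage <- stage("repertoire", gene_usage(records))
  iso <- stage("repertoire", isotype_fractions(heavy, group_by = "group"))
  meta <- unique(heavy[, c("cell_id", "subject", "timepoint")])
  bins <- stage("repertoire", clone_size_bins(clones, meta))
  utils::write.csv(clones$clones, file.path(out_dir, "clones.csv"), row.names = FALSE)
  utils::write.csv(shm, file.path(out_dir, "shm_profiles.csv"), row.names = FALSE)
  utils::write.csv(div, file.path(out_dir, "diversity.csv"), row.names = FALSE)
  utils::write.csv(usage$usage, file.path(out_dir, "gene_usage.csv"), row.names = FALSE)
  utils::write.csv(iso$fractions, file.path(out_dir, "isotype_fractions.csv"),
                   row.names = FALSE)
  utils::write.csv(bins, file.path(out_dir, "clone_size_bins.csv"), row.names = FALSE)
  manifest$stages$repertoire <- list(n_clones = length(unique(clones$clones$clone_id)),
                                     n_heavy = nrow(heavy))

  # --- proportions ------------------------------------------------------
  pcfg <- config$proportions %||% list()
  cells <- data.frame(cluster = heavy$subset, group = heavy$group,
                      stringsAsFactors = FALSE)
  prop <- stage("proportions", proportion_test(
    cells, pcfg$group_a %||% cohort$groups[1],
    pcfg$group_b %||% cohort$groups[length(cohort$groups)],
    n_perm = pcfg$n_perm %||% 1000L, n_boot = pcfg$n_boot %||% 500L,
    seed = config$seed + 29L))
  utils::write.csv(prop, file.path(out_dir, "proportion_test.csv"), row.names = FALSE)
  manifest$stages$proportions <- list(n_clusters = nrow(prop))

  # --- serology ---------------------------------------------------------
  avidity <- stage("serology", score_avidity_table(sero$chaotrope))
  ec50 <- stage("serology", fit_ec50_table(sero$dilution, blank_od = 0.04))
  utils::write.csv(avidity, file.path(out_dir, "avidity.csv"), row.names = FALSE)
  utils::write.csv(ec50, file.path(out_dir, "ec50.csv"), row.names = FALSE)
  manifest$stages$serology <- list(n_samples = nrow(avidity),
                                   n_fit_ok = sum(ec50$status == "ok"))

  # --- association ------------------------------------------------------
  summ <- stage("association", subject_summary(shm, avidity))
  assoc <- stage("association", ols_fit(summ, "trai", c("mean_shm", "dose"),
                                        cluster = "subject"))
  kw <- stage("association", group_compare(
    shm$mu_freq[shm$chain == "heavy"], shm$group[shm$chain == "heavy"]))
  utils::write.csv(summ, file.path(out_dir, "subject_summary.csv"), row.names = FALSE)
  utils::write.csv(assoc$coefficients, file.path(out_dir, "association.csv"),
                   row.names = FALSE)
  manifest$stages$association <- list(
    shm_trai_slope = assoc$coefficients$estimate[assoc$coefficients$term == "mean_shm"],
    kw_p = kw$p_value)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(records = records, clones = clones, shm = shm,
                 diversity = div, usage = usage, isotypes = iso, bins = bins,
                 proportions = prop, avidity = avidity, ec50 = ec50,
                 qc = filt, demux = demux, summary = summ,
                 association = assoc, group_compare = kw,
                 serology_truth = sero$truth, manifest = manifest,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
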