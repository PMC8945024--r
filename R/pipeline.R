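## Comparison schedule shared by both assays: target/reference pairs at one
## timepoint, mirroring the published cut-off table.
comparison_schedule <- function(timepoint_h) {
  defs <- list(
    c("RPMI", "ZERO_H"), c("T3", "RPMI"), c("T3", "ZERO_H"),
    c("LPS", "RPMI"), c("LPS", "ZERO_H"),
    c("T3_LPS", "T3"), c("T3_LPS", "RPMI"), c("T3_LPS", "ZERO_H"),
    c("T3_LPS", "LPS")
  )
  lapply(defs, function(d) comparison(d[1], d[2], timepoint_h))
}

## Category sets from a comparison table at one timepoint. Used for both
## methylation (DMP semantics) and expression (DEG semantics; the
## co-stimulation vs LPS contrast then uses the fold-change-of-means pass).
categorize_all <- function(tbl, timepoint_h) {
  tp <- timepoint_h
  differentiation <- classify_induced(tbl, "RPMI", "ZERO_H", tp,
                                      category = "DIFFERENTIATION")
  diff_attenuated <- classify_attenuated(
    differentiation, sprintf("T3_vs_RPMI@%sh", tp), tbl,
    category = "DIFF_ATTENUATED")
  t3_specific <- classify_induced(tbl, "T3", c("RPMI", "ZERO_H"), tp,
                                  category = "T3_SPECIFIC")
  lps_induced <- classify_lps_induced(tbl, tp)
  lps_base <- classify_induced(tbl, "LPS", c("RPMI", "ZERO_H"), tp,
                               category = "LPS_INDUCED")
  lps_attenuated <- classify_attenuated(
    lps_base, sprintf("T3_LPS_vs_LPS@%sh", tp), tbl,
    category = "LPS_ATTENUATED")
  t3lps_specific <- classify_induced(tbl, "T3_LPS",
                                     c("T3", "RPMI", "ZERO_H"), tp,
                                     category = "T3LPS_SPECIFIC")
  t3lps_unique <- classify_unique(t3lps_specific,
                                  sprintf("T3_LPS_vs_LPS@%sh", tp), tbl,
                                  category = "T3LPS_UNIQUE")
  list(
    DIFFERENTIATION = differentiation,
    DIFF_ATTENUATED = diff_attenuated,
    T3_SPECIFIC = t3_specific,
    LPS_INDUCED = lps_induced,
    LPS_BASE = lps_base,
    LPS_ATTENUATED = lps_attenuated,
    T3LPS_SPECIFIC = t3lps_specific,
    T3LPS_UNIQUE = t3lps_unique
  )
}

## Deterministic synthetic term database: terms of random genes plus one
## term concentrated on a supplied gene set, so the enrichment stage has
## signal on synthetic runs.
synthetic_term_db <- function(universe, enriched_genes = character(),
                              n_terms = 20, term_size = 40, seed = 1L) {
  set.seed(as.integer(seed))
  db <- lapply(seq_len(n_terms), function(i) sample(universe, term_size))
  names(db) <- sprintf("TERM%03d", seq_len(n_terms))
  if (length(enriched_genes) >= 2) {
    extra <- unique(c(enriched_genes,
                      sample(universe, max(0, term_size - length(enriched_genes)))))
    db[["TERM_PLANTED"]] <- extra
  }
  db
}

#' Run the full analysis pipeline
#'
#' Executes filter, differential statistics (both assays), category
#' classification, DMR calling, nearest-gene annotation, motif/term
#' enrichment and report summarization, optionally writing every stage
#' output (stamped with the configuration hash) under the configured output
#' directory, plus a machine-readable JSON manifest of category counts in
#' "x/y (z\%)" form.
#'
#' @param config a \code{pipeline_config} (or raw list / YAML path; it is
#'   validated first).
#' @param study optional pre-built study (list with \code{design},
#'   \code{beta}, \code{counts}, optionally \code{sequences}, \code{truth});
#'   by default a synthetic study is generated from the configuration.
#' @return object of class \code{pipeline_run}: list with the study, the
#'   per-comparison statistics, category sets, DMRs, annotation,
#'   enrichment, report bundle and manifest.
#' @export
run_pipeline <- function(config = default_config(), study = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  hash <- attr(config, "hash")
  thr <- config$thresholds
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  study <- stage("inputs", {
    if (!is.null(study)) {
      study
    } else if (!is.null(config$input_prefix)) {
      list(design = read_sample_sheet(paste0(config$input_prefix, "_samples.csv")),
           beta = read_beta_matrix(config$input_prefix),
           counts = read_count_matrix(config$input_prefix),
           sequences = NULL, truth = NULL)
    } else {
      simulate_study(
        n_donors = config$synthetic$n_donors,
        n_probes = config$synthetic$n_probes,
        n_genes = config$synthetic$n_genes,
        sex = config$synthetic$sex,
        seed = config$seed,
        with_sequences = isTRUE(config$synthetic$with_sequences)
      )
    }
  })
  design <- study$design

  filt <- stage("filter", filter_probes(study$beta))

  meth_tp <- config$comparisons$meth_timepoint
  meth_stats <- stage("diff-meth", {
    out <- list()
    for (comp in comparison_schedule(meth_tp)) {
      fit <- fit_probe_models(filt, design, comp,
                              block_donor = config$block_donor,
                              scale = config$meth_scale)
      if (isTRUE(config$moderation)) fit <- moderate_variance(fit)
      out[[comp$id]] <- fit
    }
    out
  })

  rpkm <- compute_rpkm(study$counts)
  sex_labels <- stage("sex-check", assign_sex_from_xist(rpkm, design))

  rna_stats <- stage("diff-expr", {
    out <- list()
    for (tp in config$comparisons$rna_timepoints) {
      for (comp in comparison_schedule(tp)) {
        out[[comp$id]] <- fit_gene_models(study$counts, design, comp,
                                          block_donor = config$block_donor)
      }
    }
    out
  })

  meth_tbl <- stage("categorize-meth-table", {
    comparison_table(meth_stats, effect_min = thr$delta_beta, p_max = thr$p)
  })
  meth_cats <- stage("categorize-meth", categorize_all(meth_tbl, meth_tp))

  rna_out <- stage("categorize-rna", {
    per_tp <- list()
    for (tp in config$comparisons$rna_timepoints) {
      stats_tp <- list()
      for (comp in comparison_schedule(tp)) {
        fit <- rna_stats[[comp$id]]
        if (comp$target == "T3_LPS" && comp$reference == "LPS") {
          # fold-change-of-means criterion with donor concordance
          fc <- fc_mean_test(rpkm, design, "T3_LPS", "LPS", tp,
                             fc_threshold = thr$fc_mean)
          stats_tp[[comp$id]] <- data.frame(
            feature_id = fc$feature_id, effect = log2(fc$fc_mean),
            p = NA_real_, pass = fc$pass, stringsAsFactors = FALSE)
        } else {
          degs <- call_degs(fit, lfc_threshold = thr$log2fc,
                            p_threshold = thr$p, rpkm_min = thr$rpkm_min)
          stats_tp[[comp$id]] <- data.frame(
            feature_id = fit$feature_id, effect = fit$log2fc, p = fit$p,
            pass = fit$feature_id %in% degs$feature_id,
            stringsAsFactors = FALSE)
        }
      }
      tbl <- comparison_table(stats_tp, effect_min = thr$log2fc, p_max = thr$p)
      cats <- categorize_all(tbl, tp)
      lps_up <- cats$LPS_INDUCED[cats$LPS_INDUCED$direction == "GAIN", ]
      tert <- if (nrow(lps_up) >= 1) {
        a <- design_samples(design, "RNA", "T3_LPS", tp)$sample_id
        b <- design_samples(design, "RNA", "LPS", tp)$sample_id
        ratio <- (rowMeans(rpkm[lps_up$feature_id, a, drop = FALSE]) + 0.1) /
          (rowMeans(rpkm[lps_up$feature_id, b, drop = FALSE]) + 0.1)
        tertile_partition(setNames(ratio, lps_up$feature_id))
      } else NULL
      per_tp[[paste0(tp, "h")]] <- list(table = tbl, categories = cats,
                                        tertiles = tert)
    }
    per_tp
  })

  dmrs <- stage("dmr", {
    lapply(meth_stats, call_dmrs,
           max_gap_bp = thr$dmr_max_gap_bp, min_cpgs = thr$dmr_min_cpgs,
           p_threshold = thr$p, delta_threshold = thr$delta_beta)
  })

  annotation <- stage("annotate", {
    idx <- tss_index(study$counts$annot)
    out <- list()
    for (nm in names(meth_cats)) {
      cs <- meth_cats[[nm]]
      if (nrow(cs) == 0) {
        out[[nm]] <- NULL
        next
      }
      i <- match(cs$feature_id, filt$annot$probe_id)
      ng <- nearest_gene(filt$annot$chrom[i], filt$annot$pos[i], idx,
                         max_distance_bp = config$annotation$max_distance_bp)
      ng$feature_id <- cs$feature_id
      out[[nm]] <- promoter_distal_split(
        ng, promoter_max_bp = config$annotation$promoter_max_bp)
    }
    out
  })

  enrichment <- stage("enrich", {
    res <- list()
    if (!is.null(study$sequences)) {
      motifs <- list(
        PLANTED = consensus_to_pwm("TGACGTCA", motif_id = "PLANTED",
                                   tf_gene_id = "GENE00001"),
        DECOY = consensus_to_pwm("CTTAAGGCA", motif_id = "DECOY",
                                 tf_gene_id = "GENE00002")
      )
      target_ids <- meth_cats$T3_SPECIFIC$feature_id
      target_ids <- intersect(target_ids, names(study$sequences))
      if (length(target_ids) >= 2) {
        pool <- setdiff(names(study$sequences), target_ids)
        set.seed(config$seed + 17L)
        bg_ids <- sort(sample(pool, min(config$background_size, length(pool))))
        tg_hits <- lapply(motifs, function(m) scan_pwm(study$sequences[target_ids], m))
        bg_hits <- lapply(motifs, function(m) scan_pwm(study$sequences[bg_ids], m))
        tf_expr <- tf_expression_table(rpkm, design,
                                       gene_ids = vapply(motifs, `[[`,
                                                         character(1), "tf_gene_id"))
        res$motifs <- motif_enrichment(tg_hits, bg_hits, pwms = motifs,
                                       tf_expression = tf_expr,
                                       p_max = thr$enrich_p,
                                       fold_min = thr$enrich_fold,
                                       diff_min_pp = thr$enrich_diff_pp,
                                       min_targets = thr$enrich_min_targets)
      }
    }
    universe <- study$counts$annot$gene_id
    deg_t3 <- rna_out[[length(rna_out)]]$categories$T3_SPECIFIC$feature_id
    if (length(deg_t3) >= 2) {
      db <- synthetic_term_db(universe, enriched_genes = deg_t3,
                              seed = config$seed + 19L)
      res$terms <- term_enrichment(deg_t3, universe, db,
                                   p_max = thr$enrich_p,
                                   min_genes = thr$enrich_min_genes)
    }
    res
  })

  report <- stage("report", {
    rep <- list()
    if (nrow(meth_cats$T3_SPECIFIC) >= 2) {
      sel <- filt$values[meth_cats$T3_SPECIFIC$feature_id, , drop = FALSE]
      rep$pca_t3_specific <- pca_project(sel, n_components = 3)
      rep$zscore_t3_specific <- zscore_matrix(sel)
    }
    diff_gain <- meth_cats$DIFFERENTIATION
    diff_gain <- diff_gain$feature_id[diff_gain$direction == "GAIN"]
    if (length(diff_gain) >= 1) {
      rep$trajectory_meth <- trajectory_summary(
        filt$values, design, diff_gain, arms = c("RPMI", "T3"),
        timepoint_h = meth_tp, assay = "METH")
    }
    rna_last <- rna_out[[length(rna_out)]]
    diff_up <- rna_last$categories$DIFFERENTIATION
    diff_up <- diff_up$feature_id[diff_up$direction == "GAIN"]
    if (length(diff_up) >= 1) {
      rep$trajectory_rna <- trajectory_summary(
        rpkm, design, diff_up, arms = c("RPMI", "T3"),
        timepoint_h = config$comparisons$rna_timepoints[
          length(config$comparisons$rna_timepoints)],
        assay = "RNA")
    }
    att <- meth_cats$DIFF_ATTENUATED
    if (nrow(att) >= 1) {
      mod <- meth_stats[[sprintf("T3_vs_RPMI@%sh", meth_tp)]]
      key <- mod$delta_beta[match(att$feature_id, mod$feature_id)]
      rep$top_attenuated <- rank_top_features(att, key, n = 10)
    }
    rep
  })

  manifest <- stage("manifest", {
    count_dir <- function(cs, dir) sum(cs$direction == dir)
    mc <- meth_cats
    list(
      config_hash = hash,
      seed = config$seed,
      n_probes_input = nrow(study$beta$values),
      n_probes_filtered = nrow(filt$values),
      n_genes = nrow(study$counts$counts),
      donor_sex = as.list(sex_labels),
      dmp_counts = lapply(meth_stats, function(s) {
        sum(abs(s$delta_beta) > thr$delta_beta & s$p < thr$p, na.rm = TRUE)
      }),
      dmr_counts = lapply(dmrs, nrow),
      meth_categories = list(
        differentiation = nrow(mc$DIFFERENTIATION),
        diff_attenuated_gain = category_fraction(
          count_dir(mc$DIFF_ATTENUATED, "GAIN"),
          count_dir(mc$DIFFERENTIATION, "GAIN")),
        diff_attenuated_loss = category_fraction(
          count_dir(mc$DIFF_ATTENUATED, "LOSS"),
          count_dir(mc$DIFFERENTIATION, "LOSS")),
        t3_specific = nrow(mc$T3_SPECIFIC),
        t3_specific_gain = count_dir(mc$T3_SPECIFIC, "GAIN"),
        t3_specific_loss = count_dir(mc$T3_SPECIFIC, "LOSS"),
        lps_induced = nrow(mc$LPS_INDUCED),
        lps_attenuated_gain = category_fraction(
          count_dir(mc$LPS_ATTENUATED, "GAIN"),
          count_dir(mc$LPS_BASE, "GAIN")),
        lps_attenuated_loss = category_fraction(
          count_dir(mc$LPS_ATTENUATED, "LOSS"),
          count_dir(mc$LPS_BASE, "LOSS")),
        t3lps_specific = nrow(mc$T3LPS_SPECIFIC),
        t3lps_unique = category_fraction(nrow(mc$T3LPS_UNIQUE),
                                         nrow(mc$T3LPS_SPECIFIC))
      ),
      rna_categories = lapply(rna_out, function(x) {
        lapply(x$categories, nrow)
      })
    )
  })

  run <- structure(
    list(config = config, study = study, filtered = filt,
         meth_stats = meth_stats, rna_stats = rna_stats,
         meth_categories = meth_cats, rna = rna_out, dmrs = dmrs,
         annotation = annotation, enrichment = enrichment,
         rpkm = rpkm, sex = sex_labels, report = report,
         manifest = manifest),
    class = "pipeline_run"
  )
  if (!is.null(outdir)) stage("write", write_pipeline_outputs(run, outdir))
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest
  cat("pipeline_run (config", m$config_hash, ", seed", m$seed, ")\n")
  cat("  probes:", m$n_probes_filtered, "/", m$n_probes_input,
      "after filtering; genes:", m$n_genes, "\n")
  cat("  differentiation DMPs:", m$meth_categories$differentiation,
      "| T3-specific:", m$meth_categories$t3_specific,
      "| LPS-induced:", m$meth_categories$lps_induced, "\n")
  cat("  diff attenuated by T3: gain",
      m$meth_categories$diff_attenuated_gain, ", loss",
      m$meth_categories$diff_attenuated_loss, "\n")
  cat("  unique co-stimulation:", m$meth_categories$t3lps_unique, "\n")
  invisible(x)
}

## All on-disk outputs for a finished run; deterministic file contents.
write_pipeline_outputs <- function(run, outdir) {
  hash <- run$manifest$config_hash
  for (id in names(run$meth_stats)) {
    s <- run$meth_stats[[id]]
    write_tsv(as.data.frame(s), file.path(outdir, paste0("meth_", gsub("@", "_at_", id), ".tsv")),
              hash = hash)
    dmp <- call_dmps(s, run$config$thresholds$delta_beta,
                     run$config$thresholds$p)
    write_dmp_bed(dmp, file.path(outdir, paste0("dmp_", gsub("@", "_at_", id), ".bed")),
                  hash = hash)
    write_dmr_bed(run$dmrs[[id]],
                  file.path(outdir, paste0("dmr_", gsub("@", "_at_", id), ".bed")),
                  hash = hash)
  }
  for (id in names(run$rna_stats)) {
    write_tsv(as.data.frame(run$rna_stats[[id]]),
              file.path(outdir, paste0("rna_", gsub("@", "_at_", id), ".tsv")),
              hash = hash)
  }
  for (nm in names(run$meth_categories)) {
    write_category_tsv(run$meth_categories[[nm]],
                       file.path(outdir, paste0("category_meth_", nm, ".tsv")),
                       hash = hash)
  }
  for (tp in names(run$rna)) {
    for (nm in names(run$rna[[tp]]$categories)) {
      write_category_tsv(run$rna[[tp]]$categories[[nm]],
                         file.path(outdir, sprintf("category_rna_%s_%s.tsv", tp, nm)),
                         hash = hash)
    }
    tert <- run$rna[[tp]]$tertiles
    if (!is.null(tert)) {
      write_tsv(as.data.frame(tert),
                file.path(outdir, sprintf("tertiles_%s.tsv", tp)), hash = hash)
    }
  }
  for (nm in names(run$annotation)) {
    write_tsv(run$annotation[[nm]],
              file.path(outdir, paste0("annotation_", nm, ".tsv")), hash = hash)
  }
  if (!is.null(run$enrichment$motifs)) {
    write_tsv(as.data.frame(run$enrichment$motifs),
              file.path(outdir, "enrichment_motifs.tsv"), hash = hash)
  }
  if (!is.null(run$enrichment$terms)) {
    write_tsv(as.data.frame(run$enrichment$terms),
              file.path(outdir, "enrichment_terms.tsv"), hash = hash)
  }
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Write the sample sheet as CSV
#'
#' @param design a \code{study_design}.
#' @param path output CSV.
#' @export
write_sample_sheet <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample sheet CSV into a study design
#'
#' @param path CSV written by [write_sample_sheet()].
#' @return a \code{study_design}.
#' @export
read_sample_sheet <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(d) <- c("study_design", "data.frame")
  d
}
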