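#' Configure a full pipeline run
#'
#' Bundles every stage parameter and seed so that one config reproduces one
#' run exactly. Defaults mirror the study conditions: paired marrow/blood
#' cohorts at days 0 and 29, edge admission at FDR < 50%, ARACNE at
#' tolerance 0, retention at FDR < 1%, components with more than three
#' nodes, censuses at `|r| > 0.75/0.85/0.93`.
#'
#' @param cohort A [cohort_config()]; its seed is re-derived from `seed`.
#' @param seed Master seed; stage seeds are derived from it.
#' @param days Days at which the paired analyses run.
#' @param fdr_admit,fdr_retain,min_nonzero,estimator Network-stage
#'   parameters (see [build_relevance_network()], [fdr_retain()]).
#' @param dpi_tolerance ARACNE tolerance, default 0.
#' @param thresholds Census cutoffs for [threshold_counts()].
#' @param min_component_nodes Component size floor, default 4.
#' @param n_features,class_effect,n_perm Spectra-proxy dimensions and
#'   permutation count for the multilevel stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, seed = 1L, days = c(0L, 29L),
                            fdr_admit = 0.5, fdr_retain = 0.01,
                            min_nonzero = 5, estimator = "spearman",
                            dpi_tolerance = 0,
                            thresholds = c(0.75, 0.85, 0.93),
                            min_component_nodes = 4,
                            n_features = 40, class_effect = 2, n_perm = 99) {
  seed <- as.integer(seed)
  if (is.null(cohort)) cohort <- cohort_config(seed = seed)
  cohort$seed <- seed
  structure(list(cohort = cohort, seed = seed, days = as.integer(days),
                 fdr_admit = fdr_admit, fdr_retain = fdr_retain,
                 min_nonzero = min_nonzero, estimator = estimator,
                 dpi_tolerance = dpi_tolerance, thresholds = thresholds,
                 min_component_nodes = min_component_nodes,
                 n_features = n_features, class_effect = class_effect,
                 n_perm = n_perm),
            class = "pipeline_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full paired-metabolomics pipeline
#'
#' Executes simulate, preprocess, univariate, multilevel, correlate,
#' network and report in order, writing every stage artifact plus a
#' manifest (parameter echo, seeds, per-stage record counts) to `out_dir`.
#' Identical config and seed give identical numerical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)
  manifest <- list(package = "marrownet",
                   version = as.character(utils::packageVersion("marrownet")),
                   seed = cfg$seed,
                   parameters = cfg[setdiff(names(cfg), "cohort")],
                   cohort = cfg$cohort[c("n_patients", "missing_rate",
                                         "within_patient_cor", "seed")],
                   stages = list())

  # 1. simulate -------------------------------------------------------------
  cohort <- generate_cohort(cfg$cohort)
  ann <- cohort_annotation(cfg$cohort)
  write_concentration_table(cohort, pth("cohort.tsv"))
  write_annotation(ann, pth("annotation.tsv"))
  manifest$stages$simulate <- list(
    n_samples = nrow(cohort), n_metabolites = length(ct_metabolites(cohort)),
    n_missing = sum(is.na(ct_matrix(cohort))))

  # 2. preprocess (spectra-like proxy for the multilevel stage) -------------
  fm <- generate_feature_matrix(cfg$cohort$n_patients, cfg$n_features,
                                cfg$class_effect, seed = cfg$seed + 1000L,
                                dilution_sd = 0.15)
  pq <- pqn_normalize(fm$x)
  xg <- glog_transform(pq$matrix, glog_lambda(pq$matrix))
  manifest$stages$preprocess <- list(
    n_samples = nrow(xg), n_features = ncol(xg),
    pqn_factor_range = range(pq$factors))

  # 3. univariate -----------------------------------------------------------
  cohort_r <- suppressMessages(ratio_features(cohort))
  uni <- list()
  for (d in cfg$days) {
    res <- suppressMessages(compartment_comparison(cohort_r, d))
    utils::write.table(res, pth(sprintf("univariate_day%d.tsv", d)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    uni[[as.character(d)]] <- res
  }
  manifest$stages$univariate <- lapply(uni, function(res) {
    list(n_tested = nrow(res),
         n_p05 = sum(res$p < 0.05),
         n_pfdr10 = sum(res$q < 0.10),
         n_pfdr5 = sum(res$q < 0.05))
  })

  # 4. multilevel -----------------------------------------------------------
  pca <- mpca(xg, fm$subject, k = 2)
  pls <- mplsda(xg, fm$subject, fm$class, n_lv = 2)
  perm <- permutation_validate(xg, fm$subject, fm$class,
                               n_perm = cfg$n_perm, seed = cfg$seed + 2000L)
  multilevel <- list(pc1_variance_pct = pca$variance_fraction[1],
                     lv_variance_pct = pls$variance_fraction,
                     permutation_p = perm$p,
                     sensitivity_pct = pls$sensitivity,
                     specificity_pct = pls$specificity)
  write_json_file(multilevel, pth("multilevel.json"))
  manifest$stages$multilevel <- multilevel

  # 5. correlate ------------------------------------------------------------
  census <- list()
  diffs <- list()
  for (d in cfg$days) {
    pd <- paired_differences(cohort, d)
    diffs[[as.character(d)]] <- pd
    cm <- suppressMessages(correlation_matrix(pd$differences, "pearson"))
    utils::write.table(round(cm$r, 6),
                       pth(sprintf("correlation_day%d.tsv", d)),
                       sep = "\t", quote = FALSE, col.names = NA)
    census[[paste0("day", d)]] <- as.list(threshold_counts(cm, cfg$thresholds))
  }
  write_json_file(census, pth("census.json"))
  manifest$stages$correlate <- census

  # 6. network --------------------------------------------------------------
  nets <- list()
  enr <- list()
  comps_json <- list()
  for (d in cfg$days) {
    net <- suppressMessages(build_relevance_network(
      diffs[[as.character(d)]], ann, fdr_admit = cfg$fdr_admit,
      min_nonzero = cfg$min_nonzero, estimator = cfg$estimator, day = d))
    nets[[as.character(d)]] <- net
    tag <- sprintf("day%d", d)
    for (cl in c("lipid", "amino")) {
      key <- paste0(cl, "_", tag)
      enr[[key]] <- tryCatch({
        e <- enrichment_test(net, cl, "rest")
        list(p = e$p, U = e$U, direction = e$direction,
             n_group = e$n_group, n_other = e$n_other)
      }, error = function(e) list(p = NA, note = conditionMessage(e)))
    }
    pruned <- fdr_retain(aracne_prune(net, cfg$dpi_tolerance),
                         cfg$fdr_retain)
    write_network(net, pth(sprintf("network_%s_edges.tsv", tag)), "edge_tsv")
    write_network(pruned, pth(sprintf("network_%s_pruned.graphml", tag)),
                  "graphml")
    write_network(pruned, pth(sprintf("network_%s_pruned_edges.tsv", tag)),
                  "edge_tsv")
    comps <- connected_components(pruned, cfg$min_component_nodes)
    comps_json[[tag]] <- lapply(comps, function(cc) {
      s <- component_summary(cc)
      c(as.list(s), list(members = cc$nodes$metabolite))
    })
    pdf_tab <- do.call(rbind, lapply(intersect(c("lipid", "amino", "other"),
                                               unique(net$edges$edge_class)),
      function(cl) {
        sp <- edge_pdf(net, cl)
        data.frame(edge_class = cl, p = sp$x, density = sp$density)
      }))
    if (!is.null(pdf_tab)) {
      utils::write.table(pdf_tab, pth(sprintf("edge_pdf_%s.tsv", tag)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages$network[[tag]] <- list(
      n_nodes = nrow(net$nodes), n_edges_admitted = nrow(net$edges),
      p_cutoff = net$provenance$p_cutoff,
      n_edges_post_aracne = nrow(aracne_prune(net, cfg$dpi_tolerance)$edges),
      n_edges_retained = nrow(pruned$edges),
      n_components = length(comps))
  }
  if (all(c("0", "29") %in% names(nets))) {
    enr$lipid_cross_day <- tryCatch({
      e <- enrichment_test(nets[["0"]], "lipid", "same_class_other_network",
                           other = nets[["29"]])
      list(p = e$p, U = e$U, direction = e$direction,
           n_group = e$n_group, n_other = e$n_other)
    }, error = function(e) list(p = NA, note = conditionMessage(e)))
  }
  write_json_file(enr, pth("enrichment.json"))
  write_json_file(comps_json, pth("components.json"))

  # 7. report ---------------------------------------------------------------
  manifest$stages$report <- list(file = "report.txt")
  write_json_file(manifest, pth("manifest.json"))
  report(out_dir)
  invisible(manifest)
}

fmt_num <- function(x, digits = 3) formatC(x, digits = digits, format = "g")

#' Assemble a human-readable run report
#'
#' Reads the artifacts of a completed (or partial) [run_pipeline()] output
#' directory and writes `report.txt`: compartment-comparison tables with
#' significance tiers, the census counts, enrichment results, and
#' component summaries. Missing artifacts are flagged rather than omitted;
#' regeneration is idempotent.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Character vector of report lines, invisibly.
#' @export
report <- function(run_dir) {
  pth <- function(...) file.path(run_dir, ...)
  lines <- c("Paired bone-marrow/blood metabolomics run report",
             strrep("=", 48))
  if (file.exists(pth("manifest.json"))) {
    man <- jsonlite::read_json(pth("manifest.json"))
    lines <- c(lines, sprintf("seed: %s", man$seed),
               sprintf("cohort: %s patients, %s metabolites, %s missing cells",
                       man$cohort$n_patients,
                       man$stages$simulate$n_metabolites,
                       man$stages$simulate$n_missing), "")
  } else {
    lines <- c(lines, "[manifest.json missing - partial run]", "")
  }
  for (f in list.files(run_dir, pattern = "^univariate_day[0-9]+\\.tsv$")) {
    res <- utils::read.table(pth(f), header = TRUE, sep = "\t",
                             check.names = FALSE)
    day <- gsub("\\D", "", f)
    lines <- c(lines, sprintf("Compartment comparison, day %s:", day),
               sprintf("  %d tested; %d with p<0.05; %d with pFDR<10%%; %d with pFDR<5%%",
                       nrow(res), sum(res$p < 0.05), sum(res$q < 0.10),
                       sum(res$q < 0.05)))
    sig <- res[res$tier != "ns", , drop = FALSE]
    for (i in seq_len(nrow(sig))) {
      lines <- c(lines, sprintf("    %-32s diff %10s uM  fold %6s  q=%s [%s]",
                                sig$metabolite[i], fmt_num(sig$mean_diff[i], 6),
                                fmt_num(sig$fold[i]), fmt_num(sig$q[i]),
                                sig$tier[i]))
    }
    lines <- c(lines, "")
  }
  if (file.exists(pth("census.json"))) {
    census <- jsonlite::read_json(pth("census.json"))
    lines <- c(lines, "Correlation census (difference space):")
    for (d in names(census)) {
      lines <- c(lines, sprintf("  %s: %s", d,
                                paste(sprintf("%s: %s", names(census[[d]]),
                                              unlist(census[[d]])),
                                      collapse = ", ")))
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "[census.json missing]", "")
  if (file.exists(pth("enrichment.json"))) {
    enr <- jsonlite::read_json(pth("enrichment.json"))
    lines <- c(lines, "Edge-class enrichment (Mann-Whitney on edge p-values):")
    for (k in names(enr)) {
      e <- enr[[k]]
      lines <- c(lines, if (is.null(e$note)) {
        sprintf("  %-18s p = %-10s (n = %s vs %s, smaller p-values: %s)",
                k, fmt_num(e$p), e$n_group, e$n_other, e$direction)
      } else sprintf("  %-18s not computable: %s", k, e$note))
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "[enrichment.json missing]", "")
  if (file.exists(pth("components.json"))) {
    comps <- jsonlite::read_json(pth("components.json"))
    lines <- c(lines, "Pruned-network connected components:")
    for (d in names(comps)) {
      if (!length(comps[[d]])) {
        lines <- c(lines, sprintf("  %s: 0 components (0 edges retained)", d))
        next
      }
      for (i in seq_along(comps[[d]])) {
        s <- comps[[d]][[i]]
        lines <- c(lines,
                   sprintf("  %s #%d: %s nodes, %s edges; <R2>=%s, <p>=%s, <MI>=%s",
                           d, i, s$n_nodes, s$n_edges, fmt_num(s$mean_r2),
                           fmt_num(s$mean_p), fmt_num(s$mean_mi)))
      }
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "[components.json missing]", "")
  if (file.exists(pth("multilevel.json"))) {
    ml <- jsonlite::read_json(pth("multilevel.json"))
    lines <- c(lines, "Multilevel models (spectra-proxy features):",
               sprintf("  mPCA PC1 variance: %s%%", fmt_num(ml$pc1_variance_pct)),
               sprintf("  mPLS-DA permutation p: %s; sensitivity %s%%, specificity %s%%",
                       fmt_num(ml$permutation_p), fmt_num(ml$sensitivity_pct),
                       fmt_num(ml$specificity_pct)), "")
  }
  writeLines(lines, pth("report.txt"))
  invisible(lines)
}

#' Network-signature recovery on one cohort
#'
#' Convenience composition of the network stage used for calibration
#' studies: generates (or takes) a cohort, builds the day-0 and day-29
#' relevance networks from the paired differences, and returns the three
#' headline tests -- one-sided lipid enrichment at day 0, one-sided
#' amino-acid enrichment at day 29, and the two-sided cross-day comparison
#' of the lipid edge p-values. Tests whose edge groups are empty in a
#' given replicate return `NA`.
#'
#' @param cohort A [cohort_config()] or an already generated `conc_table`.
#' @param ann Annotation map; defaults to the config's panel annotation
#'   (required when `cohort` is a table).
#' @param fdr_admit,min_nonzero,estimator Passed to
#'   [build_relevance_network()].
#' @return List with `lipid_day0_p`, `amino_day29_p`, `lipid_cross_day_p`
#'   and the two networks.
#' @export
recover_signature <- function(cohort, ann = NULL, fdr_admit = 0.5,
                              min_nonzero = 5, estimator = "spearman") {
  if (inherits(cohort, "cohort_config")) {
    if (is.null(ann)) ann <- cohort_annotation(cohort)
    cohort <- generate_cohort(cohort)
  }
  if (is.null(ann)) stop("`ann` is required when `cohort` is a table")
  build <- function(day) {
    suppressMessages(suppressWarnings(build_relevance_network(
      paired_differences(cohort, day), ann, fdr_admit = fdr_admit,
      min_nonzero = min_nonzero, estimator = estimator, day = day)))
  }
  net0 <- build(0)
  net29 <- build(29)
  safe_p <- function(expr) tryCatch(expr$p, error = function(e) NA_real_)
  list(lipid_day0_p = safe_p(enrichment_test(net0, "lipid", "rest")),
       amino_day29_p = safe_p(enrichment_test(net29, "amino", "rest")),
       lipid_cross_day_p = safe_p(enrichment_test(
         net0, "lipid", "same_class_other_network", other = net29)),
       net_day0 = net0, net_day29 = net29)
}
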