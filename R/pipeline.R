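default_thresholds <- function() {
  list(p_threshold = 5e-8, p_threshold_metabolite = 5e-8,
       clump_r2 = 0.001, alpha = 0.05, fdr_q = 0.05,
       coloc_priors = c(1e-4, 1e-4, 1e-5), coloc_window = 250000,
       presso_n_sim = 1000L, n_boot = 1000L,
       palindrome_eaf_window = 0.08)
}

resolve_trait <- function(x, id = NULL) {
  if (inherits(x, "summary_stats")) return(x)
  if (is.list(x) && !is.null(x$path)) {
    return(read_summary_stats(
      x$path, dialect = x$dialect %||% list(), trait_id = id %||% x$trait_id,
      trait_type = x$trait_type %||% "quantitative",
      sample_size_default = x$n %||% NA_real_))
  }
  stop("trait registry entries must be summary_stats objects or list(path=...)",
       call. = FALSE)
}

# small deterministic config fingerprint (polynomial rolling hash over the
# deparsed config; doubles stay exact below 2^53)
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the two-step MR mediation discovery pipeline
#'
#' Orchestrates the full workflow on a registry of summary-statistics tables:
#'
#' 1. optional LD-score-regression screen — phenotypes whose genetic
#'    correlation with the outcome fails the Bonferroni-corrected test are
#'    dropped;
#' 2. phenotype -> outcome total-effect MR with sensitivity diagnostics and
#'    data-driven method selection (the total effect `beta3`);
#' 3. phenotype -> metabolite MR (primary method + BWMR), screened by
#'    family-wise Benjamini-Hochberg FDR with sign concordance (`beta1`);
#' 4. shared-mediator grouping across phenotypes;
#' 5. metabolite -> outcome MR with step-1 instruments excluded and method
#'    selection (`beta2`);
#' 6. reverse-MR filters (mediator -> phenotype and outcome -> mediator);
#' 7. colocalization of each surviving metabolite with the outcome around
#'    the metabolite's top instrument;
#' 8. optional replication against a validation outcome dataset;
#' 9. the mediation table with delta-method intervals and evidence tiers.
#'
#' Insufficient-instrument failures in any pair are recorded in
#' `report$errors` and do not abort the run.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   `traits` — list with `outcome`, optional `outcome_validation`, named
#'   lists `phenotypes` and `metabolites` (each entry a [summary_stats()]
#'   object or `list(path=, dialect=, trait_type=, n=)`); optional `ld` (an
#'   [ld_score_table()] or path readable by [read_ld_scores()]);
#'   `thresholds` — overrides of the defaults (`p_threshold 5e-8`,
#'   `clump_r2 0.001`, `alpha 0.05`, `fdr_q 0.05`,
#'   `coloc_priors c(1e-4, 1e-4, 1e-5)`, `coloc_window 250000`,
#'   `presso_n_sim 1000`, `n_boot 1000`, `palindrome_eaf_window 0.08`);
#'   `seed` — integer master seed; `stages` — logical toggles `ldsc`,
#'   `coloc`, `validation`.
#' @param out_dir Optional directory; when given, writes `forest_table.tsv`,
#'   `mediation_table.tsv`, `coloc_results.json`, `ldsc_results.json`,
#'   `run_log.json`.
#' @param quiet Suppress per-row messages (default `TRUE`).
#' @return An object of class `mrtriad_report`: `ldsc`, `total_effects`,
#'   `forest`, `step1`, `shared`, `step2`, `reverse`, `coloc`, `mediation`
#'   (data.frame, one row per retained triangle), `errors`, `run_log`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  old_opt <- options(mrtriad.quiet = quiet)
  on.exit(options(old_opt), add = TRUE)

  th <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  stages <- utils::modifyList(list(ldsc = TRUE, coloc = TRUE,
                                   validation = TRUE),
                              config$stages %||% list())
  seed <- config$seed %||% stop("config$seed must be set", call. = FALSE)
  errors <- list()
  note_error <- function(stage, id, e) {
    errors[[length(errors) + 1L]] <<- list(stage = stage, id = id,
                                           message = conditionMessage(e))
    NULL
  }

  outcome <- resolve_trait(config$traits$outcome, "outcome")
  phenos <- config$traits$phenotypes
  metabs <- config$traits$metabolites
  stopifnot(length(phenos) >= 1L, length(metabs) >= 1L,
            !is.null(names(phenos)), !is.null(names(metabs)))
  phenos <- stats::setNames(
    lapply(names(phenos), function(k) resolve_trait(phenos[[k]], k)),
    names(phenos))
  metabs <- stats::setNames(
    lapply(names(metabs), function(k) resolve_trait(metabs[[k]], k)),
    names(metabs))
  validation <- if (stages$validation &&
                    !is.null(config$traits$outcome_validation)) {
    resolve_trait(config$traits$outcome_validation, "outcome_validation")
  } else NULL

  # -- stage 1: LDSC screen --------------------------------------------------
  ldsc_res <- NULL
  if (stages$ldsc && !is.null(config$ld)) {
    ld <- if (inherits(config$ld, "ld_score_table")) config$ld else
      read_ld_scores(config$ld)
    thr <- bonferroni_threshold(th$alpha, length(phenos))
    ldsc_res <- lapply(names(phenos), function(k) {
      r <- tryCatch(ldsc_rg(phenos[[k]], outcome, ld),
                    error = function(e) note_error("ldsc", k, e))
      if (is.null(r)) return(NULL)
      list(phenotype = k, h2 = r$h2_1, h2_se = r$h2_1_se, rg = r$rg,
           rg_se = r$rg_se, rg_p = r$rg_p,
           pass = is.finite(r$rg_p) && r$rg_p < thr)
    })
    names(ldsc_res) <- names(phenos)
    keep <- vapply(ldsc_res, function(r) isTRUE(r$pass), logical(1))
    phenos <- phenos[keep]
    if (length(phenos) == 0L) {
      stop("no phenotype passes the genetic-correlation screen", call. = FALSE)
    }
  }

  # -- stage 2: total effects with method selection --------------------------
  fit_with_selection <- function(hs, seed_i) {
    sens <- mr_sensitivity(hs, n_sim = th$presso_n_sim, seed = seed_i,
                           alpha = th$alpha)
    fit <- mr_fit(hs, method = sens$chosen_method, n_boot = th$n_boot,
                  seed = seed_i + 1L)
    list(fit = fit, sens = sens)
  }
  phen_iv <- list()
  total <- list()
  forest <- list()
  for (k in names(phenos)) {
    res <- tryCatch({
      iv <- select_instruments(phenos[[k]], th$p_threshold, th$clump_r2,
                               ld = config$ld_matrix %||% NULL)
      phen_iv[[k]] <- iv
      hs <- harmonize(iv, outcome, th$palindrome_eaf_window)
      sel <- fit_with_selection(hs, seed + 11L)
      ivw <- mr_fit(hs, method = "ivw_mre")
      forest[[length(forest) + 1L]] <- forest_table(list(sel$fit, ivw))
      list(fit = sel$fit, sens = sel$sens, hs = hs)
    }, error = function(e) note_error("total_effect", k, e))
    if (!is.null(res)) total[[k]] <- res
  }

  # -- stage 3: phenotype -> metabolite, FDR screen --------------------------
  step1 <- list()
  for (k in names(total)) {
    rows <- lapply(names(metabs), function(m) {
      tryCatch({
        hs <- harmonize(phen_iv[[k]], metabs[[m]], th$palindrome_eaf_window)
        ivw <- mr_fit(hs, method = "ivw_mre")
        bw <- mr_fit(hs, method = "bwmr")
        data.frame(id = m, beta_primary = ivw$beta, se_primary = ivw$se,
                   p_primary = ivw$pval, beta_bwmr = bw$beta,
                   se_bwmr = bw$se, p_bwmr = bw$pval,
                   stringsAsFactors = FALSE)
      }, error = function(e) note_error("step1", paste(k, m, sep = "->"), e))
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab) || nrow(tab) == 0L) next
    step1[[k]] <- screen_step1(tab, fdr_q = th$fdr_q)
  }

  # -- stage 4: shared mediators ---------------------------------------------
  sig_sets <- lapply(step1, function(t) t$id[t$selected])
  shared <- if (length(sig_sets) >= 2L) {
    shared_mediators(sig_sets)
  } else {
    list(membership = data.frame(
      id = unlist(sig_sets, use.names = FALSE),
      phenotypes = rep(names(sig_sets), lengths(sig_sets)),
      n = 1L, retained = TRUE, stringsAsFactors = FALSE),
      groups = sig_sets)
  }
  cand <- shared$membership[shared$membership$retained, , drop = FALSE]

  # -- stage 5: metabolite -> outcome with step-1 exclusion ------------------
  step2 <- list()
  for (m in unique(cand$id)) {
    phen_for_m <- strsplit(cand$phenotypes[cand$id == m][1], "+",
                           fixed = TRUE)[[1]]
    res <- tryCatch({
      iv_m <- select_instruments(metabs[[m]], th$p_threshold_metabolite,
                                 th$clump_r2)
      for (k in intersect(phen_for_m, names(phen_iv))) {
        iv_m <- exclude_step1_instruments(phen_iv[[k]], iv_m)
      }
      hs <- harmonize(iv_m, outcome, th$palindrome_eaf_window)
      sel <- fit_with_selection(hs, seed + 23L)
      forest[[length(forest) + 1L]] <- forest_table(list(sel$fit))
      list(fit = sel$fit, sens = sel$sens, iv = iv_m)
    }, error = function(e) note_error("step2", m, e))
    if (!is.null(res)) step2[[m]] <- res
  }

  # -- stage 6: reverse MR ---------------------------------------------------
  reverse <- list()
  for (m in names(step2)) {
    phen_for_m <- strsplit(cand$phenotypes[cand$id == m][1], "+",
                           fixed = TRUE)[[1]]
    for (k in intersect(phen_for_m, names(total))) {
      p_mp <- tryCatch({
        hs <- harmonize(step2[[m]]$iv, phenos[[k]], th$palindrome_eaf_window)
        mr_fit(hs, method = "ivw_mre")$pval
      }, error = function(e) NA_real_)
      p_om <- tryCatch({
        iv_o <- select_instruments(outcome, th$p_threshold, th$clump_r2)
        hs <- harmonize(iv_o, metabs[[m]], th$palindrome_eaf_window)
        mr_fit(hs, method = "ivw_mre", allow_single = TRUE)$pval
      }, error = function(e) NA_real_)
      reverse[[paste(k, m, sep = "->")]] <-
        list(phenotype = k, metabolite = m,
             p_mediator_phenotype = p_mp, p_outcome_mediator = p_om)
    }
  }

  # -- stage 7: colocalization -----------------------------------------------
  coloc <- list()
  if (stages$coloc) {
    for (m in names(step2)) {
      coloc[[m]] <- tryCatch({
        iv_m <- step2[[m]]$iv
        lead <- iv_m$instruments[which.min(iv_m$instruments$pval), ]
        if (is.na(lead$pos) || is.na(lead$chrom)) {
          stop("lead variant lacks coordinates", call. = FALSE)
        }
        r1 <- region_stats(metabs[[m]], lead$chrom, lead$pos, th$coloc_window)
        r2 <- region_stats(outcome, lead$chrom, lead$pos, th$coloc_window)
        coloc_abf(r1, r2, priors = th$coloc_priors)
      }, error = function(e) note_error("coloc", m, e))
    }
  }

  # -- stage 8: external validation ------------------------------------------
  validated <- list()
  if (!is.null(validation)) {
    for (m in names(step2)) {
      validated[[m]] <- tryCatch({
        hs <- harmonize(step2[[m]]$iv, validation, th$palindrome_eaf_window)
        fit <- mr_fit(hs, method = "ivw_mre")
        fit$pval < th$alpha && sign(fit$beta) == sign(step2[[m]]$fit$beta)
      }, error = function(e) { note_error("validation", m, e); NA })
    }
  }

  # -- stage 9: mediation table with evidence tiers --------------------------
  mediation <- list()
  for (m in names(step2)) {
    phen_for_m <- strsplit(cand$phenotypes[cand$id == m][1], "+",
                           fixed = TRUE)[[1]]
    for (k in intersect(phen_for_m, names(total))) {
      s1 <- step1[[k]]; s1 <- s1[s1$id == m, ]
      if (nrow(s1) != 1L || !s1$selected) next
      med <- mediate(s1$beta_primary, s1$se_primary,
                     step2[[m]]$fit$beta, step2[[m]]$fit$se,
                     total[[k]]$fit$beta, total[[k]]$fit$se,
                     exposure_id = k, mediator_id = m, outcome_id = "outcome")
      tier <- if (!is.null(coloc[[m]])) coloc_tier(coloc[[m]]) else "none"
      tr <- list(exposure = k, mediator = m,
                 coloc_tier = tier,
                 validated_external = isTRUE(validated[[m]]))
      tr <- assign_evidence_tier(tr)
      # exclusion gates on the mediator -> phenotype reverse effect; the
      # outcome -> mediator check is recorded in report$reverse but cannot
      # gate here (the outcome's instruments may act through the mediator)
      rv <- reverse[[paste(k, m, sep = "->")]]
      tr <- reverse_mr_filter(tr, rv$p_mediator_phenotype, alpha = th$alpha)
      mediation[[length(mediation) + 1L]] <- data.frame(
        exposure = k, mediator = m, outcome = "outcome",
        beta1 = med$beta1, se1 = med$se1, beta2 = med$beta2, se2 = med$se2,
        beta3 = med$beta3, se3 = med$se3,
        indirect = med$indirect, indirect_se = med$indirect_se,
        indirect_ci_low = med$indirect_ci[[1]],
        indirect_ci_high = med$indirect_ci[[2]],
        indirect_p = med$indirect_p,
        proportion = med$proportion, proportion_pct = med$proportion_pct,
        proportion_ci_low = med$proportion_ci[[1]],
        proportion_ci_high = med$proportion_ci[[2]],
        significant = med$significant, inconsistent = med$inconsistent,
        step2_method = step2[[m]]$fit$method,
        total_method = total[[k]]$fit$method,
        coloc_tier = tier, validated_external = tr$validated_external,
        evidence_tier = tr$evidence_tier,
        reverse_excluded = tr$reverse_excluded,
        stringsAsFactors = FALSE)
    }
  }
  mediation <- if (length(mediation) > 0L) do.call(rbind, mediation) else
    data.frame()
  if (nrow(mediation) > 0L) {
    mediation <- mediation[!mediation$reverse_excluded, , drop = FALSE]
    rownames(mediation) <- NULL
  }

  run_log <- list(
    config_hash = config_hash(config[setdiff(names(config), "traits")]),
    seed = seed, thresholds = th,
    stages = stages, timestamp = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("mrtriad")),
    n_phenotypes = length(phenos), n_metabolites = length(metabs),
    ldsc_screened = stages$ldsc && !is.null(config$ld),
    n_errors = length(errors))

  report <- structure(
    list(ldsc = ldsc_res, total_effects = total,
         forest = if (length(forest) > 0L) do.call(rbind, forest) else
           data.frame(),
         step1 = step1, shared = shared, step2 = step2, reverse = reverse,
         coloc = coloc, validated = validated, mediation = mediation,
         errors = errors, run_log = run_log),
    class = "mrtriad_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' @param report An `mrtriad_report` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "mrtriad_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$forest, file.path(out_dir, "forest_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$mediation,
                     file.path(out_dir, "mediation_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  coloc_flat <- lapply(report$coloc, function(x) {
    if (is.null(x)) return(NULL)
    list(pph0 = x$pph0, pph1 = x$pph1, pph2 = x$pph2, pph3 = x$pph3,
         pph4 = x$pph4, n_snps_shared = x$n_snps_shared,
         top_shared_snp = x$top_shared_snp, tier = coloc_tier(x))
  })
  jsonlite::write_json(coloc_flat, file.path(out_dir, "coloc_results.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$ldsc %||% list(),
                       file.path(out_dir, "ldsc_results.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.mrtriad_report <- function(x, ...) {
  cat("Two-step MR mediation report\n")
  cat(sprintf("  phenotypes analysed: %d; total-effect fits: %d\n",
              x$run_log$n_phenotypes, length(x$total_effects)))
  cat(sprintf("  candidate mediators: %d; retained triangles: %d\n",
              length(x$step2), nrow(x$mediation)))
  if (nrow(x$mediation) > 0L) {
    cat("  mediation proportions (%):\n")
    for (i in seq_len(nrow(x$mediation))) {
      cat(sprintf("    %s -> %s: %.3f%% [%s]\n", x$mediation$exposure[i],
                  x$mediation$mediator[i], x$mediation$proportion_pct[i],
                  x$mediation$evidence_tier[i]))
    }
  }
  if (length(x$errors) > 0L) {
    cat(sprintf("  %d pair(s) skipped with recorded errors\n",
                length(x$errors)))
  }
  invisible(x)
}
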