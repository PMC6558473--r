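.config_hash <- function(...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(list(...), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end classification and survival analysis
#'
#' Reads the four input files, calls gene-level copy-number states, builds
#' per-sample alteration profiles, classifies every tumor with the ordered
#' decision tree, and evaluates the prognostic value of the subtypes:
#' per-subtype Kaplan-Meier curves and horizon survival rates, the k-group
#' log-rank test, and univariate (subtype only) plus multivariate
#' (subtype + clinical covariates) Cox models for each endpoint. The run is
#' deterministic for fixed inputs and configuration; the report carries a
#' provenance block (package version, configuration hash, input checksums)
#' and no timestamp, so reruns are byte-identical.
#'
#' Samples present in the clinical table but absent from both molecular
#' inputs are classified unclassified, flagged `no_molecular_data`, and
#' excluded from molecular frequency denominators.
#'
#' @param mutations,segments,genes,arms,clinical Paths to the mutation TSV,
#'   SEG file, BED gene model, arm table and clinical TSV.
#' @param calling A [calling_config()].
#' @param classifier A [classifier_config()].
#' @param endpoints Endpoints to analyze, subset of `c("os", "pfs")`.
#' @param horizon_months Horizon for survival rates; default 60 (5 years).
#' @param cox_covariates Clinical covariates for the multivariate Cox model.
#' @param ties Cox tie handling, `"efron"` or `"breslow"`.
#' @param out_dir Optional output directory; when given, the report JSON and
#'   derived TSV tables are written there.
#' @return An object of class `npc_report`.
#' @export
run_pipeline <- function(mutations, segments, genes, arms, clinical,
                         calling = calling_config(),
                         classifier = classifier_config(),
                         endpoints = c("os", "pfs"), horizon_months = 60,
                         cox_covariates = c("age_years", "sex", "stage"),
                         ties = "efron", out_dir = NULL) {
  if (horizon_months <= 0) stop("run_pipeline: horizon must be > 0", call. = FALSE)
  endpoints <- match.arg(endpoints, c("os", "pfs"), several.ok = TRUE)
  paths <- c(mutations = mutations, segments = segments, genes = genes,
             arms = arms, clinical = clinical)
  stage_ctx <- "input"
  result <- tryCatch({
    stage_ctx <- "variant_io"
    mut <- read_mutations(mutations)
    seg <- read_segments(segments)
    gm <- read_gene_model(genes, arms)
    clin <- read_clinical(clinical)

    stage_ctx <- "alteration_calling"
    cnv <- call_gene_cnv(seg, gm, calling)
    arm_calls <- summarize_arms(seg, utils::read.delim(arms), calling)
    profiles <- build_profiles(mut, cnv, calling)

    stage_ctx <- "classifier"
    molecular_ids <- names(profiles)
    no_mol <- setdiff(clin$sample_id, molecular_ids)
    all_profiles <- profiles
    if (length(no_mol) > 0) {
      for (s in no_mol) {
        p <- structure(list(sample_id = s,
                            mutations = mut[0, , drop = FALSE],
                            cnv = character(0), tmb = 0),
                       class = "npc_profile")
        all_profiles[[s]] <- p
      }
      class(all_profiles) <- "npc_profiles"
    }
    cls <- classify_cohort(all_profiles, classifier)
    cls$calls$no_molecular_data <- cls$calls$sample_id %in% no_mol

    stage_ctx <- "summaries"
    tmb <- data.frame(
      sample_id = molecular_ids,
      tmb = vapply(profiles, function(p) p$tmb, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    n_mol <- length(molecular_ids)
    ns <- filter_nonsilent(mut)
    mut_freq <- if (nrow(ns) > 0) {
      tab <- table(unique(ns[, c("sample_id", "gene")])$gene)
      data.frame(gene = names(tab), n_mutated = as.integer(tab),
                 frequency = as.integer(tab) / n_mol,
                 stringsAsFactors = FALSE, row.names = NULL)
    } else {
      data.frame(gene = character(), n_mutated = integer(),
                 frequency = numeric(), stringsAsFactors = FALSE)
    }
    nn <- cnv[cnv$state != "neutral", , drop = FALSE]
    cnv_freq <- if (nrow(nn) > 0) {
      agg <- stats::aggregate(sample_id ~ gene + state, data = nn,
                              FUN = function(x) length(unique(x)))
      names(agg)[3] <- "n_samples"
      agg$frequency <- agg$n_samples / n_mol
      agg[order(agg$gene, agg$state), , drop = FALSE]
    } else {
      data.frame(gene = character(), state = character(),
                 n_samples = integer(), frequency = numeric(),
                 stringsAsFactors = FALSE)
    }

    stage_ctx <- "survival_stats"
    surv_df <- merge(clin, cls$calls[, c("sample_id", "subtype")],
                     by = "sample_id")
    survival_out <- list()
    for (ep in endpoints) {
      tcol <- paste0(ep, "_months"); ecol <- paste0(ep, "_event")
      d <- surv_df[!is.na(surv_df[[tcol]]), , drop = FALSE]
      if (nrow(d) == 0) next
      per_subtype <- list()
      for (s in intersect(SUBTYPES, unique(d$subtype))) {
        ds <- d[d$subtype == s, , drop = FALSE]
        km <- km_estimate(ds[[tcol]], ds[[ecol]])
        rate <- suppressWarnings(survival_rate_at(km, horizon_months))
        per_subtype[[s]] <- list(
          n = nrow(ds), km = km,
          rate_at_horizon = rate$rate, rate_ci = rate$ci,
          extrapolated = rate$extrapolated)
      }
      lr <- NULL
      if (length(unique(d$subtype)) >= 2 && sum(d[[ecol]]) > 0) {
        lr <- logrank_test(d[[tcol]], d[[ecol]], d$subtype)
      }
      d$subtype <- stats::relevel(factor(d$subtype), ref = "UNCLASSIFIED")
      cox_uni <- tryCatch(
        cox_fit(d, tcol, ecol, "subtype", ties = ties),
        error = function(e) conditionMessage(e))
      mv_cov <- intersect(cox_covariates, names(d))
      mv_cov <- mv_cov[vapply(mv_cov, function(cv) {
        length(unique(stats::na.omit(d[[cv]]))) > 1
      }, logical(1))]
      cox_multi <- tryCatch(
        cox_fit(d, tcol, ecol, c(mv_cov, "subtype"), ties = ties),
        error = function(e) conditionMessage(e))
      survival_out[[ep]] <- list(
        n = nrow(d), per_subtype = per_subtype, logrank = lr,
        cox_univariate = cox_uni, cox_multivariate = cox_multi)
    }

    structure(list(
      subtype_calls = cls$calls, counts = cls$counts, percent = cls$percent,
      n = cls$n, n_molecular = n_mol,
      tmb = tmb, tmb_median = stats::median(tmb$tmb),
      mutation_frequencies = mut_freq, cnv_frequencies = cnv_freq,
      arm_calls = arm_calls, survival = survival_out,
      clinical = clin[, c("sample_id", "age_years", "sex", "stage", "who_class")],
      horizon_months = horizon_months,
      calling_config = calling, classifier_config = classifier,
      provenance = list(
        package_version = as.character(utils::packageVersion("npcmolclass")),
        config_hash = .config_hash(unclass(calling), unclass(classifier),
                                   endpoints, horizon_months,
                                   cox_covariates, ties),
        input_md5 = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                            names(paths))))
    ), class = "npc_report")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage_ctx,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(out_dir)) write_report(result, out_dir)
  result
}

#' Write a cohort report as JSON plus derived TSV tables
#'
#' The JSON report is the single source of truth; the TSV tables are
#' derived views of it.
#'
#' @param report An `npc_report`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  js <- .report_to_list(report)
  paths <- c(report = file.path(out_dir, "report.json"),
             subtypes = file.path(out_dir, "subtype_calls.tsv"),
             tmb = file.path(out_dir, "tmb.tsv"),
             cnv = file.path(out_dir, "gene_cnv_frequencies.tsv"),
             arms = file.path(out_dir, "arm_calls.tsv"))
  jsonlite::write_json(js, paths[["report"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.table(report$subtype_calls, paths[["subtypes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$tmb, paths[["tmb"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$cnv_frequencies, paths[["cnv"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$arm_calls, paths[["arms"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (ep in names(report$survival)) {
    p <- file.path(out_dir, sprintf("km_%s.tsv", ep))
    rows <- list()
    for (s in names(report$survival[[ep]]$per_subtype)) {
      km <- report$survival[[ep]]$per_subtype[[s]]$km
      if (length(km$event_times) == 0) next
      rows[[s]] <- data.frame(subtype = s, time = km$event_times,
                              at_risk = km$at_risk, events = km$n_events,
                              survival = km$survival,
                              greenwood_var = km$greenwood_var,
                              stringsAsFactors = FALSE)
    }
    if (length(rows) > 0) {
      utils::write.table(do.call(rbind, rows), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, stats::setNames(p, paste0("km_", ep)))
    }
  }
  invisible(paths)
}

.report_to_list <- function(report) {
  surv <- lapply(report$survival, function(ep) {
    list(
      n = ep$n,
      per_subtype = lapply(ep$per_subtype, function(s) {
        list(n = s$n, rate_at_horizon = s$rate_at_horizon,
             rate_ci = s$rate_ci, extrapolated = s$extrapolated,
             km = list(event_times = s$km$event_times,
                       survival = s$km$survival,
                       greenwood_var = s$km$greenwood_var,
                       at_risk = s$km$at_risk))
      }),
      logrank = if (is.null(ep$logrank)) NULL else
        list(chi2 = ep$logrank$chi2, df = ep$logrank$df,
             p_value = ep$logrank$p_value),
      cox_univariate = if (is.character(ep$cox_univariate)) ep$cox_univariate
        else ep$cox_univariate$table,
      cox_multivariate = if (is.character(ep$cox_multivariate)) ep$cox_multivariate
        else ep$cox_multivariate$table
    )
  })
  list(
    n = report$n, n_molecular = report$n_molecular,
    counts = as.list(report$counts), percent = as.list(report$percent),
    tmb_median = report$tmb_median,
    tmb = report$tmb,
    mutation_frequencies = report$mutation_frequencies,
    cnv_frequencies = report$cnv_frequencies,
    survival = surv, horizon_months = report$horizon_months,
    calling_config = unclass(report$calling_config),
    classifier_config = unclass(report$classifier_config),
    provenance = report$provenance
  )
}

#' @export
print.npc_report <- function(x, ...) {
  cat(sprintf("NPC cohort report: %d patient(s) (%d with molecular data)\n",
              x$n, x$n_molecular))
  for (s in SUBTYPES) {
    cat(sprintf("  %-13s %3d (%.1f%%)\n", s, x$counts[[s]], x$percent[[s]]))
  }
  cat(sprintf("  median TMB: %.3f mutations/Mb\n", x$tmb_median))
  for (ep in names(x$survival)) {
    lr <- x$survival[[ep]]$logrank
    if (!is.null(lr)) {
      cat(sprintf("  %s log-rank: chi2 = %.3f (df %d), p = %.4f\n",
                  toupper(ep), lr$chi2, lr$df, lr$p_value))
    }
  }
  invisible(x)
}

#' @export
summary.npc_report <- function(object, ...) {
  print(object)
  for (ep in names(object$survival)) {
    cat(sprintf("%s %g-month survival rates:\n", toupper(ep),
                object$horizon_months))
    for (s in names(object$survival[[ep]]$per_subtype)) {
      r <- object$survival[[ep]]$per_subtype[[s]]
      cat(sprintf("  %-13s %.1f%% (95%% CI %.1f-%.1f)%s\n", s,
                  100 * r$rate_at_horizon, 100 * r$rate_ci[1],
                  100 * r$rate_ci[2],
                  if (r$extrapolated) " [extrapolated]" else ""))
    }
  }
  invisible(object)
}

#' Plot Kaplan-Meier curves stratified by subtype
#'
#' @param x An `npc_report`.
#' @param endpoint `"pfs"` (default) or `"os"`.
#' @param ... Passed to [survival::plot.survfit()].
#' @export
plot.npc_report <- function(x, endpoint = "pfs", ...) {
  ep <- x$survival[[endpoint]]
  if (is.null(ep)) stop("no survival analysis for endpoint ", endpoint, call. = FALSE)
  cols <- c(RAS_PI3K_AKT = "#d62728", CELL_CYCLE = "#1f77b4",
            UNCLASSIFIED = "#2ca02c")
  subs <- names(ep$per_subtype)
  plot(NULL, xlim = c(0, max(vapply(ep$per_subtype, function(s)
    max(c(0, s$km$event_times)), numeric(1)))),
    ylim = c(0, 1), xlab = "Months", ylab = "Survival probability",
    main = sprintf("%s by genetic subtype", toupper(endpoint)), ...)
  for (s in subs) {
    km <- ep$per_subtype[[s]]$km
    graphics::lines(stats::stepfun(km$event_times, c(1, km$survival)),
                    do.points = FALSE, col = cols[[s]], lwd = 2)
  }
  graphics::legend("bottomleft", legend = subs, col = cols[subs], lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Compare two cohort reports
#'
#' Wilcoxon rank-sum tests on mutation burden; Pearson chi-square tests on
#' the subtype distribution; Benjamini-Hochberg adjustment across the
#' comparison family. Reports must come from identical configurations.
#'
#' @param report_a,report_b Two `npc_report` objects.
#' @return A data.frame: `comparison`, `test`, `p_value`, `q_value`.
#' @export
compare_cohorts <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "npc_report"), inherits(report_b, "npc_report"))
  ha <- report_a$provenance$config_hash
  hb <- report_b$provenance$config_hash
  if (!identical(ha, hb)) {
    diffs <- c()
    for (part in c("calling_config", "classifier_config")) {
      a <- unclass(report_a[[part]]); b <- unclass(report_b[[part]])
      for (f in union(names(a), names(b))) {
        if (!identical(a[[f]], b[[f]])) diffs <- c(diffs, paste0(part, "$", f))
      }
    }
    stop("compare_cohorts: incompatible configurations; differing field(s): ",
         paste(if (length(diffs)) diffs else "(run options)", collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  add <- function(comparison, test, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison, test = test, p_value = p,
      stringsAsFactors = FALSE)
  }
  add("tmb", "wilcoxon_rank_sum",
      rank_sum_test(report_a$tmb$tmb, report_b$tmb$tmb))
  age_a <- stats::na.omit(report_a$clinical$age_years)
  age_b <- stats::na.omit(report_b$clinical$age_years)
  if (length(age_a) > 0 && length(age_b) > 0) {
    add("age_years", "wilcoxon_rank_sum", rank_sum_test(age_a, age_b))
  }
  cat_test <- function(name, levels_a, levels_b, lev) {
    tab <- rbind(table(factor(levels_a, levels = lev)),
                 table(factor(levels_b, levels = lev)))
    keep <- colSums(tab) > 0
    if (sum(keep) >= 2 && all(rowSums(tab) > 0)) {
      add(name, "pearson_chi_square",
          chi_square_test(tab[, keep, drop = FALSE])$p_value)
    }
  }
  tab <- rbind(report_a$counts, report_b$counts)
  keep <- colSums(tab) > 0
  if (sum(keep) >= 2) {
    add("subtype_distribution", "pearson_chi_square",
        chi_square_test(tab[, keep, drop = FALSE])$p_value)
  }
  cat_test("sex", report_a$clinical$sex, report_b$clinical$sex,
           c("male", "female"))
  cat_test("stage", report_a$clinical$stage, report_b$clinical$stage,
           c("early", "advanced"))
  cat_test("who_class", report_a$clinical$who_class, report_b$clinical$who_class,
           c("NKUC", "NKDC", "KSCC"))
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out
}
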