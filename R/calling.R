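#' Configuration for alteration calling
#'
#' Bundles the thresholds used to reduce raw mutations and copy-number
#' segments to per-sample alteration evidence.
#'
#' @param amp_threshold Segment log2 ratio above which (strictly) a gene is
#'   called amplified. Default 0.8.
#' @param del_threshold Segment log2 ratio below which (strictly) a gene is
#'   called deleted. Default -0.8.
#' @param pathogenicity_threshold Minimum (inclusive) pathogenicity score for
#'   [filter_pathogenic()]. Default 0.07.
#' @param exome_size_mb Assayed coding territory in megabases, the
#'   denominator of tumor mutation burden. Default 38. Cohorts captured with
#'   different kits should set cohort-specific values before comparing TMB.
#' @param arm_event_log2 Absolute log2 ratio a segment must exceed to count
#'   toward an arm-level gain or loss. Default 0.3.
#' @param arm_coverage_fraction Fraction of an arm's length that qualifying
#'   segments must cover for an arm-level call. Default 0.5.
#' @return An object of class `calling_config`.
#' @export
calling_config <- function(amp_threshold = 0.8, del_threshold = -0.8,
                           pathogenicity_threshold = 0.07,
                           exome_size_mb = 38, arm_event_log2 = 0.3,
                           arm_coverage_fraction = 0.5) {
  stopifnot(is.numeric(amp_threshold), is.numeric(del_threshold))
  if (!(del_threshold < 0 && 0 < amp_threshold)) {
    stop("calling_config: need del_threshold < 0 < amp_threshold", call. = FALSE)
  }
  if (pathogenicity_threshold < 0 || pathogenicity_threshold > 1) {
    stop("calling_config: pathogenicity_threshold must be in [0,1]", call. = FALSE)
  }
  if (exome_size_mb <= 0) stop("calling_config: exome_size_mb must be > 0", call. = FALSE)
  if (arm_coverage_fraction <= 0 || arm_coverage_fraction > 1) {
    stop("calling_config: arm_coverage_fraction must be in (0,1]", call. = FALSE)
  }
  structure(list(
    amp_threshold = amp_threshold, del_threshold = del_threshold,
    pathogenicity_threshold = pathogenicity_threshold,
    exome_size_mb = exome_size_mb, arm_event_log2 = arm_event_log2,
    arm_coverage_fraction = arm_coverage_fraction
  ), class = "calling_config")
}

#' @export
print.calling_config <- function(x, ...) {
  cat("Alteration-calling configuration\n")
  cat(sprintf("  amplification: log2 > %g (strict)\n", x$amp_threshold))
  cat(sprintf("  deletion:      log2 < %g (strict)\n", x$del_threshold))
  cat(sprintf("  pathogenicity: score >= %g\n", x$pathogenicity_threshold))
  cat(sprintf("  TMB denominator: %g Mb\n", x$exome_size_mb))
  cat(sprintf("  arm events: |log2| > %g over >= %g of arm length\n",
              x$arm_event_log2, x$arm_coverage_fraction))
  invisible(x)
}

#' Keep nonsilent mutations
#'
#' Retains exactly the protein-altering and splice-disrupting classes
#' (`nonsynonymous_SNV`, `frameshift_indel`, `inframe_indel`, `stopgain`,
#' `stoploss`, `splicing`); `silent` and `other` rows are dropped.
#'
#' @param mutations Mutation data.frame (see [read_mutations()]).
#' @return The nonsilent subset, row order preserved.
#' @export
filter_nonsilent <- function(mutations) {
  mutations[mutations$variant_class %in% NONSILENT_CLASSES, , drop = FALSE]
}

#' Keep putatively pathogenic mutations
#'
#' Retains nonsilent mutations whose pathogenicity score is present and at or
#' above the threshold (the threshold is inclusive). Mutations without a
#' score are excluded: a missing prediction is not evidence of
#' pathogenicity.
#'
#' @param mutations Mutation data.frame.
#' @param threshold Minimum score in `[0,1]`; default 0.07.
#' @return The filtered subset, row order preserved.
#' @export
filter_pathogenic <- function(mutations, threshold = 0.07) {
  if (threshold < 0 || threshold > 1) {
    stop("filter_pathogenic: threshold must be in [0,1]", call. = FALSE)
  }
  ns <- filter_nonsilent(mutations)
  ns[!is.na(ns$score) & ns$score >= threshold, , drop = FALSE]
}

#' Tumor mutation burden
#'
#' The number of nonsilent coding mutations per megabase of assayed exome.
#'
#' @param mutations Mutation data.frame for one sample (silent rows are
#'   excluded internally).
#' @param exome_size_mb Denominator in megabases; must be positive.
#' @return Mutations per Mb, a non-negative number.
#' @export
compute_tmb <- function(mutations, exome_size_mb = 38) {
  if (!is.numeric(exome_size_mb) || exome_size_mb <= 0) {
    stop("compute_tmb: exome_size_mb must be > 0", call. = FALSE)
  }
  nrow(filter_nonsilent(mutations)) / exome_size_mb
}

#' Call gene-level copy-number state from segments
#'
#' For each (sample, gene), all segments overlapping the gene span by at
#' least 1 bp are considered; the determining segment is the one with the
#' largest absolute log2 ratio (ties broken by the earliest start
#' coordinate). The gene is `amplified` when the determining log2 is
#' strictly above `amp_threshold`, `deleted` when strictly below
#' `del_threshold`, otherwise `neutral`. Genes with no overlapping segment
#' are `neutral` with a supporting log2 of 0. The strict inequalities mean a
#' segment at exactly the threshold never produces a call.
#'
#' @param segments Segment data.frame (0-based half-open, see
#'   [read_segments()]).
#' @param gene_model Gene data.frame (see [read_gene_model()]).
#' @param config A [calling_config()].
#' @return A data.frame with one row per (sample, gene): `sample_id`, `gene`,
#'   `state` (`amplified`/`neutral`/`deleted`), `supporting_log2`.
#' @export
call_gene_cnv <- function(segments, gene_model, config = calling_config()) {
  if (is.null(gene_model) || nrow(gene_model) == 0) {
    stop("call_gene_cnv: empty gene model", call. = FALSE)
  }
  samples <- sort(unique(segments$sample_id))
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    seg <- segments[segments$sample_id == samples[si], , drop = FALSE]
    supporting <- numeric(nrow(gene_model))
    for (gi in seq_len(nrow(gene_model))) {
      ov <- seg$chrom == gene_model$chrom[gi] &
        seg$start < gene_model$end[gi] & seg$end > gene_model$start[gi]
      if (any(ov)) {
        hit <- seg[ov, , drop = FALSE]
        best <- order(-abs(hit$log2_ratio), hit$start)[1]
        supporting[gi] <- hit$log2_ratio[best]
      }
    }
    state <- ifelse(supporting > config$amp_threshold, "amplified",
                    ifelse(supporting < config$del_threshold, "deleted", "neutral"))
    out[[si]] <- data.frame(sample_id = samples[si], gene = gene_model$gene,
                            state = state, supporting_log2 = supporting,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(sample_id = character(), gene = character(),
                      state = character(), supporting_log2 = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

# Total length of the union of half-open intervals.
.interval_union_length <- function(starts, ends) {
  if (length(starts) == 0) return(0)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  total <- 0; cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]; cur_e <- ends[i]
    } else {
      cur_e <- max(cur_e, ends[i])
    }
  }
  total + (cur_e - cur_s)
}

#' Summarize arm-level gains and losses
#'
#' An arm is called `gain` (`loss`) when segments with log2 above
#' `+arm_event_log2` (below `-arm_event_log2`) cover at least
#' `arm_coverage_fraction` of the arm's length; when both directions
#' qualify, the larger covered fraction wins. Arm summaries are descriptive
#' only and never feed the subtype classifier.
#'
#' @param segments Segment data.frame (0-based half-open).
#' @param arm_table Data.frame with `chrom`, `start`, `end`, `arm`.
#' @param config A [calling_config()].
#' @return A data.frame with `sample_id`, `arm`, `call`
#'   (`gain`/`loss`/`neutral`), `gain_fraction`, `loss_fraction`.
#' @export
summarize_arms <- function(segments, arm_table, config = calling_config()) {
  missing_chroms <- setdiff(unique(segments$chrom), unique(arm_table$chrom))
  if (length(missing_chroms) > 0) {
    stop("summarize_arms: segment chromosome(s) absent from arm table: ",
         paste(missing_chroms, collapse = ", "), call. = FALSE)
  }
  samples <- sort(unique(segments$sample_id))
  rows <- list()
  for (s in samples) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    for (ai in seq_len(nrow(arm_table))) {
      a <- arm_table[ai, ]
      on_arm <- seg[seg$chrom == a$chrom & seg$start < a$end & seg$end > a$start, , drop = FALSE]
      if (nrow(on_arm) == 0) next
      cs <- pmax(on_arm$start, a$start); ce <- pmin(on_arm$end, a$end)
      arm_len <- a$end - a$start
      up <- on_arm$log2_ratio > config$arm_event_log2
      dn <- on_arm$log2_ratio < -config$arm_event_log2
      gain_frac <- .interval_union_length(cs[up], ce[up]) / arm_len
      loss_frac <- .interval_union_length(cs[dn], ce[dn]) / arm_len
      call <- "neutral"
      if (gain_frac >= config$arm_coverage_fraction || loss_frac >= config$arm_coverage_fraction) {
        call <- if (gain_frac >= loss_frac) "gain" else "loss"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, arm = a$arm, call = call,
        gain_fraction = gain_frac, loss_fraction = loss_frac,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sample_id = character(), arm = character(),
                      call = character(), gain_fraction = numeric(),
                      loss_fraction = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Assemble per-sample alteration profiles
#'
#' Merges mutation and gene-level copy-number evidence into one profile per
#' sample; samples appearing in only one input get empty evidence of the
#' other kind. Qualifying mutations are the nonsilent subset (optionally
#' restricted to pathogenic-scored ones); TMB is computed per sample from
#' all of that sample's mutations.
#'
#' @param mutations Mutation data.frame (may be empty).
#' @param cnv_calls Gene-level CNV calls from [call_gene_cnv()] (may be empty).
#' @param config A [calling_config()].
#' @param pathogenic_only If `TRUE`, qualifying mutations are additionally
#'   filtered by [filter_pathogenic()] at `config$pathogenicity_threshold`.
#' @return A named list of class `npc_profiles`; each element is an
#'   `npc_profile` list with `sample_id`, `mutations` (qualifying subset),
#'   `cnv` (named character vector gene -> state) and `tmb`.
#' @export
build_profiles <- function(mutations, cnv_calls, config = calling_config(),
                           pathogenic_only = FALSE) {
  samples <- sort(union(unique(mutations$sample_id), unique(cnv_calls$sample_id)))
  profiles <- lapply(samples, function(s) {
    mut_s <- mutations[mutations$sample_id == s, , drop = FALSE]
    qual <- filter_nonsilent(mut_s)
    if (pathogenic_only) qual <- filter_pathogenic(qual, config$pathogenicity_threshold)
    cnv_s <- cnv_calls[cnv_calls$sample_id == s, , drop = FALSE]
    cnv <- stats::setNames(cnv_s$state, cnv_s$gene)
    structure(list(
      sample_id = s,
      mutations = qual,
      cnv = cnv,
      tmb = compute_tmb(mut_s, config$exome_size_mb)
    ), class = "npc_profile")
  })
  structure(stats::setNames(profiles, samples), class = "npc_profiles")
}

#' @export
print.npc_profile <- function(x, ...) {
  cat(sprintf("Sample %s: %d qualifying mutation(s), %d non-neutral CNV gene(s), TMB %.3f/Mb\n",
              x$sample_id, nrow(x$mutations),
              sum(x$cnv != "neutral"), x$tmb))
  invisible(x)
}

#' @export
print.npc_profiles <- function(x, ...) {
  cat(sprintf("Alteration profiles for %d sample(s)\n", length(x)))
  invisible(x)
}
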