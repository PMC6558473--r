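SUBTYPES <- c("RAS_PI3K_AKT", "CELL_CYCLE", "UNCLASSIFIED")

#' Configuration of the ordered subtype decision tree
#'
#' The classifier assigns each tumor to one of three genetic subtypes by an
#' ordered rule cascade: tier 1 fires on nonsilent mutations in RAS-pathway
#' genes (RAS/PI3K/AKT subtype), tier 2 on cell-cycle copy-number events
#' (CDKN2A/CDKN2B deletion or CCND1/CDKN1B amplification), and tumors
#' matching neither rule are unclassified. Annotation gene sets (epigenetic
#' regulators, Notch pathway) decorate the output but never affect the
#' assignment.
#'
#' "RAS" is expanded to the three family members KRAS, NRAS and HRAS, all of
#' which occur mutated in this tumor type. CDKN1B amplification is included
#' among the tier-2 amplification events exactly as defined by the subtype,
#' even though amplification of a CDK inhibitor is biologically surprising;
#' users can drop it from `tier2_amplification_genes`.
#'
#' @param tier1_mutation_genes Genes whose nonsilent mutation defines the
#'   RAS/PI3K/AKT subtype.
#' @param tier2_deletion_genes Genes whose deletion defines the cell-cycle
#'   subtype.
#' @param tier2_amplification_genes Genes whose amplification defines the
#'   cell-cycle subtype.
#' @param annotation_genes Named list of gene sets used only to annotate
#'   calls (default: epigenetic regulators and Notch pathway).
#' @param require_pathogenic_for_tier1 If `TRUE`, only mutations with a
#'   pathogenicity score at or above `pathogenicity_threshold` can trigger
#'   tier 1. Default `FALSE`: any nonsilent mutation qualifies.
#' @param pathogenicity_threshold Score threshold used when
#'   `require_pathogenic_for_tier1` is `TRUE`. Default 0.07.
#' @return An object of class `npc_classifier_config`.
#' @export
classifier_config <- function(
    tier1_mutation_genes = c("KRAS", "NRAS", "HRAS", "AKT1", "PIK3CA"),
    tier2_deletion_genes = c("CDKN2A", "CDKN2B"),
    tier2_amplification_genes = c("CCND1", "CDKN1B"),
    annotation_genes = list(
      epigenetic = c("KMT2C", "KMT2D", "KMT2B", "PRDM2", "PRDM16",
                     "NCOR2", "KAT6B", "EP300", "CREBBP"),
      notch = c("NOTCH1", "NOTCH2")
    ),
    require_pathogenic_for_tier1 = FALSE,
    pathogenicity_threshold = 0.07) {
  tier2 <- union(tier2_deletion_genes, tier2_amplification_genes)
  if (length(tier1_mutation_genes) == 0 || length(tier2_deletion_genes) == 0 ||
      length(tier2_amplification_genes) == 0) {
    stop("classifier_config: tier gene sets must be nonempty", call. = FALSE)
  }
  clash <- intersect(tier1_mutation_genes, tier2)
  if (length(clash) > 0) {
    stop("classifier_config: tier-1 and tier-2 gene sets must be disjoint; shared: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  structure(list(
    tier1_mutation_genes = tier1_mutation_genes,
    tier2_deletion_genes = tier2_deletion_genes,
    tier2_amplification_genes = tier2_amplification_genes,
    annotation_genes = annotation_genes,
    require_pathogenic_for_tier1 = isTRUE(require_pathogenic_for_tier1),
    pathogenicity_threshold = pathogenicity_threshold
  ), class = "npc_classifier_config")
}

#' @export
print.npc_classifier_config <- function(x, ...) {
  cat("Ordered NPC subtype classifier\n")
  cat("  tier 1 (RAS/PI3K/AKT): mutation in",
      paste(x$tier1_mutation_genes, collapse = ", "), "\n")
  cat("  tier 2 (cell-cycle): deletion of",
      paste(x$tier2_deletion_genes, collapse = "/"),
      "or amplification of",
      paste(x$tier2_amplification_genes, collapse = "/"), "\n")
  cat("  otherwise: UNCLASSIFIED, annotated for",
      paste(names(x$annotation_genes), collapse = ", "), "\n")
  if (x$require_pathogenic_for_tier1) {
    cat(sprintf("  tier-1 mutations restricted to score >= %g\n",
                x$pathogenicity_threshold))
  }
  invisible(x)
}

#' Write a classifier configuration to YAML
#'
#' @param config An [classifier_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a classifier configuration from YAML
#'
#' The YAML document mirrors [classifier_config()]'s arguments; write/read
#' round trips are lossless.
#'
#' @param path Path to a YAML config file.
#' @return An `npc_classifier_config` object.
#' @export
read_classifier_config <- function(path) {
  doc <- yaml::read_yaml(path)
  do.call(classifier_config, doc)
}

#' Classify one tumor by the ordered decision tree
#'
#' Rules are evaluated strictly in order. Tier 1: if any qualifying mutation
#' falls in a tier-1 gene, the tumor is RAS/PI3K/AKT regardless of any
#' copy-number evidence. Tier 2 (only reached when tier 1 did not fire): a
#' deletion of a tier-2 deletion gene or an amplification of a tier-2
#' amplification gene makes the tumor cell-cycle; the rule is
#' direction-specific, so e.g. an amplified CDKN2A never triggers it.
#' Otherwise the tumor is unclassified. Annotation labels are attached for
#' any annotation gene set with a mutated member.
#'
#' @param profile An `npc_profile` (see [build_profiles()]).
#' @param config An [classifier_config()].
#' @return An `npc_subtype_call` list: `sample_id`, `subtype`, `evidence`
#'   (data.frame of rule/gene/alteration triples) and `annotations`.
#' @export
classify_sample <- function(profile, config = classifier_config()) {
  stopifnot(inherits(profile, "npc_profile"))
  muts <- profile$mutations
  qual <- muts
  if (config$require_pathogenic_for_tier1) {
    qual <- qual[!is.na(qual$score) & qual$score >= config$pathogenicity_threshold, ,
                 drop = FALSE]
  }
  annotations <- names(config$annotation_genes)[vapply(
    config$annotation_genes,
    function(g) any(muts$gene %in% g), logical(1))]

  t1 <- qual[qual$gene %in% config$tier1_mutation_genes, , drop = FALSE]
  if (nrow(t1) > 0) {
    ev <- data.frame(rule = "tier1_mutation", gene = t1$gene,
                     alteration = t1$variant_class, stringsAsFactors = FALSE)
    return(.subtype_call(profile$sample_id, "RAS_PI3K_AKT", ev, annotations))
  }
  cnv <- profile$cnv
  del <- names(cnv)[cnv == "deleted" & names(cnv) %in% config$tier2_deletion_genes]
  amp <- names(cnv)[cnv == "amplified" & names(cnv) %in% config$tier2_amplification_genes]
  if (length(del) + length(amp) > 0) {
    ev <- rbind(
      if (length(del)) data.frame(rule = "tier2_deletion", gene = del,
                                  alteration = "deleted", stringsAsFactors = FALSE),
      if (length(amp)) data.frame(rule = "tier2_amplification", gene = amp,
                                  alteration = "amplified", stringsAsFactors = FALSE)
    )
    return(.subtype_call(profile$sample_id, "CELL_CYCLE", ev, annotations))
  }
  ev <- data.frame(rule = character(), gene = character(),
                   alteration = character(), stringsAsFactors = FALSE)
  .subtype_call(profile$sample_id, "UNCLASSIFIED", ev, annotations)
}

.subtype_call <- function(sample_id, subtype, evidence, annotations) {
  structure(list(sample_id = sample_id, subtype = subtype,
                 evidence = evidence, annotations = annotations),
            class = "npc_subtype_call")
}

#' @export
print.npc_subtype_call <- function(x, ...) {
  cat(sprintf("%s -> %s", x$sample_id, x$subtype))
  if (nrow(x$evidence) > 0) {
    cat(" [", paste(sprintf("%s:%s(%s)", x$evidence$rule, x$evidence$gene,
                            x$evidence$alteration), collapse = "; "), "]", sep = "")
  }
  if (length(x$annotations) > 0) {
    cat(" {", paste(x$annotations, collapse = ", "), "}", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Classify a cohort of tumors
#'
#' Applies [classify_sample()] to every profile and tabulates subtype
#' counts. Classification is deterministic: rerunning on the same profiles
#' and configuration reproduces the same calls.
#'
#' @param profiles An `npc_profiles` list (see [build_profiles()]).
#' @param config An [classifier_config()].
#' @return An object of class `npc_classification` with components `calls`
#'   (data.frame: sample_id, subtype, evidence, annotations), `detail`
#'   (list of `npc_subtype_call`), `counts` and `percent` (named by
#'   subtype), and `n`.
#' @export
classify_cohort <- function(profiles, config = classifier_config()) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("classify_cohort: duplicate sample_id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  detail <- lapply(profiles, classify_sample, config = config)
  calls <- data.frame(
    sample_id = ids,
    subtype = vapply(detail, function(d) d$subtype, character(1)),
    evidence = vapply(detail, function(d) {
      if (nrow(d$evidence) == 0) "" else
        paste(sprintf("%s:%s:%s", d$evidence$rule, d$evidence$gene,
                      d$evidence$alteration), collapse = ";")
    }, character(1)),
    annotations = vapply(detail, function(d) paste(d$annotations, collapse = ";"),
                         character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  counts <- vapply(SUBTYPES, function(s) sum(calls$subtype == s), integer(1))
  structure(list(
    calls = calls, detail = detail, counts = counts,
    percent = 100 * counts / length(ids), n = length(ids),
    config = config
  ), class = "npc_classification")
}

#' @export
print.npc_classification <- function(x, ...) {
  cat(sprintf("NPC genetic subtype classification of %d tumors\n", x$n))
  for (s in SUBTYPES) {
    cat(sprintf("  %-13s %3d (%.1f%%)\n", s, x$counts[[s]], x$percent[[s]]))
  }
  invisible(x)
}

#' @export
summary.npc_classification <- function(object, ...) {
  print(object)
  ann <- object$calls$annotations[object$calls$subtype == "UNCLASSIFIED"]
  ann <- ann[nzchar(ann)]
  if (length(ann) > 0) {
    tab <- sort(table(unlist(strsplit(ann, ";"))), decreasing = TRUE)
    cat("Annotations among unclassified tumors:\n")
    for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  }
  invisible(object)
}

#' Write subtype calls as a tab-separated table
#'
#' @param classification An `npc_classification`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subtype_calls <- function(classification, path) {
  utils::write.table(classification$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
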