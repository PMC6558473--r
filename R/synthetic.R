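#' Packaged synthetic mini gene model
#'
#' Gene spans and chromosome arms used by the synthetic cohorts. The
#' coordinates are small synthetic spans on synthetic contigs (2 Mb per
#' chromosome, arms split at 1 Mb), not real genome coordinates, so the
#' fixture is genome-build independent; the reader and calling stack treat
#' them exactly like real coordinates.
#'
#' @return A list with `genes` (gene, chrom, start, end, arm; 0-based
#'   half-open) and `arms` (chrom, start, end, arm).
#' @export
npc_gene_model <- function() {
  g <- function(gene, chrom, start) {
    data.frame(gene = gene, chrom = chrom, start = start, end = start + 10000L,
               stringsAsFactors = FALSE)
  }
  genes <- rbind(
    g("NRAS",   "chr1",  100000L),
    g("PRDM16", "chr1",  300000L),
    g("PRDM2",  "chr1",  500000L),
    g("NOTCH2", "chr1",  700000L),
    g("TTN",    "chr2",  1200000L),
    g("PIK3CA", "chr3",  1200000L),
    g("KMT2C",  "chr7",  1700000L),
    g("CDKN2A", "chr9",  200000L),
    g("CDKN2B", "chr9",  230000L),
    g("NOTCH1", "chr9",  1500000L),
    g("KAT6B",  "chr10", 1400000L),
    g("HRAS",   "chr11", 50000L),
    g("CCND1",  "chr11", 1300000L),
    g("CDKN1B", "chr12", 100000L),
    g("KRAS",   "chr12", 500000L),
    g("KMT2D",  "chr12", 1100000L),
    g("NCOR2",  "chr12", 1700000L),
    g("AKT1",   "chr14", 1600000L),
    g("CREBBP", "chr16", 150000L),
    g("TP53",   "chr17", 400000L),
    g("KMT2B",  "chr19", 1200000L),
    g("EP300",  "chr22", 1300000L)
  )
  chroms <- unique(genes$chrom)
  bare <- sub("^chr", "", chroms)
  arms <- rbind(
    data.frame(chrom = chroms, start = 0L, end = 1000000L,
               arm = paste0(bare, "p"), stringsAsFactors = FALSE),
    data.frame(chrom = chroms, start = 1000000L, end = 2000000L,
               arm = paste0(bare, "q"), stringsAsFactors = FALSE)
  )
  arms <- arms[order(arms$chrom, arms$start), , drop = FALSE]
  rownames(arms) <- NULL
  genes$arm <- assign_arm(genes, arms)
  list(genes = genes, arms = arms)
}

#' Specification of the deterministic fixture cohort
#'
#' Describes the 82-patient fixture: how many patients carry tier-1
#' (RAS-pathway) mutations, how many additional patients carry tier-2
#' (cell-cycle) copy-number events, the planted per-gene copy-number call
#' counts, which tier-1 patients also carry tier-2 events (making rule
#' precedence observable), and near-threshold / non-overlapping decoy
#' segments that must never produce calls.
#'
#' @param n_patients Cohort size. Default 82.
#' @param tier1_count Patients with a tier-1 mutation. Default 9.
#' @param tier2_only_count Additional patients with tier-2 copy-number
#'   events and no tier-1 mutation. Default 34.
#' @param cnv_counts Data.frame (`gene`, `state`, `count`) of planted
#'   gene-level call counts. Defaults: CDKN2A deleted in 19, CDKN2B deleted
#'   in 16, CCND1 amplified in 17 patients.
#' @param overlap_plan List (indexed by tier-1 patient number) of
#'   `"gene:state"` events those patients carry in addition to their tier-1
#'   mutation. Default: 4 of the 9 tier-1 patients carry tier-2 events.
#' @param decoy_plan Data.frame (`gene`, `log2`, `overlaps`) of decoy
#'   segments planted in otherwise alteration-free patients: values exactly
#'   at the thresholds (0.8 / -0.8), below them (0.75 / -0.75), beyond
#'   threshold but not overlapping the gene, and a wrong-direction event
#'   (CDKN2A amplification) that must not trigger the deletion rule.
#' @return An object of class `npc_fixture_spec`.
#' @export
fixture_spec <- function(
    n_patients = 82L, tier1_count = 9L, tier2_only_count = 34L,
    cnv_counts = data.frame(
      gene = c("CDKN2A", "CDKN2B", "CCND1"),
      state = c("deleted", "deleted", "amplified"),
      count = c(19L, 16L, 17L),
      stringsAsFactors = FALSE),
    overlap_plan = list(
      "CDKN2A:deleted", "CDKN2B:deleted", "CCND1:amplified",
      c("CDKN2A:deleted", "CDKN2B:deleted")),
    decoy_plan = data.frame(
      gene = c("CCND1", "CDKN2A", "CCND1", "CDKN2A", "CCND1", "CDKN2A", "CDKN2A"),
      log2 = c(0.8, -0.8, 0.75, -0.75, 2, -2, 1),
      overlaps = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE)) {
  if (tier1_count + tier2_only_count > n_patients) {
    stop("fixture_spec: tier1_count + tier2_only_count exceeds n_patients",
         call. = FALSE)
  }
  if (length(overlap_plan) > tier1_count) {
    stop("fixture_spec: overlap plan names more patients than tier1_count",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 tier1_count = as.integer(tier1_count),
                 tier2_only_count = as.integer(tier2_only_count),
                 cnv_counts = cnv_counts, overlap_plan = overlap_plan,
                 decoy_plan = decoy_plan),
            class = "npc_fixture_spec")
}

# Deterministic allocation of tier-2 events: overlap-plan events go to the
# designated tier-1 patients; remaining per-gene counts are dealt cyclically
# to the tier2-only patients so that every one of them carries >= 1 event.
.allocate_tier2_events <- function(spec) {
  key <- paste(spec$cnv_counts$gene, spec$cnv_counts$state, sep = ":")
  planted <- stats::setNames(spec$cnv_counts$count, key)
  overlap_events <- unlist(spec$overlap_plan, use.names = FALSE)
  bad <- setdiff(overlap_events, key)
  if (length(bad) > 0) {
    stop("fixture: overlap plan uses event(s) not in cnv_counts: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  used <- table(factor(overlap_events, levels = key))
  rem <- planted - as.integer(used)
  if (any(rem < 0)) {
    stop("fixture: overlap plan exceeds planted count for ",
         paste(key[rem < 0], collapse = ", "), call. = FALSE)
  }
  m <- spec$tier2_only_count
  if (sum(rem) < m) {
    stop("fixture: planted events (", sum(rem), " after overlaps) cannot give each of ",
         m, " cell-cycle-only patients an event", call. = FALSE)
  }
  if (any(rem > m)) {
    stop("fixture: planted count for ", paste(key[rem > m], collapse = ", "),
         " exceeds the number of cell-cycle-only patients", call. = FALSE)
  }
  seq_events <- rep(key, times = rem)
  patient <- ((seq_along(seq_events) - 1L) %% m) + 1L
  alloc <- split(seq_events, patient)
  if (any(vapply(alloc, anyDuplicated, integer(1)) > 0)) {
    stop("fixture: cyclic allocation would plant the same event twice in one patient",
         call. = FALSE)
  }
  alloc
}

.fixture_mut_row <- function(sample_id, gene, genes, class, score,
                             ref = "G", alt = "A") {
  start <- genes$start[match(gene, genes$gene)]
  data.frame(sample_id = sample_id, gene = gene,
             chrom = genes$chrom[match(gene, genes$gene)],
             pos = start + 501L, ref = ref, alt = alt,
             variant_class = class, score = score, stringsAsFactors = FALSE)
}

.fixture_seg_row <- function(sample_id, gene, genes, log2, pad = 5000L,
                             overlaps = TRUE) {
  i <- match(gene, genes$gene)
  if (overlaps) {
    start <- genes$start[i] - pad; end <- genes$end[i] + pad
  } else {
    # strictly left of the gene span (a gene-free stretch in this model):
    # no 1-bp overlap with any gene is possible
    start <- genes$start[i] - 50000L; end <- genes$start[i] - 1000L
  }
  data.frame(sample_id = sample_id, chrom = genes$chrom[i],
             start = as.integer(max(0L, start)), end = as.integer(end),
             log2_ratio = log2, n_probes = 50L, stringsAsFactors = FALSE)
}

#' Build the deterministic fixture cohort
#'
#' Constructs, with no randomness at all, a cohort whose classifier and
#' gene-level copy-number call counts match the planted totals of the
#' specification: by default 9 RAS/PI3K/AKT patients (4 of which also carry
#' cell-cycle copy-number events, exercising rule precedence), 34
#' cell-cycle-only patients, and 39 unclassified patients carrying only
#' annotation-gene mutations, decoy segments or nothing. Planted segments
#' sit strictly beyond threshold (|log2| = 1); decoy segments sit exactly at
#' the thresholds, just below them, in the wrong direction, or beyond
#' threshold but not overlapping any gene, and must never produce calls.
#' Two identical builds are byte-identical when written.
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `npc_cohort`: `mutations`, `segments` (0-based
#'   half-open), `clinical`, `truth` (planted subtype per patient),
#'   `gene_model`, `arm_table`.
#' @export
npc_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "npc_fixture_spec"))
  gm <- npc_gene_model()
  genes <- gm$genes
  n <- spec$n_patients
  ids <- sprintf("NPC%03d", seq_len(n))
  tier1_idx <- seq_len(spec$tier1_count)
  cc_idx <- spec$tier1_count + seq_len(spec$tier2_only_count)
  unc_idx <- setdiff(seq_len(n), c(tier1_idx, cc_idx))

  tier1_genes <- c("KRAS", "NRAS", "HRAS", "AKT1", "PIK3CA")
  epi_genes <- c("KMT2C", "KMT2D", "KMT2B", "PRDM2", "PRDM16", "NCOR2",
                 "KAT6B", "EP300", "CREBBP")
  notch_genes <- c("NOTCH1", "NOTCH2")

  muts <- list(); segs <- list()
  add_mut <- function(row) muts[[length(muts) + 1L]] <<- row
  add_seg <- function(row) segs[[length(segs) + 1L]] <<- row

  # tier-1 mutations; patient 5 gets a sub-threshold pathogenicity score so
  # the pathogenic-only tier-1 mode is observable on the fixture
  t1_classes <- c("nonsynonymous_SNV", "nonsynonymous_SNV", "nonsynonymous_SNV",
                  "stopgain", "nonsynonymous_SNV", "nonsynonymous_SNV",
                  "splicing", "nonsynonymous_SNV", "nonsynonymous_SNV")
  for (k in seq_along(tier1_idx)) {
    i <- tier1_idx[k]
    gene <- tier1_genes[((k - 1L) %% length(tier1_genes)) + 1L]
    score <- if (k == 5) 0.02 else round(0.5 + 0.01 * k, 2)
    cls <- t1_classes[((k - 1L) %% length(t1_classes)) + 1L]
    add_mut(.fixture_mut_row(ids[i], gene, genes, cls, score))
  }
  # tier-2 events co-occurring in tier-1 patients (the overlap plan)
  for (k in seq_along(spec$overlap_plan)) {
    for (ev in spec$overlap_plan[[k]]) {
      parts <- strsplit(ev, ":", fixed = TRUE)[[1]]
      log2 <- if (parts[2] == "amplified") 1 else -1
      add_seg(.fixture_seg_row(ids[tier1_idx[k]], parts[1], genes, log2))
    }
  }
  # tier-2 events for the cell-cycle-only patients
  alloc <- .allocate_tier2_events(spec)
  for (p in names(alloc)) {
    i <- cc_idx[as.integer(p)]
    for (ev in alloc[[p]]) {
      parts <- strsplit(ev, ":", fixed = TRUE)[[1]]
      log2 <- if (parts[2] == "amplified") 1 else -1
      add_seg(.fixture_seg_row(ids[i], parts[1], genes, log2))
    }
  }
  # unclassified patients: annotation mutations for the first 22, decoy
  # segments and decoy mutations for later ones, nothing for the rest
  ann_genes <- c(epi_genes, notch_genes)
  n_ann <- min(22L, length(unc_idx))
  for (k in seq_len(n_ann)) {
    i <- unc_idx[k]
    gene <- ann_genes[((k - 1L) %% length(ann_genes)) + 1L]
    score <- if (k %% 3 == 0) NA_real_ else round(0.05 + 0.02 * k, 2)
    add_mut(.fixture_mut_row(ids[i], gene, genes, "nonsynonymous_SNV", score))
  }
  decoys <- spec$decoy_plan
  n_dec <- nrow(decoys)
  if (length(unc_idx) < n_ann + n_dec + 2L) {
    stop("fixture: not enough unclassified patients for annotations, decoys ",
         "and mutation-class decoys", call. = FALSE)
  }
  if (n_dec > 0) {
    dec_slots <- unc_idx[seq(length(unc_idx) - n_dec - 1L,
                             length.out = n_dec)]
    for (k in seq_len(n_dec)) {
      add_seg(.fixture_seg_row(ids[dec_slots[k]], decoys$gene[k], genes,
                               decoys$log2[k], pad = 2000L,
                               overlaps = decoys$overlaps[k]))
    }
  }
  # mutation-class decoys: a silent tier-1-gene mutation and a noncoding one
  # must never trigger tier 1
  last2 <- utils::tail(unc_idx, 2)
  add_mut(.fixture_mut_row(ids[last2[1]], "PIK3CA", genes, "silent", NA_real_,
                           ref = "C", alt = "T"))
  add_mut(.fixture_mut_row(ids[last2[2]], "KRAS", genes, "other", NA_real_))
  # passenger background for every patient: one nonsilent TP53, one silent TTN
  for (i in seq_len(n)) {
    add_mut(.fixture_mut_row(ids[i], "TP53", genes, "nonsynonymous_SNV",
                             if (i %% 2 == 0) NA_real_ else round(0.1 + 0.005 * i, 3)))
    add_mut(.fixture_mut_row(ids[i], "TTN", genes, "silent", NA_real_,
                             ref = "C", alt = "T"))
  }

  mutations <- do.call(rbind, muts); rownames(mutations) <- NULL
  segments <- do.call(rbind, segs)
  segments <- segments[order(segments$sample_id, segments$chrom, segments$start), ,
                       drop = FALSE]
  rownames(segments) <- NULL

  truth <- data.frame(
    sample_id = ids,
    subtype = c(rep("RAS_PI3K_AKT", length(tier1_idx)),
                rep("CELL_CYCLE", length(cc_idx)),
                rep("UNCLASSIFIED", length(unc_idx))),
    stringsAsFactors = FALSE
  )
  clinical <- .fixture_clinical(ids, truth$subtype)
  structure(list(mutations = mutations, segments = segments,
                 clinical = clinical, truth = truth,
                 gene_model = genes, arm_table = gm$arms),
            class = "npc_cohort")
}

# Deterministic clinical table: survival times are exponential quantiles at
# evenly spaced probabilities within each subtype group (medians follow the
# simulator defaults), with periodic censoring and administrative capping at
# 96 months; demographics loosely follow the marginal structure of an NPC
# surgical cohort (three-quarters male, >90% advanced stage, mostly NKUC).
.fixture_clinical <- function(ids, subtype) {
  n <- length(ids)
  med_pfs <- c(RAS_PI3K_AKT = 18, CELL_CYCLE = 36, UNCLASSIFIED = 60)
  med_os <- 2 * med_pfs
  pfs <- numeric(n); pfs_ev <- integer(n)
  os <- numeric(n); os_ev <- integer(n)
  for (s in unique(subtype)) {
    idx <- which(subtype == s)
    g <- length(idx)
    p <- seq_len(g) / (g + 1)
    t_pfs <- stats::qexp(p, rate = log(2) / med_pfs[[s]])
    t_os <- stats::qexp(p, rate = log(2) / med_os[[s]])
    ev_pfs <- as.integer(seq_len(g) %% 4 != 0)
    ev_os <- as.integer(seq_len(g) %% 3 != 0)
    t_pfs[ev_pfs == 0] <- t_pfs[ev_pfs == 0] * 0.6
    t_os[ev_os == 0] <- t_os[ev_os == 0] * 0.6
    cap <- function(t, e) {
      over <- t > 96
      list(t = ifelse(over, 96, t), e = ifelse(over, 0L, e))
    }
    cp <- cap(t_pfs, ev_pfs); co <- cap(t_os, ev_os)
    pfs[idx] <- round(cp$t, 1); pfs_ev[idx] <- cp$e
    os[idx] <- round(pmax(co$t, cp$t), 1); os_ev[idx] <- co$e
  }
  i <- seq_len(n)
  data.frame(
    sample_id = ids,
    age_years = 19 + ((i * 13) %% 53),
    sex = ifelse(i %% 4 == 0, "female", "male"),
    stage = ifelse(i %in% seq(10, 70, by = 10), "early", "advanced"),
    who_class = ifelse(i %in% c(5, 15, 25, 35, 45, 55, 65), "NKDC",
                       ifelse(i %in% c(41, n), "KSCC", "NKUC")),
    os_months = os, os_event = os_ev,
    pfs_months = pfs, pfs_event = pfs_ev,
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic cohort to the standard file formats
#'
#' Writes the mutation table, SEG file, clinical table, gene model (BED +
#' arm table) and, when present, the truth table of a cohort built by
#' [npc_fixture()] or [simulate_cohort()]. Output is deterministic: two
#' writes of the same cohort are byte-identical.
#'
#' @param cohort An `npc_cohort` list.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    mutations = file.path(dir, "mutations.tsv"),
    segments = file.path(dir, "segments.seg"),
    clinical = file.path(dir, "clinical.tsv"),
    genes = file.path(dir, "genes.bed"),
    arms = file.path(dir, "arms.tsv")
  )
  write_mutations(cohort$mutations, paths[["mutations"]])
  write_segments(cohort$segments, paths[["segments"]])
  write_clinical(cohort$clinical, paths[["clinical"]])
  gm <- cohort$gene_model
  if (is.null(gm)) gm <- npc_gene_model()$genes
  arms <- cohort$arm_table
  if (is.null(arms)) arms <- npc_gene_model()$arms
  write_gene_model(gm, arms, paths[["genes"]], paths[["arms"]])
  if (!is.null(cohort$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.tsv"))
    utils::write.table(cohort$truth, paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Build and write the deterministic fixture cohort
#'
#' Convenience wrapper: [npc_fixture()] followed by [write_cohort()].
#'
#' @param dir Output directory.
#' @param spec A [fixture_spec()].
#' @return Named character vector of written paths.
#' @export
plant_fixture_cohort <- function(dir, spec = fixture_spec()) {
  paths <- write_cohort(npc_fixture(spec), dir)
  paths
}

#' Parameters for the stochastic cohort simulator
#'
#' @param n_patients Cohort size.
#' @param subtype_prevalences Named probabilities (summing to 1) of the
#'   three subtypes; defaults follow the proportions observed in an 82-tumor
#'   discovery cohort (9:34:39).
#' @param co_occurrence_rate Probability that a RAS/PI3K/AKT patient also
#'   carries a cell-cycle copy-number event (default 4/9, matching the
#'   fixture's overlap plan).
#' @param annotation_rate Probability that an unclassified patient carries a
#'   mutation in an epigenetic-regulator or Notch gene.
#' @param background_mutation_mean Poisson mean of passenger mutations per
#'   patient.
#' @param median_pfs_months Named per-subtype PFS medians in months;
#'   defaults 18 (RAS/PI3K/AKT), 36 (cell-cycle), 60 (unclassified) encode
#'   the poor / intermediate / good progression ordering.
#' @param median_os_months Named per-subtype OS medians; default twice the
#'   PFS medians.
#' @param censor_window_months Independent uniform administrative censoring
#'   window (months).
#' @param seed Integer seed; the simulator is fully reproducible given it.
#' @return An object of class `npc_sim_params`.
#' @export
simulation_params <- function(
    n_patients = 200L,
    subtype_prevalences = c(RAS_PI3K_AKT = 9, CELL_CYCLE = 34, UNCLASSIFIED = 39) / 82,
    co_occurrence_rate = 4 / 9,
    annotation_rate = 0.6,
    background_mutation_mean = 2,
    median_pfs_months = c(RAS_PI3K_AKT = 18, CELL_CYCLE = 36, UNCLASSIFIED = 60),
    median_os_months = 2 * median_pfs_months,
    censor_window_months = 96,
    seed = 1L) {
  if (abs(sum(subtype_prevalences) - 1) > 1e-8) {
    stop("simulation_params: prevalences must sum to 1", call. = FALSE)
  }
  if (!all(sort(names(subtype_prevalences)) == sort(SUBTYPES))) {
    stop("simulation_params: prevalences must be named by the three subtypes",
         call. = FALSE)
  }
  if (any(median_pfs_months <= 0) || any(median_os_months <= 0)) {
    stop("simulation_params: medians must be positive", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    subtype_prevalences = subtype_prevalences,
    co_occurrence_rate = co_occurrence_rate,
    annotation_rate = annotation_rate,
    background_mutation_mean = background_mutation_mean,
    median_pfs_months = median_pfs_months,
    median_os_months = median_os_months,
    censor_window_months = censor_window_months,
    seed = as.integer(seed)
  ), class = "npc_sim_params")
}

#' Simulate a stochastic cohort
#'
#' Draws each patient's subtype from the configured prevalences, plants
#' molecular evidence consistent with the drawn subtype (RAS-pathway
#' mutations for tier 1, cell-cycle copy-number events for tier 2, optional
#' annotation-gene mutations for unclassified patients, plus Poisson
#' passenger mutations), and generates exponential PFS/OS times with
#' subtype-specific rates `ln 2 / median` under independent uniform
#' administrative censoring. The truth table records the drawn subtype and
#' the uncensored event times. The same seed reproduces the cohort exactly.
#'
#' @param params A [simulation_params()].
#' @return A list of class `npc_cohort` with `mutations`, `segments`,
#'   `clinical`, `truth`, `gene_model`, `arm_table`, `params`.
#' @export
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "npc_sim_params"))
  set.seed(params$seed)
  gm <- npc_gene_model()
  genes <- gm$genes
  n <- params$n_patients
  ids <- sprintf("SIM%04d", seq_len(n))
  subtype <- sample(SUBTYPES, n, replace = TRUE,
                    prob = params$subtype_prevalences[SUBTYPES])
  tier1_genes <- c("KRAS", "NRAS", "HRAS", "AKT1", "PIK3CA")
  tier2_events <- c("CDKN2A:deleted", "CDKN2B:deleted",
                    "CCND1:amplified", "CDKN1B:amplified")
  ann_genes <- c("KMT2C", "KMT2D", "KMT2B", "PRDM2", "PRDM16", "NCOR2",
                 "KAT6B", "EP300", "CREBBP", "NOTCH1", "NOTCH2")

  mut_sample <- character(); mut_gene <- character(); mut_class <- character()
  mut_score <- numeric()
  seg_sample <- character(); seg_event <- character()

  i1 <- which(subtype == "RAS_PI3K_AKT")
  if (length(i1) > 0) {
    mut_sample <- c(mut_sample, ids[i1])
    mut_gene <- c(mut_gene, sample(tier1_genes, length(i1), replace = TRUE))
    mut_class <- c(mut_class, rep("nonsynonymous_SNV", length(i1)))
    mut_score <- c(mut_score, round(stats::runif(length(i1), 0.1, 0.9), 2))
    co <- i1[stats::runif(length(i1)) < params$co_occurrence_rate]
    if (length(co) > 0) {
      seg_sample <- c(seg_sample, ids[co])
      seg_event <- c(seg_event, sample(tier2_events, length(co), replace = TRUE))
    }
  }
  i2 <- which(subtype == "CELL_CYCLE")
  if (length(i2) > 0) {
    seg_sample <- c(seg_sample, ids[i2])
    seg_event <- c(seg_event, sample(tier2_events, length(i2), replace = TRUE))
  }
  i3 <- which(subtype == "UNCLASSIFIED")
  if (length(i3) > 0) {
    ann <- i3[stats::runif(length(i3)) < params$annotation_rate]
    if (length(ann) > 0) {
      mut_sample <- c(mut_sample, ids[ann])
      mut_gene <- c(mut_gene, sample(ann_genes, length(ann), replace = TRUE))
      mut_class <- c(mut_class, rep("nonsynonymous_SNV", length(ann)))
      mut_score <- c(mut_score, round(stats::runif(length(ann)), 2))
    }
  }
  n_bg <- stats::rpois(n, params$background_mutation_mean)
  if (sum(n_bg) > 0) {
    bg_ids <- rep(ids, n_bg)
    mut_sample <- c(mut_sample, bg_ids)
    mut_gene <- c(mut_gene, sample(c("TP53", "TTN"), sum(n_bg), replace = TRUE))
    cls <- sample(c("nonsynonymous_SNV", "silent"), sum(n_bg), replace = TRUE)
    mut_class <- c(mut_class, cls)
    sc <- round(stats::runif(sum(n_bg)), 2)
    sc[cls == "silent"] <- NA_real_
    mut_score <- c(mut_score, sc)
  }
  gi <- match(mut_gene, genes$gene)
  mutations <- data.frame(
    sample_id = mut_sample, gene = mut_gene, chrom = genes$chrom[gi],
    pos = genes$start[gi] + 501L,
    ref = ifelse(mut_class == "silent", "C", "G"),
    alt = ifelse(mut_class == "silent", "T", "A"),
    variant_class = mut_class, score = mut_score, stringsAsFactors = FALSE
  )
  mutations <- mutations[order(mutations$sample_id, mutations$gene), , drop = FALSE]
  rownames(mutations) <- NULL

  if (length(seg_sample) > 0) {
    parts <- strsplit(seg_event, ":", fixed = TRUE)
    sg <- vapply(parts, `[`, character(1), 1)
    st <- vapply(parts, `[`, character(1), 2)
    gi <- match(sg, genes$gene)
    segments <- data.frame(
      sample_id = seg_sample, chrom = genes$chrom[gi],
      start = genes$start[gi] - 5000L, end = genes$end[gi] + 5000L,
      log2_ratio = ifelse(st == "amplified", 1, -1),
      n_probes = 50L, stringsAsFactors = FALSE
    )
    segments <- segments[order(segments$sample_id, segments$chrom, segments$start), ,
                         drop = FALSE]
    rownames(segments) <- NULL
  } else {
    segments <- data.frame(sample_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           log2_ratio = numeric(), n_probes = integer(),
                           stringsAsFactors = FALSE)
  }

  rate_pfs <- log(2) / params$median_pfs_months[subtype]
  rate_os <- log(2) / params$median_os_months[subtype]
  pfs_true <- stats::rexp(n, rate_pfs)
  os_true <- stats::rexp(n, rate_os)
  c_pfs <- stats::runif(n, 0, params$censor_window_months)
  c_os <- stats::runif(n, 0, params$censor_window_months)
  clinical <- data.frame(
    sample_id = ids,
    age_years = 19 + floor(stats::runif(n, 0, 53)),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.75, 0.25)),
    stage = sample(c("early", "advanced"), n, replace = TRUE, prob = c(0.09, 0.91)),
    who_class = sample(c("NKUC", "NKDC", "KSCC"), n, replace = TRUE,
                       prob = c(0.89, 0.085, 0.025)),
    os_months = round(pmin(os_true, c_os), 1),
    os_event = as.integer(os_true <= c_os),
    pfs_months = round(pmin(pfs_true, c_pfs), 1),
    pfs_event = as.integer(pfs_true <= c_pfs),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(sample_id = ids, subtype = subtype,
                      pfs_true = pfs_true, os_true = os_true,
                      stringsAsFactors = FALSE)
  structure(list(mutations = mutations, segments = segments,
                 clinical = clinical, truth = truth,
                 gene_model = genes, arm_table = gm$arms, params = params),
            class = "npc_cohort")
}

#' @export
print.npc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic NPC cohort: %d patient(s), %d mutation(s), %d segment(s)\n",
              nrow(x$clinical), nrow(x$mutations), nrow(x$segments)))
  invisible(x)
}
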