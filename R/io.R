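# Canonical variant-class vocabulary used throughout the package.
VARIANT_CLASSES <- c(
  "nonsynonymous_SNV", "frameshift_indel", "inframe_indel",
  "stopgain", "stoploss", "splicing", "silent", "other"
)

# Classes counted as nonsilent (protein-altering or splice-disrupting).
NONSILENT_CLASSES <- setdiff(VARIANT_CLASSES, c("silent", "other"))

#' Normalize chromosome names to a canonical prefix style
#'
#' Input files from different centers may or may not carry a `"chr"` prefix.
#' All readers funnel chromosome names through this function so that overlap
#' logic never compares `"9"` with `"chr9"`.
#'
#' @param x Character vector of chromosome names.
#' @param style Either `"chr"` (default; names get a `"chr"` prefix) or
#'   `"plain"` (prefix stripped).
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_chrom(c("9", "chr9", "X"))
normalize_chrom <- function(x, style = c("chr", "plain")) {
  style <- match.arg(style)
  x <- as.character(x)
  bare <- sub("^chr", "", x)
  if (style == "chr") paste0("chr", bare) else bare
}

#' Default mapping from MAF variant-classification labels to canonical classes
#'
#' The mapping is shipped as a plain-text table (`extdata/variant_class_map.tsv`)
#' so that additional MAF dialect labels can be added without code changes.
#' Labels already in the canonical vocabulary map to themselves, which makes
#' write/read round trips lossless.
#'
#' @return A data.frame with columns `label` and `class`.
#' @export
variant_class_map <- function() {
  path <- system.file("extdata", "variant_class_map.tsv", package = "npcmolclass")
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "class") %in% names(map)))
  map
}

.map_variant_class <- function(labels, map) {
  idx <- match(labels, map$label)
  out <- map$class[idx]
  unknown <- unique(labels[is.na(idx)])
  if (length(unknown) > 0) {
    warning("unknown variant classification label(s) mapped to 'other': ",
            paste(unknown, collapse = ", "), call. = FALSE)
    out[is.na(idx)] <- "other"
  }
  out
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

.row_error <- function(what, rows, msg) {
  # rows are data-row indices; +1 converts to file line numbers (header = 1)
  stop(sprintf("%s: %s at line(s) %s", what, msg,
               paste(rows + 1L, collapse = ", ")), call. = FALSE)
}

#' Read a MAF-like somatic mutation table
#'
#' Reads the tab-separated mutation format used throughout the package: a
#' narrow MAF subset with one somatic variant call per row. Variant
#' classification labels are translated to the canonical vocabulary
#' (`nonsynonymous_SNV`, `frameshift_indel`, `inframe_indel`, `stopgain`,
#' `stoploss`, `splicing`, `silent`, `other`) via [variant_class_map()];
#' unknown labels become `other` with a warning. A missing pathogenicity
#' score is stored as `NA`, never as 0, because 0 is a legal score.
#'
#' @param path Path to a tab-separated file with header columns
#'   `Tumor_Sample_Barcode`, `Hugo_Symbol`, `Chromosome`, `Start_Position`,
#'   `Reference_Allele`, `Tumor_Seq_Allele2`, `Variant_Classification` and
#'   optionally `ParsSNP_Score`.
#' @param class_map Optional replacement mapping table (columns `label`,
#'   `class`); defaults to [variant_class_map()].
#' @param chrom_style Canonical chromosome-name style, see [normalize_chrom()].
#' @return A data.frame with columns `sample_id`, `gene`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `variant_class`, `score`.
#' @export
read_mutations <- function(path, class_map = variant_class_map(),
                           chrom_style = "chr") {
  if (!file.exists(path)) stop("mutation file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  required <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
                "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
                "Variant_Classification")
  .require_columns(raw, required, "mutation file")
  if (nrow(raw) == 0) {
    return(data.frame(sample_id = character(), gene = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      variant_class = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  pos <- suppressWarnings(as.integer(raw$Start_Position))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad) > 0) .row_error("mutation file", bad, "unparsable or non-positive coordinate")
  same <- which(raw$Reference_Allele == raw$Tumor_Seq_Allele2)
  if (length(same) > 0) .row_error("mutation file", same, "reference allele equals alternate allele")
  score <- rep(NA_real_, nrow(raw))
  if ("ParsSNP_Score" %in% names(raw)) {
    txt <- raw$ParsSNP_Score
    has <- !is.na(txt) & nzchar(trimws(txt))
    score[has] <- suppressWarnings(as.numeric(txt[has]))
    bad <- which(has & (is.na(score) | score < 0 | score > 1))
    if (length(bad) > 0) .row_error("mutation file", bad, "pathogenicity score outside [0,1]")
  }
  data.frame(
    sample_id = raw$Tumor_Sample_Barcode,
    gene = raw$Hugo_Symbol,
    chrom = normalize_chrom(raw$Chromosome, chrom_style),
    pos = pos,
    ref = raw$Reference_Allele,
    alt = raw$Tumor_Seq_Allele2,
    variant_class = .map_variant_class(raw$Variant_Classification, class_map),
    score = score,
    stringsAsFactors = FALSE
  )
}

#' Write a somatic mutation table
#'
#' Inverse of [read_mutations()]: canonical variant classes are written
#' verbatim (they map to themselves on re-read), missing scores as empty
#' cells.
#'
#' @param mutations Data.frame as returned by [read_mutations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  out <- data.frame(
    Tumor_Sample_Barcode = mutations$sample_id,
    Hugo_Symbol = mutations$gene,
    Chromosome = mutations$chrom,
    Start_Position = mutations$pos,
    Reference_Allele = mutations$ref,
    Tumor_Seq_Allele2 = mutations$alt,
    Variant_Classification = mutations$variant_class,
    ParsSNP_Score = ifelse(is.na(mutations$score), "",
                           format(mutations$score, trim = TRUE, scientific = FALSE)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read copy-number segments in SEG format
#'
#' SEG rows carry 1-based inclusive coordinates; internally the package uses
#' 0-based half-open coordinates everywhere, so `loc.start` is decremented on
#' input. Records are sorted by (sample, chromosome, start), which makes
#' reader output deterministic for a fixed file.
#'
#' @param path Path to a tab-separated SEG file with header columns `sample`
#'   (or `ID`), `chromosome` (or `chrom`), `loc.start`, `loc.end`, optional
#'   `num.mark`, and `seg.mean`.
#' @param chrom_style See [normalize_chrom()].
#' @return A data.frame with columns `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `log2_ratio`, `n_probes` (`NA` when absent).
#' @export
read_segments <- function(path, chrom_style = "chr") {
  if (!file.exists(path)) stop("SEG file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(raw)
  pick <- function(aliases) {
    hit <- nm[tolower(nm) %in% aliases]
    if (length(hit) == 0) NA_character_ else hit[1]
  }
  cols <- c(sample = pick(c("sample", "id", "sampleid", "sample_id")),
            chrom = pick(c("chromosome", "chrom")),
            start = pick("loc.start"), end = pick("loc.end"),
            log2 = pick("seg.mean"))
  missing <- names(cols)[is.na(cols)]
  if (length(missing) > 0) {
    stop("SEG file: missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      log2_ratio = numeric(), n_probes = integer(),
                      stringsAsFactors = FALSE))
  }
  start1 <- suppressWarnings(as.numeric(raw[[cols["start"]]]))
  end1 <- suppressWarnings(as.numeric(raw[[cols["end"]]]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad) > 0) .row_error("SEG file", bad, "unparsable coordinate")
  start0 <- as.integer(start1) - 1L
  end0 <- as.integer(end1)
  bad <- which(start0 >= end0 | start0 < 0L)
  if (length(bad) > 0) .row_error("SEG file", bad, "empty or negative interval after coordinate conversion")
  probes_col <- pick("num.mark")
  n_probes <- if (is.na(probes_col)) rep(NA_integer_, nrow(raw)) else
    suppressWarnings(as.integer(raw[[probes_col]]))
  seg <- data.frame(
    sample_id = as.character(raw[[cols["sample"]]]),
    chrom = normalize_chrom(raw[[cols["chrom"]]], chrom_style),
    start = start0, end = end0,
    log2_ratio = suppressWarnings(as.numeric(raw[[cols["log2"]]])),
    n_probes = n_probes,
    stringsAsFactors = FALSE
  )
  seg <- seg[order(seg$sample_id, seg$chrom, seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Write copy-number segments in SEG format
#'
#' Converts internal 0-based half-open coordinates back to 1-based inclusive
#' SEG rows; a read/write cycle is the identity on well-formed segments.
#'
#' @param segments Data.frame as returned by [read_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- data.frame(
    sample = segments$sample_id,
    chromosome = segments$chrom,
    loc.start = segments$start + 1L,
    loc.end = segments$end,
    num.mark = ifelse(is.na(segments$n_probes), "", as.character(segments$n_probes)),
    seg.mean = format(segments$log2_ratio, trim = TRUE, scientific = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED gene model plus a chromosome-arm table
#'
#' The gene model is BED4 (0-based half-open, no header) with the gene symbol
#' in column 4; the arm table is a tab-separated file with header columns
#' `chrom`, `start`, `end`, `arm`, also 0-based half-open. Each gene is
#' annotated with the arm whose half-open interval contains the gene's
#' midpoint.
#'
#' @param bed_path Path to the BED4 gene model.
#' @param arm_path Path to the arm table.
#' @param chrom_style See [normalize_chrom()].
#' @return A data.frame with columns `gene`, `chrom`, `start`, `end`, `arm`.
#' @export
read_gene_model <- function(bed_path, arm_path, chrom_style = "chr") {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path, call. = FALSE)
  if (!file.exists(arm_path)) stop("arm table not found: ", arm_path, call. = FALSE)
  bed <- utils::read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("gene model must be BED4+ (symbol in column 4)", call. = FALSE)
  genes <- data.frame(
    gene = as.character(bed[[4]]),
    chrom = normalize_chrom(bed[[1]], chrom_style),
    start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]]),
    stringsAsFactors = FALSE
  )
  bad <- which(genes$start >= genes$end)
  if (length(bad) > 0) .row_error("gene model", bad - 1L, "empty gene span")
  dup <- unique(genes$gene[duplicated(genes$gene)])
  if (length(dup) > 0) {
    stop("gene model: duplicate gene symbol(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  arms <- utils::read.delim(arm_path, stringsAsFactors = FALSE)
  .require_columns(arms, c("chrom", "start", "end", "arm"), "arm table")
  arms$chrom <- normalize_chrom(arms$chrom, chrom_style)
  genes$arm <- assign_arm(genes, arms)
  genes
}

#' Assign each gene to the chromosome arm containing its midpoint
#'
#' @param genes Data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param arms Data.frame with `chrom`, `start`, `end`, `arm`.
#' @return Character vector of arm labels (`NA` where no arm interval
#'   contains the midpoint).
#' @export
assign_arm <- function(genes, arms) {
  mid <- floor((genes$start + genes$end) / 2)
  out <- rep(NA_character_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    hit <- which(arms$chrom == genes$chrom[i] &
                   arms$start <= mid[i] & mid[i] < arms$end)
    if (length(hit) > 0) out[i] <- arms$arm[hit[1]]
  }
  if (anyNA(out)) {
    warning("gene(s) outside all arm intervals: ",
            paste(genes$gene[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a gene model as BED4 plus an arm table
#'
#' @param genes Data.frame with `gene`, `chrom`, `start`, `end`.
#' @param arms Data.frame with `chrom`, `start`, `end`, `arm`.
#' @param bed_path,arm_path Output paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_gene_model <- function(genes, arms, bed_path, arm_path) {
  bed <- genes[, c("chrom", "start", "end", "gene")]
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(arms[, c("chrom", "start", "end", "arm")], arm_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed_path, arms = arm_path))
}

#' Read a clinical follow-up table
#'
#' Tab-separated with header columns `sample_id`, `age_years`, `sex`,
#' `stage`, `who_class`, `os_months`, `os_event`, `pfs_months`, `pfs_event`;
#' empty cells mean missing. TNM stage groups I/II are collapsed to
#' `early` and III/IV to `advanced`. A survival time must be present exactly
#' when its event indicator is, so a record is either fully informative or
#' fully missing for each endpoint.
#'
#' @param path Path to the clinical table.
#' @return A data.frame with typed columns; `stage` is `early`/`advanced`,
#'   `sex` is `male`/`female`, `who_class` one of `NKUC`, `NKDC`, `KSCC`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  .require_columns(raw, "sample_id", "clinical file")
  n <- nrow(raw)
  get <- function(col) if (col %in% names(raw)) raw[[col]] else rep("", n)
  blank2na <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA_character_, trimws(x))
  num <- function(x, col) {
    x <- blank2na(x)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) .row_error("clinical file", bad, paste("unparsable", col))
    out
  }
  stage_raw <- blank2na(get("stage"))
  stage <- rep(NA_character_, n)
  stage[stage_raw %in% c("I", "II", "early")] <- "early"
  stage[stage_raw %in% c("III", "IV", "advanced")] <- "advanced"
  bad <- which(!is.na(stage_raw) & is.na(stage))
  if (length(bad) > 0) .row_error("clinical file", bad, "unrecognized stage")
  sex_raw <- tolower(blank2na(get("sex")))
  sex <- rep(NA_character_, n)
  sex[sex_raw %in% c("male", "m")] <- "male"
  sex[sex_raw %in% c("female", "f")] <- "female"
  bad <- which(!is.na(sex_raw) & is.na(sex))
  if (length(bad) > 0) .row_error("clinical file", bad, "unrecognized sex")
  who <- blank2na(get("who_class"))
  bad <- which(!is.na(who) & !who %in% c("NKUC", "NKDC", "KSCC"))
  if (length(bad) > 0) .row_error("clinical file", bad, "unrecognized WHO class")
  out <- data.frame(
    sample_id = raw$sample_id,
    age_years = num(get("age_years"), "age"),
    sex = sex, stage = stage, who_class = who,
    os_months = num(get("os_months"), "OS time"),
    os_event = num(get("os_event"), "OS event"),
    pfs_months = num(get("pfs_months"), "PFS time"),
    pfs_event = num(get("pfs_event"), "PFS event"),
    stringsAsFactors = FALSE
  )
  for (ep in c("os", "pfs")) {
    tm <- out[[paste0(ep, "_months")]]
    ev <- out[[paste0(ep, "_event")]]
    bad <- which(is.na(tm) != is.na(ev))
    if (length(bad) > 0) .row_error("clinical file", bad, paste(toupper(ep), "time and event must be present together"))
    bad <- which(!is.na(tm) & tm < 0)
    if (length(bad) > 0) .row_error("clinical file", bad, paste("negative", toupper(ep), "time"))
    bad <- which(!is.na(ev) & !ev %in% c(0, 1))
    if (length(bad) > 0) .row_error("clinical file", bad, paste(toupper(ep), "event not 0/1"))
    out[[paste0(ep, "_event")]] <- as.integer(ev)
  }
  out
}

#' Write a clinical follow-up table
#'
#' @param clinical Data.frame as returned by [read_clinical()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  out <- clinical
  for (col in names(out)) {
    x <- out[[col]]
    out[[col]] <- ifelse(is.na(x), "", format(x, trim = TRUE, scientific = FALSE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
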