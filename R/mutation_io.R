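#' @importFrom utils read.delim write.table head
NULL

# canonical record columns, fixed order
.maf_canonical_cols <- c(
  "patient_id", "gene", "transcript_id", "protein_pos", "aa_change",
  "consequence", "chrom", "genomic_pos", "ref_allele", "alt_allele",
  "cancer_type"
)

.consequence_levels <- c(
  "missense", "nonsense", "nonstop", "silent", "splice", "frameshift",
  "inframe_indel", "start_site", "other"
)

# default TCGA-style MAF dialect -> canonical field
.maf_default_map <- list(
  patient_id    = c("Tumor_Sample_Barcode", "patient_id"),
  gene          = c("Hugo_Symbol", "gene"),
  transcript_id = c("Transcript_ID", "Annotation_Transcript", "Transcript",
                    "transcript_id"),
  protein_change = c("Protein_Change", "HGVSp_Short", "HGVSp"),
  consequence   = c("Variant_Classification", "consequence"),
  chrom         = c("Chromosome", "chrom"),
  genomic_pos   = c("Start_Position", "Start_position", "genomic_pos"),
  ref_allele    = c("Reference_Allele", "ref_allele"),
  alt_allele    = c("Tumor_Seq_Allele2", "Tumor_Seq_Allele1", "alt_allele"),
  cancer_type   = c("Cancer_Type", "tumor_type", "cancer_type")
)

# parse "p.V600E" / "V600E" style short protein change -> list(pos, change)
.parse_protein_change <- function(x) {
  x <- sub("^p\\.", "", trimws(x))
  pos <- suppressWarnings(as.integer(sub("^\\(?[A-Za-z\\*]{1,3}?(\\d+).*$",
                                         "\\1", x)))
  pos[!grepl("^\\(?[A-Za-z\\*]", x)] <- NA_integer_
  pos[x == ""] <- NA_integer_
  list(pos = pos, change = ifelse(x == "", NA_character_, x))
}

#' Map MAF variant classification strings to consequence classes
#'
#' Recognizes the TCGA MAF dialect (`Missense_Mutation`, `Silent`,
#' `Frame_Shift_Del`, ...) as well as already-canonical class names;
#' anything unrecognized maps to `"other"`.
#'
#' @param x character vector of variant classification strings.
#' @return character vector over the canonical classes: missense, nonsense,
#'   nonstop, silent, splice, frameshift, inframe_indel, start_site, other.
#' @export
classify_consequence <- function(x) {
  lut <- c(
    Missense_Mutation = "missense",
    Nonsense_Mutation = "nonsense",
    Nonstop_Mutation  = "nonstop",
    Silent            = "silent",
    Splice_Site       = "splice",
    Splice_Region     = "splice",
    Frame_Shift_Del   = "frameshift",
    Frame_Shift_Ins   = "frameshift",
    In_Frame_Del      = "inframe_indel",
    In_Frame_Ins      = "inframe_indel",
    Translation_Start_Site = "start_site",
    Start_Codon_SNP   = "start_site",
    Start_Codon_Del   = "start_site",
    Start_Codon_Ins   = "start_site"
  )
  lut <- c(lut, stats::setNames(.consequence_levels, .consequence_levels))
  out <- unname(lut[as.character(x)])
  out[is.na(out)] <- "other"
  out
}

#' Read a MAF-style mutation table
#'
#' Reads a tab-separated mutation table (TCGA MAF dialect or the package's
#' canonical schema), returning one canonical record per row. Rows whose
#' protein change cannot be parsed keep `protein_pos = NA` (they are kept,
#' not dropped; see [filter_coding()]). Rows with an unparseable genomic
#' position are skipped with a warning and counted in the load report.
#'
#' @param path path to a tab-separated file with a header row; lines
#'   starting with `#` are ignored.
#' @param column_map optional named list overriding the dialect lookup,
#'   e.g. `list(gene = "GeneSymbol")`; names are canonical fields
#'   (`patient_id`, `gene`, `transcript_id`, `protein_change`,
#'   `consequence`, `chrom`, `genomic_pos`, `ref_allele`, `alt_allele`,
#'   `cancer_type`).
#' @return data.frame of canonical mutation records with attribute
#'   `load_report` (rows read / kept / skipped).
#' @export
read_maf <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  map <- .maf_default_map
  if (!is.null(column_map)) for (f in names(column_map)) map[[f]] <- column_map[[f]]

  pick <- function(field) {
    hit <- intersect(map[[field]], names(raw))
    if (length(hit)) raw[[hit[1L]]] else NULL
  }
  for (mandatory in c("gene", "patient_id", "consequence")) {
    if (is.null(pick(mandatory)))
      stop("mandatory column for '", mandatory, "' not found (expected one of: ",
           paste(map[[mandatory]], collapse = ", "), ")")
  }
  n_raw <- nrow(raw)
  grab <- function(field, default = NA_character_) {
    v <- pick(field)
    if (is.null(v)) rep(default, n_raw) else ifelse(v == "", default, v)
  }
  if ("protein_pos" %in% names(raw)) {
    # already-canonical schema: positions and changes are stored directly
    aa <- if ("aa_change" %in% names(raw)) raw[["aa_change"]] else
      rep(NA_character_, n_raw)
    pc <- list(pos = suppressWarnings(as.integer(raw[["protein_pos"]])),
               change = ifelse(aa %in% c("", NA), NA_character_, aa))
  } else {
    pc <- .parse_protein_change(if (is.null(pick("protein_change")))
      rep("", n_raw) else pick("protein_change"))
  }
  gpos <- suppressWarnings(as.integer(grab("genomic_pos")))
  rec <- data.frame(
    patient_id = grab("patient_id"),
    gene = grab("gene"),
    transcript_id = grab("transcript_id"),
    protein_pos = pc$pos,
    aa_change = pc$change,
    consequence = classify_consequence(grab("consequence")),
    chrom = grab("chrom"),
    genomic_pos = gpos,
    ref_allele = toupper(grab("ref_allele")),
    alt_allele = toupper(grab("alt_allele")),
    cancer_type = grab("cancer_type"),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(grab("genomic_pos")) & grab("genomic_pos") != "" & is.na(gpos)
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable genomic position skipped")
    rec <- rec[!bad, , drop = FALSE]
  }
  attr(rec, "load_report") <- list(rows_read = n_raw, rows_kept = nrow(rec),
                                   rows_skipped = n_raw - nrow(rec))
  rec
}

#' Write mutation records in the canonical TSV schema
#'
#' Fixed column order; [read_maf()] on the result reproduces the records
#' (identity round-trip).
#'
#' @param records canonical mutation record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(records, path) {
  stopifnot(all(.maf_canonical_cols %in% names(records)))
  out <- records[, .maf_canonical_cols, drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Keep only records usable for protein-position hotspot calling
#'
#' The subset of records with a parsed protein position, input order
#' preserved. Idempotent.
#'
#' @param records canonical mutation record data.frame.
#' @return the subset data.frame.
#' @export
filter_coding <- function(records) {
  records[!is.na(records$protein_pos), , drop = FALSE]
}

#' Aggregate mutations per gene and protein position
#'
#' For each gene, counts the number of *distinct patients* mutated at each
#' protein position (one patient mutated twice at a site counts once, so a
#' site's recurrence can never exceed the cohort size), and records the
#' most frequent transcript supplying positions for the gene.
#'
#' @param records canonical records; all must have `protein_pos`
#'   (apply [filter_coding()] first).
#' @param dedup_patients if `FALSE`, count raw mutation rows instead of
#'   distinct patients.
#' @param protein_lengths optional named vector gene -> protein length.
#' @return named list of `position_counts` objects: `gene`,
#'   `transcript_id`, `counts` (named vector position -> recurrence),
#'   `protein_length`.
#' @export
aggregate_positions <- function(records, dedup_patients = TRUE,
                                protein_lengths = NULL) {
  if (any(is.na(records$protein_pos)))
    stop("records contain missing protein_pos; run filter_coding() first")
  out <- lapply(split(records, records$gene), function(df) {
    key <- df$protein_pos
    cnt <- if (dedup_patients) {
      tapply(df$patient_id, key, function(p) length(unique(p)))
    } else {
      tapply(df$patient_id, key, length)
    }
    cnt <- cnt[order(as.integer(names(cnt)))]
    tx <- names(sort(table(df$transcript_id), decreasing = TRUE))
    gene <- df$gene[1L]
    plen <- if (!is.null(protein_lengths) && gene %in% names(protein_lengths))
      as.integer(protein_lengths[[gene]]) else NA_integer_
    if (!is.na(plen) && any(as.integer(names(cnt)) > plen))
      stop("gene ", gene, ": mutated position beyond protein length ", plen)
    structure(list(gene = gene,
                   transcript_id = if (length(tx)) tx[1L] else NA_character_,
                   counts = stats::setNames(as.integer(cnt), names(cnt)),
                   protein_length = plen),
              class = "position_counts")
  })
  out[order(names(out))]
}

#' Per-cancer-type cohort summary
#'
#' @param records canonical mutation record data.frame.
#' @return data.frame with one row per `cancer_type`: distinct `n_patients`
#'   and total `n_mutations`.
#' @export
cohort_summary <- function(records) {
  if (!nrow(records))
    return(data.frame(cancer_type = character(), n_patients = integer(),
                      n_mutations = integer(), stringsAsFactors = FALSE))
  sp <- split(records$patient_id, records$cancer_type)
  data.frame(
    cancer_type = names(sp),
    n_patients = vapply(sp, function(p) length(unique(p)), integer(1)),
    n_mutations = lengths(sp),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
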