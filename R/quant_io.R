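#' @title proteinGroups-dialect input/output and identification filters
#'
#' @description
#' MaxQuant writes protein-level quantification as a tab-separated
#' `proteinGroups.txt` with one row per protein group: semicolon-joined
#' accessions, gene names, unique-peptide counts, `"+"`-flag columns marking
#' decoy (reverse) and contaminant entries, and one raw intensity column per
#' sample. These readers consume that dialect (raw `Intensity <sample>`
#' columns by default; the column-name template is configurable) and apply
#' the standard identification filters: drop reverse hits and contaminants,
#' and require a minimum number of unique peptides.
#'
#' A zero or absent intensity means "not quantified"; no distinction between
#' the two is kept.
#'
#' @name quant_io
NULL

.PG_META_COLS <- c("Protein IDs", "Gene names", "Unique peptides",
                   "Reverse", "Potential contaminant")

#' Construct a protein quantification table
#'
#' @param protein_id character, unique per row (semicolon-joined accessions,
#'   group representative first).
#' @param gene_name character (may be empty strings).
#' @param unique_peptides non-negative integer vector.
#' @param is_reverse,is_contaminant logical vectors.
#' @param intensities numeric matrix (proteins x samples) of non-negative raw
#'   intensities, with column names equal to sample ids; 0 = not quantified.
#' @return A `data.frame` of class `protein_quant_table` with metadata columns
#'   followed by one numeric column per sample.
#' @export
protein_quant_table <- function(protein_id, gene_name, unique_peptides,
                                is_reverse, is_contaminant, intensities) {
  intensities <- as.matrix(intensities)
  n <- length(protein_id)
  stopifnot(nrow(intensities) == n, !is.null(colnames(intensities)))
  if (anyDuplicated(protein_id)) stop("protein_id must be unique")
  if (any(unique_peptides < 0)) stop("unique_peptides must be >= 0")
  if (any(intensities < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  intensities[is.na(intensities)] <- 0
  out <- data.frame(protein_id = as.character(protein_id),
                    gene_name = as.character(gene_name),
                    unique_peptides = as.integer(unique_peptides),
                    is_reverse = as.logical(is_reverse),
                    is_contaminant = as.logical(is_contaminant),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(intensities, check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "sample_ids") <- colnames(intensities)
  class(out) <- c("protein_quant_table", "data.frame")
  out
}

#' Sample ids quantified in a protein table
#' @param table a [protein_quant_table()].
#' @export
table_samples <- function(table) attr(table, "sample_ids")

#' Intensity matrix (proteins x samples) of a protein table
#' @param table a [protein_quant_table()].
#' @return numeric matrix with protein ids as row names.
#' @export
table_intensities <- function(table) {
  m <- as.matrix(table[, table_samples(table), drop = FALSE])
  rownames(m) <- table$protein_id
  m
}

#' Read a MaxQuant-style proteinGroups table
#'
#' @param path path to a tab-separated proteinGroups file (UTF-8, header row).
#' @param design an [experiment_design()]; one intensity column per design
#'   sample is required.
#' @param intensity_template `sprintf`-style template mapping a sample id to
#'   its intensity column name. Default `"Intensity %s"` (raw MaxQuant
#'   intensities; use `"LFQ intensity %s"` for the MaxLFQ columns).
#' @return A [protein_quant_table()] whose intensity columns are named by
#'   design sample ids. Empty or missing intensity cells are read as 0;
#'   `"+"` in `Reverse` / `Potential contaminant` sets the flags.
#' @export
read_protein_groups <- function(path, design,
                                intensity_template = "Intensity %s") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  missing_meta <- setdiff(.PG_META_COLS, names(raw))
  if (length(missing_meta)) {
    stop("proteinGroups file lacks column(s): ",
         paste(missing_meta, collapse = ", "))
  }
  int_cols <- sprintf(intensity_template, design$sample_id)
  absent <- !int_cols %in% names(raw)
  if (any(absent)) {
    stop("no intensity column for sample(s): ",
         paste(design$sample_id[absent], collapse = ", "),
         " (expected column(s) ", paste(int_cols[absent], collapse = ", "), ")")
  }
  upep <- .parse_numeric_cells(raw[["Unique peptides"]], "Unique peptides",
                               default = 0)
  intens <- matrix(0, nrow = nrow(raw), ncol = length(int_cols),
                   dimnames = list(NULL, design$sample_id))
  for (j in seq_along(int_cols)) {
    intens[, j] <- .parse_numeric_cells(raw[[int_cols[j]]], int_cols[j],
                                        default = 0)
  }
  protein_quant_table(protein_id = raw[["Protein IDs"]],
                      gene_name = raw[["Gene names"]],
                      unique_peptides = upep,
                      is_reverse = raw[["Reverse"]] == "+",
                      is_contaminant = raw[["Potential contaminant"]] == "+",
                      intensities = intens)
}

# empty cells parse to `default`; anything non-numeric is a hard error
# naming the offending row and column
.parse_numeric_cells <- function(x, column, default = 0) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop("unparseable numeric value '", x[which(bad)[1]], "' in column '",
         column, "', row ", which(bad)[1])
  }
  out[is.na(out)] <- default
  out
}

#' Apply the identification filters
#'
#' Removes reverse (decoy) hits and contaminants and keeps proteins with at
#' least `min_unique_peptides` unique peptides. Input order is preserved and
#' surviving rows are unchanged; the operation is idempotent.
#'
#' @param table a [protein_quant_table()].
#' @param min_unique_peptides minimum unique-peptide count (default 2).
#' @return the filtered [protein_quant_table()].
#' @export
filter_identified <- function(table, min_unique_peptides = 2L) {
  keep <- !table$is_reverse & !table$is_contaminant &
    table$unique_peptides >= min_unique_peptides
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_ids") <- table_samples(table)
  class(out) <- class(table)
  out
}

#' Write a protein table in the proteinGroups dialect
#'
#' Floats are written with 6 significant digits; flag columns use `"+"`/`""`.
#' `read_protein_groups(write_protein_groups(x))` reproduces `x`
#' field-for-field (after the canonical 6-significant-digit formatting of
#' intensities).
#'
#' @param table a [protein_quant_table()].
#' @param path output path.
#' @param intensity_template column-name template, as in
#'   [read_protein_groups()].
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(table, path,
                                 intensity_template = "Intensity %s") {
  samples <- table_samples(table)
  out <- data.frame(`Protein IDs` = table$protein_id,
                    `Gene names` = table$gene_name,
                    `Unique peptides` = table$unique_peptides,
                    Reverse = ifelse(table$is_reverse, "+", ""),
                    `Potential contaminant` = ifelse(table$is_contaminant,
                                                     "+", ""),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (s in samples) {
    out[[sprintf(intensity_template, s)]] <- .format_float(table[[s]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.format_float <- function(x) sprintf("%.6g", x)
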