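# Readers and writers for the tabular and sequence formats the pipeline
# touches. Mutation tables are MAF-like TSVs, not the full MAF spec; a column
# map adapts external headers. Coordinates are 1-based inclusive throughout.

.MT_REQUIRED <- c("sample", "chrom", "pos", "ref", "alt")
.MT_DIALECTS <- c("capture", "amplicon", "registry")

#' Read a MAF-like mutation table
#'
#' Validates every row against the SNV invariants (1-based position, single
#' A/C/G/T ref and alt with ref != alt, VAF in \[0,1\] when present) and drops
#' malformed rows, reporting their row numbers. Indels (allele length != 1) are
#' rejected at this stage.
#'
#' @param path TSV file with a header row.
#' @param dialect One of `"capture"`, `"amplicon"`, `"registry"`; recorded as
#'   an attribute and used by the variant filters to decide which support
#'   fields they need.
#' @param column_map Optional named character vector mapping standard column
#'   names to the file's headers, e.g. `c(sample = "Tumor_Sample_Barcode")`.
#' @param provenance Free-text provenance note stored on the table.
#' @return A `mutation_table` (data frame) with attributes `dialect`,
#'   `provenance` and `rejected` (a data frame of dropped row numbers and the
#'   violated rule).
#' @export
read_mutation_table <- function(path, dialect = c("capture", "amplicon", "registry"),
                                column_map = NULL, provenance = path) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(x)) {
        stop(sprintf("column map refers to missing column '%s'", src),
             call. = FALSE)
      }
      names(x)[names(x) == src] <- std
    }
  }
  as_mutation_table(x, dialect = dialect, provenance = provenance)
}

#' Validate a data frame as a mutation table
#'
#' @param x Data frame with at least sample, chrom, pos, ref, alt.
#' @inheritParams read_mutation_table
#' @return A `mutation_table`; malformed rows are dropped with a message.
#' @export
as_mutation_table <- function(x, dialect = "capture", provenance = "in-memory") {
  dialect <- match.arg(dialect, .MT_DIALECTS)
  missing_cols <- setdiff(.MT_REQUIRED, names(x))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x$ref <- toupper(as.character(x$ref))
  x$alt <- toupper(as.character(x$alt))
  rule <- rep(NA_character_, nrow(x))
  flag <- function(cond, label) {
    cond[is.na(cond)] <- TRUE
    ifelse(is.na(rule) & cond, label, rule)
  }
  rule <- flag(!(nchar(x$ref) == 1L & x$ref %in% .BASES), "ref not a single A/C/G/T base")
  rule <- flag(!(nchar(x$alt) == 1L & x$alt %in% .BASES), "alt not a single A/C/G/T base")
  rule <- flag(x$ref == x$alt, "ref equals alt")
  posn <- suppressWarnings(as.numeric(x$pos))
  rule <- flag(is.na(posn) | posn < 1 | posn != floor(posn), "position not a positive integer")
  rule <- flag(is.na(x$sample) | x$sample == "", "missing sample identifier")
  rule <- flag(is.na(x$chrom) | x$chrom == "", "missing chromosome")
  if ("vaf" %in% names(x)) {
    v <- suppressWarnings(as.numeric(x$vaf))
    bad_vaf <- !is.na(x$vaf) & (is.na(v) | v < 0 | v > 1)
    rule <- ifelse(is.na(rule) & bad_vaf, "VAF outside [0,1]", rule)
  }
  bad <- !is.na(rule)
  rejected <- data.frame(row = which(bad), rule = rule[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    message(sprintf("rejected %d malformed row(s): %s", nrow(rejected),
                    paste(sprintf("row %d (%s)", rejected$row, rejected$rule),
                          collapse = "; ")))
  }
  out <- x[!bad, , drop = FALSE]
  out$pos <- as.integer(out$pos)
  rownames(out) <- NULL
  class(out) <- c("mutation_table", "data.frame")
  attr(out, "dialect") <- dialect
  attr(out, "provenance") <- provenance
  attr(out, "rejected") <- rejected
  out
}

#' Write a mutation table as TSV
#' @param x A `mutation_table`.
#' @param path Output path.
#' @export
write_mutation_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.STOPS <- c("TAA", "TAG", "TGA")

#' Construct a validated coding sequence object
#'
#' A CDS must start with ATG, have length divisible by 3, and contain exactly
#' one in-frame stop codon, at its end.
#'
#' @param seq Coding-strand sequence 5'->3' (character or `DNAString`).
#' @param gene Gene identifier.
#' @return A `cds_fasta` list with elements `gene`, `seq`, `protein_length`
#'   (number of residues, excluding the stop).
#' @export
cds_fasta <- function(seq, gene = "gene") {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (grepl("[^ACGT]", seq)) {
    stop(sprintf("%s: CDS contains non-ACGT characters", gene), call. = FALSE)
  }
  if (n %% 3L != 0L) {
    stop(sprintf("%s: CDS length %d not divisible by 3", gene, n), call. = FALSE)
  }
  if (substr(seq, 1, 3) != "ATG") {
    stop(sprintf("%s: CDS does not start with ATG", gene), call. = FALSE)
  }
  codons <- substring(seq, seq(1, n - 2, 3), seq(3, n, 3))
  stops <- which(codons %in% .STOPS)
  if (length(stops) != 1L || stops != length(codons)) {
    stop(sprintf("%s: CDS must contain exactly one in-frame stop, at the end",
                 gene), call. = FALSE)
  }
  structure(list(gene = gene, seq = seq,
                 protein_length = length(codons) - 1L),
            class = "cds_fasta")
}

#' Read one gene's coding sequence from a FASTA file
#'
#' @param path FASTA with one record per gene.
#' @param gene Record to select (matched against the first whitespace-separated
#'   token of each header); if `NULL` and the file has a single record, that
#'   record is used.
#' @return A `cds_fasta`.
#' @export
read_cds_fasta <- function(path, gene = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  recs <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(recs), "\\s+"), `[`, character(1), 1L)
  if (is.null(gene)) {
    if (length(recs) != 1L) {
      stop("FASTA has multiple records; specify 'gene'", call. = FALSE)
    }
    idx <- 1L
    gene <- ids[1L]
  } else {
    idx <- match(gene, ids)
    if (is.na(idx)) stop(sprintf("gene '%s' not found in %s", gene, path),
                         call. = FALSE)
  }
  cds_fasta(as.character(recs[[idx]]), gene = gene)
}

#' Write a CDS as FASTA
#' @param cds A `cds_fasta`.
#' @param path Output path.
#' @export
write_cds_fasta <- function(cds, path) {
  s <- Biostrings::DNAStringSet(cds$seq)
  names(s) <- cds$gene
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' @param path YAML file. Recognised fields: `bin_scheme` (path),
#'   `repeat_annotation` (path), `drift` (list of ns, lambda, pr, tau),
#'   `alpha` (significance level), `seed`, `out_dir`.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$alpha)) cfg$alpha <- 0.05
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("significance level 'alpha' must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.numeric(cfg$seed) || cfg$seed < 0 || cfg$seed != floor(cfg$seed)) {
    stop("'seed' must be a non-negative integer", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}
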