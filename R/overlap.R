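.AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

.aa_to_one <- function(code, raw) {
  up <- toupper(code)
  if (nchar(up) == 1) {
    if (!up %in% .AA3_TO_1) {
      stop(sprintf("validation error: unknown amino-acid code '%s' in '%s'",
                   code, raw), call. = FALSE)
    }
    return(up)
  }
  if (nchar(up) == 3) {
    one <- .AA3_TO_1[[up]]
    if (is.null(one)) {
      stop(sprintf("validation error: unknown amino-acid code '%s' in '%s'",
                   code, raw), call. = FALSE)
    }
    return(one)
  }
  stop(sprintf("validation error: unparseable amino-acid code '%s' in '%s'",
               code, raw), call. = FALSE)
}

#' Normalize a missense protein-change string
#'
#' Accepts one-letter or three-letter amino-acid codes, with or without the
#' `p.` prefix, case-insensitively, and emits the canonical one-letter form
#' `p.XnY` (e.g. `"P.Gly245Ser"` and `"G245S"` both become `"p.G245S"`).
#'
#' @param raw protein-change string(s).
#' @return character vector of normalized `p.XnY` strings.
#' @export
normalize_protein_change <- function(raw) {
  vapply(raw, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      stop("validation error: empty protein change", call. = FALSE)
    }
    s0 <- trimws(s)
    body <- sub("^[pP]\\.", "", s0)
    m <- regmatches(body, regexec("^([A-Za-z]+)([0-9]+)([A-Za-z]+)$", body))[[1]]
    if (length(m) != 4) {
      stop(sprintf("validation error: unparseable protein change '%s'", s0),
           call. = FALSE)
    }
    pos <- as.integer(m[3])
    if (is.na(pos) || pos < 1) {
      stop(sprintf("validation error: invalid residue position in '%s'", s0),
           call. = FALSE)
    }
    sprintf("p.%s%d%s", .aa_to_one(m[2], s0), pos, .aa_to_one(m[4], s0))
  }, character(1), USE.NAMES = FALSE)
}

# round half-up at d decimals (base round() is half-to-even)
.round_half_up <- function(x, d = 1) {
  floor(x * 10^d + 0.5) / 10^d
}

#' Overlap summary from pre-computed counts
#'
#' Computes the shared-variant rates from counts alone: each rate is
#' `100 * n_common / n`, rounded half-up to one decimal. Rates with a zero
#' denominator are `NA`.
#'
#' @param gene gene symbol.
#' @param n_germline,n_somatic,n_common non-negative counts,
#'   `n_common <= min(n_germline, n_somatic)`.
#' @return one-row data.frame with columns `gene`, `n_germline`,
#'   `n_somatic`, `n_common`, `germline_rate`, `somatic_rate`.
#' @export
overlap_summary_from_counts <- function(gene, n_germline, n_somatic, n_common) {
  if (n_common > min(n_germline, n_somatic)) {
    stop("validation error: n_common cannot exceed either input count", call. = FALSE)
  }
  rate <- function(n) if (n > 0) .round_half_up(100 * n_common / n, 1) else NA_real_
  data.frame(gene = toupper(gene), n_germline = n_germline,
             n_somatic = n_somatic, n_common = n_common,
             germline_rate = rate(n_germline), somatic_rate = rate(n_somatic),
             stringsAsFactors = FALSE)
}

#' Intersect germline and somatic missense variant tables for one gene
#'
#' Variants are matched on the key (gene, normalized protein change):
#' germline and somatic variants altering the same residue to the same
#' amino acid are counted as shared. Duplicates within each origin are
#' removed before counting. Rates are percentages of each origin's distinct
#' variants that are shared, rounded half-up to one decimal.
#'
#' @param germline,somatic data.frames with columns `gene` and
#'   `protein_change` (extra columns ignored). Protein changes are
#'   normalized with [normalize_protein_change()].
#' @param gene gene symbol to restrict to (matched case-insensitively).
#' @return one-row data.frame as in [overlap_summary_from_counts()]; empty
#'   input sets give zero counts and `NA` rates, not errors.
#' @export
compute_overlap <- function(germline, somatic, gene) {
  keys <- function(df) {
    if (!all(c("gene", "protein_change") %in% names(df))) {
      stop("validation error: variant tables need columns gene, protein_change",
           call. = FALSE)
    }
    df <- df[toupper(df$gene) == toupper(gene), , drop = FALSE]
    if (!nrow(df)) return(character())
    unique(paste(toupper(df$gene), normalize_protein_change(df$protein_change)))
  }
  gk <- keys(germline)
  sk <- keys(somatic)
  overlap_summary_from_counts(gene, length(gk), length(sk),
                              length(intersect(gk, sk)))
}

#' Read a variant table TSV
#'
#' Expects header columns `gene`, `protein_change`, optionally
#' `cdna_change`.
#'
#' @param path TSV path.
#' @return data.frame of variant records.
#' @export
read_variant_tsv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input error: file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "protein_change") %in% names(df))) {
    stop("validation error: variant TSV must have columns gene, protein_change",
         call. = FALSE)
  }
  df
}

#' Per-gene overlap table for several genes
#'
#' @inheritParams compute_overlap
#' @param genes character vector of gene symbols; defaults to all genes
#'   present in either table.
#' @return data.frame with one row per gene, mirroring the per-gene shared
#'   germline/somatic counts-and-rates layout.
#' @export
overlap_table <- function(germline, somatic, genes = NULL) {
  if (is.null(genes)) {
    genes <- sort(unique(toupper(c(germline$gene, somatic$gene))))
  }
  do.call(rbind, lapply(genes, function(g) compute_overlap(germline, somatic, g)))
}
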