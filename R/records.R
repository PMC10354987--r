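# Core domain records: sequences, features, annotation sets.
# All internal coordinates are 0-based half-open; conversion to the 1-based
# inclusive convention happens only at the GenBank/GFF3 format boundary.

#' Create a sequence record
#'
#' A `seq_record` holds one identified nucleotide sequence (a read, a
#' contig, or the reference mitogenome). Bases are normalized to uppercase
#' DNA over `{A,C,G,T,N}`; `U` is mapped to `T`.
#'
#' @param id Record identifier (non-empty, no whitespace).
#' @param bases Nucleotide string.
#' @param description Optional free-text description.
#' @return An object of class `seq_record` with elements `id`,
#'   `description`, `bases`.
#' @export
seq_record <- function(id, bases, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id))
    stop("seq_record id must be a non-empty token without whitespace")
  bases <- normalize_bases(bases)
  if (nchar(bases) < 1L) stop("seq_record bases must be non-empty")
  structure(list(id = id, description = description, bases = bases),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d bp)%s\n", x$id, nchar(x$bases),
              if (nzchar(x$description)) paste0(" ", x$description) else ""))
  invisible(x)
}

#' Normalize a nucleotide string
#'
#' Uppercases, maps U to T, and validates the `{A,C,G,T,N}` alphabet.
#'
#' @param bases Nucleotide string.
#' @return Normalized string.
#' @export
normalize_bases <- function(bases) {
  if (!is.character(bases) || length(bases) != 1L)
    stop("bases must be a single character string")
  b <- chartr("u", "T", toupper(bases))
  b <- chartr("U", "T", b)
  if (grepl("[^ACGTN]", b)) {
    bad <- regmatches(b, regexpr("[^ACGTN]", b))
    stop(sprintf("invalid character '%s' in sequence", bad))
  }
  b
}

#' Reverse complement
#'
#' @param bases Nucleotide string over `{A,C,G,T,N}`.
#' @return The reverse complement string.
#' @export
revcomp <- function(bases) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(bases)))
}

#' Create a feature record
#'
#' A located, stranded gene feature. Coordinates are 0-based half-open on
#' the sequence `seq_id`. A feature whose location runs across the origin
#' of a circular sequence has `end > sequence length` and the qualifier
#' `origin_spanning = TRUE`.
#'
#' @param seq_id Identifier of the annotated sequence.
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`, `"gene"`.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param strand `"+"` or `"-"`.
#' @param name Gene symbol (normalized, e.g. `"COX1"`, `"trnF"`).
#' @param qualifiers Named list of extra qualifiers.
#' @return An object of class `feature_record`.
#' @export
feature_record <- function(seq_id, kind, start, end, strand, name,
                           qualifiers = list()) {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA", "gene", "other"))
  if (!is.numeric(start) || !is.numeric(end) || start < 0 || start >= end)
    stop("feature coordinates must satisfy 0 <= start < end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(seq_id = seq_id, kind = kind,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, name = name, qualifiers = qualifiers),
            class = "feature_record")
}

feature_is_origin_spanning <- function(f) isTRUE(f$qualifiers$origin_spanning)

#' Create an annotation set
#'
#' An ordered collection of features annotating one sequence, plus the
#' NCBI genetic-code table id used to interpret its CDS features.
#' Features are sorted by start, then end.
#'
#' @param seq_id Identifier of the annotated sequence.
#' @param features List of [feature_record()] objects.
#' @param genetic_code_id NCBI translation-table id (e.g. 2, 4, 5).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(seq_id, features = list(), genetic_code_id = 1L) {
  if (length(features)) {
    bad <- vapply(features, function(f) !identical(f$seq_id, seq_id), logical(1))
    if (any(bad)) stop("all features must reference seq_id '", seq_id, "'")
    o <- order(vapply(features, `[[`, integer(1), "start"),
               vapply(features, `[[`, integer(1), "end"))
    features <- features[o]
  }
  structure(list(seq_id = seq_id, features = features,
                 genetic_code_id = as.integer(genetic_code_id)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  kinds <- vapply(x$features, `[[`, character(1), "kind")
  cat(sprintf("<annotation_set> %s: %d features (%s), code table %d\n",
              x$seq_id, length(x$features),
              paste(sprintf("%d %s", table(kinds), names(table(kinds))),
                    collapse = ", "),
              x$genetic_code_id))
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$features)

feature_df <- function(ann) {
  if (!length(ann$features))
    return(data.frame(seq_id = character(), kind = character(),
                      start = integer(), end = integer(),
                      strand = character(), name = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    seq_id = vapply(ann$features, `[[`, character(1), "seq_id"),
    kind = vapply(ann$features, `[[`, character(1), "kind"),
    start = vapply(ann$features, `[[`, integer(1), "start"),
    end = vapply(ann$features, `[[`, integer(1), "end"),
    strand = vapply(ann$features, `[[`, character(1), "strand"),
    name = vapply(ann$features, `[[`, character(1), "name"),
    stringsAsFactors = FALSE)
}

#' Normalize a mitochondrial gene name
#'
#' Maps common synonyms onto a single namespace so gene sets can be
#' compared across annotations (`COI`/`CO1`/`COX1` -> `COX1`;
#' `tRNA-Phe`/`trnF-uuc` -> `trnF`; `16S`/`l-rRNA` -> `rrnL`; ...).
#'
#' @param name Raw gene or product name.
#' @return Normalized name; unrecognized names are returned with
#'   surrounding whitespace stripped.
#' @export
normalize_gene_name <- function(name) {
  vapply(name, function(nm) {
    x <- trimws(nm)
    u <- toupper(x)
    u <- gsub("[ _]", "-", u)
    syn <- c(
      "COI" = "COX1", "CO1" = "COX1", "COXI" = "COX1", "COX1" = "COX1",
      "COII" = "COX2", "CO2" = "COX2", "COXII" = "COX2", "COX2" = "COX2",
      "COIII" = "COX3", "CO3" = "COX3", "COXIII" = "COX3", "COX3" = "COX3",
      "CYTB" = "CYTB", "COB" = "CYTB", "CYB" = "CYTB",
      "NAD1" = "ND1", "NAD2" = "ND2", "NAD3" = "ND3", "NAD4" = "ND4",
      "NAD4L" = "ND4L", "NAD5" = "ND5", "NAD6" = "ND6",
      "ATPASE6" = "ATP6", "ATPASE8" = "ATP8",
      "12S" = "rrnS", "12S-RRNA" = "rrnS", "S-RRNA" = "rrnS",
      "RRNS" = "rrnS", "SMALL-SUBUNIT-RIBOSOMAL-RNA" = "rrnS",
      "16S" = "rrnL", "16S-RRNA" = "rrnL", "L-RRNA" = "rrnL",
      "RRNL" = "rrnL", "LARGE-SUBUNIT-RIBOSOMAL-RNA" = "rrnL")
    if (u %in% names(syn)) return(unname(syn[u]))
    if (u %in% c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
                 "ATP6", "ATP8")) return(u)
    # tRNAs: trnF, trnF-gaa, tRNA-Phe, TRNF ...
    aa3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
    m <- regmatches(x, regexec("^tRNA[-_ ]?([A-Za-z]{3})[0-9]?$", x,
                               ignore.case = TRUE))[[1]]
    if (length(m) == 2) {
      key <- paste0(toupper(substr(m[2], 1, 1)), tolower(substr(m[2], 2, 3)))
      suffix <- sub("^tRNA[-_ ]?[A-Za-z]{3}", "", x, ignore.case = TRUE)
      if (key %in% names(aa3)) return(paste0("trn", aa3[[key]], suffix))
    }
    m <- regmatches(x, regexec("^trn([A-Za-z][0-9]?)([-(].*)?$", x,
                               ignore.case = TRUE))[[1]]
    if (length(m) >= 2) {
      core <- m[2]
      return(paste0("trn", toupper(substr(core, 1, 1)),
                    substr(core, 2, nchar(core))))
    }
    x
  }, character(1), USE.NAMES = FALSE)
}
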