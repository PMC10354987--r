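# Format I/O: FASTA/FASTQ (via Biostrings), GenBank flat file, GFF3, TSV.
# Internal coordinates are 0-based half-open; GenBank and GFF3 emit the
# 1-based inclusive convention.

#' Read sequences from FASTA or FASTQ
#'
#' The format is auto-detected from the first non-blank character (`>` for
#' FASTA, `@` for FASTQ). FASTQ qualities are discarded: no downstream
#' step uses base quality. Bases are normalized (uppercase, `U` to `T`).
#'
#' @param path Path to a FASTA or FASTQ file.
#' @return A list of [seq_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- ""
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) break
    if (nzchar(trimws(ln))) { first <- substr(trimws(ln), 1L, 1L); break }
  }
  if (first == "")
    stop("no sequences: ", path, " is empty")
  if (!first %in% c(">", "@"))
    stop("parse error at line 1 of ", path,
         ": expected '>' (FASTA) or '@' (FASTQ)")
  fmt <- if (first == ">") "fasta" else "fastq"
  set <- Biostrings::readBStringSet(path, format = fmt)
  if (length(set) == 0L) stop("no sequences in ", path)
  nms <- names(set)
  lapply(seq_along(set), function(i) {
    nm <- nms[i]
    id <- sub("\\s.*$", "", nm)
    desc <- if (grepl("\\s", nm)) sub("^\\S+\\s+", "", nm) else ""
    seq_record(id, as.character(set[[i]]), desc)
  })
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param records A list of [seq_record()] objects (a single record is
#'   also accepted).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1), "bases"))
  names(set) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

# ---- GenBank flat file ----------------------------------------------------

parse_gb_location <- function(loc, seq_len) {
  strand <- "+"
  x <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\(", "", x); x <- sub("\\)$", "", x)
  }
  joined <- FALSE
  if (grepl("^join\\(", x)) {
    joined <- TRUE
    x <- sub("^join\\(", "", x); x <- sub("\\)$", "", x)
  }
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  iv <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", p))[[1]]
    if (length(m) != 3) {
      m1 <- regmatches(p, regexec("^(\\d+)$", p))[[1]]
      if (length(m1) == 2) return(c(as.integer(m1[2]), as.integer(m1[2])))
      stop("cannot parse GenBank location: ", loc)
    }
    c(as.integer(m[2]), as.integer(m[3]))
  })
  origin_spanning <- FALSE
  if (joined && length(iv) == 2L && iv[[1]][2] == seq_len && iv[[2]][1] == 1L) {
    # join over the origin of a circular sequence
    start <- iv[[1]][1] - 1L
    end <- seq_len + iv[[2]][2]
    origin_spanning <- TRUE
  } else if (length(iv) == 1L) {
    start <- iv[[1]][1] - 1L
    end <- iv[[1]][2]
  } else {
    start <- min(vapply(iv, `[`, integer(1), 1)) - 1L
    end <- max(vapply(iv, `[`, integer(1), 2))
  }
  if (!origin_spanning && end > seq_len)
    stop("feature location ", loc, " extends beyond sequence length ",
         seq_len, " and is not an origin-spanning join")
  list(start = start, end = end, strand = strand,
       origin_spanning = origin_spanning)
}

format_gb_location <- function(f, seq_len) {
  if (feature_is_origin_spanning(f)) {
    loc <- sprintf("join(%d..%d,%d..%d)", f$start + 1L, seq_len,
                   1L, f$end - seq_len)
  } else {
    loc <- sprintf("%d..%d", f$start + 1L, f$end)
  }
  if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Read a GenBank flat file
#'
#' Parses the ORIGIN sequence and the CDS/tRNA/rRNA features of a GenBank
#' record. Coordinates are converted to the internal 0-based half-open
#' convention; `complement(...)` yields strand `-`; a `join(a..L,1..b)`
#' across the origin of a circular record becomes a single feature with
#' the `origin_spanning` qualifier and `end > L`. The gene name is taken
#' from `/gene`, falling back to `/product`, and normalized with
#' [normalize_gene_name()].
#'
#' @param path Path to a GenBank flat file.
#' @return A list with `record` (a [seq_record()]) and `annotation`
#'   (an [annotation_set()]).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("not a GenBank flat file (no LOCUS line): ", path)
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  seq_id <- locus[2]
  seq_len <- suppressWarnings(as.integer(locus[3]))
  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i)) stop("GenBank file has no ORIGIN section: ", path)
  end_i <- grep("^//", lines)
  end_i <- end_i[end_i > origin_i[1]][1]
  if (is.na(end_i)) end_i <- length(lines) + 1L
  seq_lines <- lines[(origin_i[1] + 1L):(end_i - 1L)]
  bases <- gsub("[0-9 /]", "", paste(seq_lines, collapse = ""))
  bases <- normalize_bases(bases)
  if (!is.na(seq_len) && nchar(bases) != seq_len)
    seq_len <- nchar(bases)
  if (is.na(seq_len)) seq_len <- nchar(bases)

  # definition
  def_i <- grep("^DEFINITION", lines)
  desc <- if (length(def_i)) trimws(sub("^DEFINITION", "", lines[def_i[1]])) else ""

  features <- list()
  code_id <- NA_integer_
  feat_i <- grep("^FEATURES", lines)
  if (length(feat_i)) {
    i <- feat_i[1] + 1L
    cur <- NULL
    flush <- function(cur) {
      if (is.null(cur)) return(NULL)
      if (!cur$key %in% c("CDS", "tRNA", "rRNA", "gene")) return(NULL)
      loc <- parse_gb_location(cur$loc, seq_len)
      quals <- cur$quals
      name <- quals$gene %||% quals$product %||% cur$key
      q <- list()
      if (!is.null(quals$gene)) q$gene <- quals$gene
      if (!is.null(quals$product)) q$product <- quals$product
      if (!is.null(quals$transl_table)) q$transl_table <- quals$transl_table
      if (loc$origin_spanning) q$origin_spanning <- TRUE
      feature_record(seq_id, cur$key, loc$start, loc$end, loc$strand,
                     normalize_gene_name(name), q)
    }
    while (i <= length(lines) && !grepl("^\\S", lines[i])) {
      ln <- lines[i]
      if (grepl("^ {5}\\S", ln)) {
        f <- flush(cur)
        if (!is.null(f)) features[[length(features) + 1L]] <- f
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        cur <- list(key = parts[1], loc = paste(parts[-1], collapse = ""),
                    quals = list())
      } else if (!is.null(cur)) {
        t <- trimws(ln)
        if (startsWith(t, "/")) {
          m <- regmatches(t, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', t))[[1]]
          if (length(m) == 3) cur$quals[[m[2]]] <- m[3]
        } else {
          cur$loc <- paste0(cur$loc, t) # continued location
        }
      }
      i <- i + 1L
    }
    f <- flush(cur)
    if (!is.null(f)) features[[length(features) + 1L]] <- f
    for (f in features) {
      tt <- f$qualifiers$transl_table
      if (!is.null(tt) && is.na(code_id)) code_id <- as.integer(tt)
    }
  }
  if (is.na(code_id)) code_id <- 1L
  list(record = seq_record(seq_id, bases, desc),
       annotation = annotation_set(seq_id, features, code_id))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a GenBank flat file
#'
#' Emits a parseable GenBank record: features in coordinate order with
#' 1-based inclusive locations (origin-spanning features become
#' `join(a..L,1..b)`), then the ORIGIN sequence in the standard 60-base
#' rows of ten-base groups.
#'
#' @param record A [seq_record()].
#' @param annotation An [annotation_set()] for the same `seq_id`.
#' @param path Output path.
#' @param circular Mark the molecule as circular in the LOCUS line.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, annotation, path, circular = TRUE) {
  if (!identical(record$id, annotation$seq_id))
    stop("annotation seq_id '", annotation$seq_id,
         "' does not match record id '", record$id, "'")
  n <- nchar(record$bases)
  out <- c(
    sprintf("LOCUS       %-17s %d bp    DNA     %s   UNA",
            record$id, n, if (circular) "circular" else "linear  "),
    if (nzchar(record$description))
      sprintf("DEFINITION  %s", record$description),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n))
  for (f in annotation$features) {
    out <- c(out, sprintf("     %-16s%s", f$kind, format_gb_location(f, n)))
    gene <- f$qualifiers$gene %||% f$name
    out <- c(out, sprintf('                     /gene="%s"', gene))
    if (!is.null(f$qualifiers$product))
      out <- c(out, sprintf('                     /product="%s"',
                            f$qualifiers$product))
    if (f$kind == "CDS")
      out <- c(out, sprintf("                     /transl_table=%d",
                            f$qualifiers$transl_table %||%
                              annotation$genetic_code_id))
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(record$bases, p, min(n, p + 59L))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(nchar(chunk), seq(10L, nchar(chunk) + 9L, 10L)))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Write an annotation as GFF3
#'
#' Emits a `##gff-version 3` file with 1-based inclusive coordinates.
#' Origin-spanning features are written as two part-lines sharing an ID.
#'
#' @param annotation An [annotation_set()].
#' @param path Output path.
#' @param seq_len Sequence length, required to split origin-spanning
#'   features; defaults to the largest feature end.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path, seq_len = NULL) {
  lines <- "##gff-version 3"
  feats <- annotation$features
  if (length(feats) && is.null(seq_len))
    seq_len <- max(vapply(feats, `[[`, integer(1), "end"))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    attrs <- sprintf("ID=%s_%d;Name=%s", f$kind, i, f$name)
    if (feature_is_origin_spanning(f)) {
      lines <- c(lines,
        paste(annotation$seq_id, "hifimito", f$kind, f$start + 1L, seq_len,
              ".", f$strand, ".", attrs, sep = "\t"),
        paste(annotation$seq_id, "hifimito", f$kind, 1L, f$end - seq_len,
              ".", f$strand, ".", attrs, sep = "\t"))
    } else {
      lines <- c(lines,
        paste(annotation$seq_id, "hifimito", f$kind, f$start + 1L, f$end,
              ".", f$strand, ".", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- TSV reports ----------------------------------------------------------

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(comment, con, sep = "\n")
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      vapply(col, function(v) format(v, scientific = FALSE, digits = 6),
             character(1))
    } else as.character(col)
  })
  body <- if (nrow(df)) do.call(paste, c(cols, sep = "\t")) else character()
  lines <- c(paste(colnames(df), collapse = "\t"), body)
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write the per-contig statistics table
#'
#' One row per candidate contig: assembly size, gene counts, frameshift
#' presence, circularisation data, and final-selection status.
#'
#' @param rows A data.frame with one row per contig.
#' @param path Output path.
#' @param reference_id Optional reference identifier recorded as a
#'   comment line above the header.
#' @return `path`, invisibly.
#' @export
write_stats_table <- function(rows, path, reference_id = NULL) {
  comment <- if (!is.null(reference_id))
    sprintf("# reference: %s", reference_id)
  write_tsv(rows, path, comment = comment)
}

#' Write the shared-genes table
#'
#' Marks each reference gene as present or absent in each candidate
#' contig's annotation: rows are reference genes, one column per contig.
#'
#' @param reference_annotation The reference [annotation_set()].
#' @param contig_annotations Named list of per-contig annotation sets.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shared_genes <- function(reference_annotation, contig_annotations, path) {
  ref <- feature_df(reference_annotation)
  ref <- ref[ref$kind %in% c("CDS", "rRNA", "tRNA"), , drop = FALSE]
  genes <- unique(ref$name)
  df <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (cid in names(contig_annotations)) {
    have <- unique(feature_df(contig_annotations[[cid]])$name)
    df[[cid]] <- ifelse(genes %in% have, "present", "absent")
  }
  write_tsv(df, path)
}
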