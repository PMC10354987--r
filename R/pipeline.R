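# Pipeline orchestration: the end-to-end workflow from reads (or
# pre-assembled contigs) plus a related reference mitogenome to the
# final circularized, rotated, annotated mitogenome, with all report
# files and a run manifest.

pipeline_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hifimito_error")))
}

#' Run the pipeline from HiFi-class reads
#'
#' Recruits reads against the reference, excludes NUMT-length reads,
#' assembles candidate contigs, filters them against the reference,
#' circularizes, annotates, rotates to the tRNA-Phe start, selects the
#' final mitogenome and (optionally) writes all output files.
#'
#' @param reads List of [seq_record()] reads, or a FASTA/FASTQ path.
#' @param reference_record Reference mitogenome [seq_record()], or a
#'   FASTA path.
#' @param reference_annotation Reference [annotation_set()], or a
#'   GenBank path (also supplying the record when `reference_record` is
#'   `NULL`).
#' @param config A [pipeline_config()].
#' @param outdir Output directory; `NULL` skips file output.
#' @return An object of class `hifimito_run`; see [run_from_contigs()].
#' @export
run_from_reads <- function(reads, reference_record = NULL,
                           reference_annotation, config = pipeline_config(),
                           outdir = NULL) {
  if (is.character(reads)) reads <- read_fasta(reads)
  ref <- load_reference(reference_record, reference_annotation)
  config <- resolve_config(config, nchar(ref$record$bases))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  mappings <- map_reads(reads, ref$record, config)
  rec <- recruit_reads(reads, mappings, config)
  timings["recruit"] <- tic() - t0
  if (!length(rec$reads))
    pipeline_error("no reads were recruited against the reference",
                   "hifimito_no_recruited_reads")
  t0 <- tic()
  contigs <- assemble(rec$reads, config)
  timings["assemble"] <- tic() - t0
  finish_run(contigs, ref, config, outdir,
             reads = rec$reads, recruitment = rec$report,
             mappings = mappings, timings = timings)
}

#' Run the pipeline from pre-assembled contigs
#'
#' The contig entry point: skips recruitment and assembly, then applies
#' the same filtering, circularization, annotation, rotation and
#' selection stages as [run_from_reads()].
#'
#' @param contigs List of [seq_record()]s or [draft_contig()]s, or a
#'   FASTA path.
#' @param reference_record,reference_annotation,config,outdir As in
#'   [run_from_reads()].
#' @return An object of class `hifimito_run`: a list with `final`
#'   (`contig`, `annotation`, `circular`), `candidates` (per-contig
#'   `contig`, `annotation`, `circularity`, `missing_genes`),
#'   `selection` (ranked table from [rank_and_select()]), `filter`
#'   (verdicts from [filter_contigs()]), `gene_summary`
#'   ([count_genes()]), `rotation_anchor`, `recruitment`, `coverage`,
#'   `warnings`, `timings`, `config`, `outputs` (written paths).
#' @export
run_from_contigs <- function(contigs, reference_record = NULL,
                             reference_annotation,
                             config = pipeline_config(), outdir = NULL) {
  if (is.character(contigs)) contigs <- read_fasta(contigs)
  if (length(contigs) && inherits(contigs[[1]], "seq_record"))
    contigs <- accept_contigs(contigs)
  ref <- load_reference(reference_record, reference_annotation)
  config <- resolve_config(config, nchar(ref$record$bases))
  finish_run(contigs, ref, config, outdir, reads = NULL,
             recruitment = NULL, mappings = NULL, timings = c())
}

# Accept paths or objects for the reference pair.
load_reference <- function(reference_record, reference_annotation) {
  if (is.character(reference_annotation)) {
    gb <- read_genbank(reference_annotation)
    rec <- if (is.null(reference_record)) gb$record else {
      if (is.character(reference_record)) read_fasta(reference_record)[[1]]
      else reference_record
    }
    return(list(record = rec, annotation = gb$annotation))
  }
  if (is.null(reference_record))
    stop("a reference record (FASTA) is required when the annotation is ",
         "given as an object")
  if (is.character(reference_record))
    reference_record <- read_fasta(reference_record)[[1]]
  list(record = reference_record, annotation = reference_annotation)
}

# Shared back half of both entry points: filter, circularize, annotate,
# rotate, select, report.
finish_run <- function(contigs, ref, config, outdir, reads, recruitment,
                       mappings, timings) {
  warnings <- character()
  catch_warn <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  tic <- function() proc.time()[["elapsed"]]

  if (!length(contigs))
    pipeline_error("assembly produced no contigs", "hifimito_no_contigs")

  t0 <- tic()
  matches <- lapply(contigs, match_contig_to_reference, ref$record, config)
  flt <- filter_contigs(matches, config)
  timings["filter"] <- tic() - t0
  if (!length(flt$retained))
    pipeline_error("no contig passed the reference-comparison filters",
                   "hifimito_no_contigs")
  kept <- contigs[flt$retained]

  t0 <- tic()
  candidates <- list()
  for (cid in names(kept)) {
    ct <- kept[[cid]]
    circ <- detect_terminal_redundancy(ct, config)
    if (circ$is_circular) {
      tr <- trim_redundancy(ct, circ, config)
      ct <- tr$contig
      circ <- tr$result
    }
    candidates[[cid]] <- list(contig = ct, circularity = circ)
  }
  timings["circularize"] <- tic() - t0

  t0 <- tic()
  for (cid in names(candidates)) {
    cand <- candidates[[cid]]
    ann <- catch_warn(transfer_features(
      ref$record, ref$annotation, cand$contig, config,
      circular = cand$circularity$is_circular))
    candidates[[cid]]$annotation <- ann$annotation
    candidates[[cid]]$missing_genes <- ann$missing
  }
  timings["annotate"] <- tic() - t0

  t0 <- tic()
  annotations <- lapply(candidates, `[[`, "annotation")
  anchor <- catch_warn(choose_rotation_anchor(annotations))
  if (!is.na(anchor)) for (cid in names(candidates)) {
    cand <- candidates[[cid]]
    if (!cand$circularity$is_circular) next
    rot <- catch_warn(rotate_contig(cand$contig, cand$annotation, anchor))
    candidates[[cid]]$contig <- rot$contig
    candidates[[cid]]$annotation <- rot$annotation
  }
  timings["rotate"] <- tic() - t0

  gene_summary <- count_genes(lapply(candidates, `[[`, "annotation"),
                              ref$annotation)
  reports <- do.call(rbind, lapply(names(candidates), function(cid) {
    cand <- candidates[[cid]]
    df <- feature_df(cand$annotation)
    fs <- vapply(cand$annotation$features, function(f)
      identical(f$kind, "CDS") && isTRUE(f$qualifiers$frameshift), logical(1))
    data.frame(contig_id = cid, length_bp = nchar(cand$contig$bases),
               gene_count = unname(gene_summary$counts[cid]),
               frameshift_count = sum(fs),
               is_circular = cand$circularity$is_circular,
               stringsAsFactors = FALSE)
  }))
  sel <- catch_warn(rank_and_select(reports, nchar(ref$record$bases)))
  final <- candidates[[sel$final_id]]

  coverage <- NULL
  if (!is.null(reads)) {
    t0 <- tic()
    coverage <- compute_coverage(reads, lapply(candidates, `[[`, "contig"),
                                 config)
    timings["coverage"] <- tic() - t0
  }

  run <- structure(list(
    final = list(contig = final$contig, annotation = final$annotation,
                 circular = final$circularity$is_circular),
    candidates = candidates,
    selection = sel$ranked,
    filter = flt$verdicts,
    gene_summary = gene_summary,
    rotation_anchor = anchor,
    reference = ref,
    recruitment = recruitment,
    mappings = mappings,
    reads = reads,
    coverage = coverage,
    warnings = unique(c(warnings, sel$warnings)),
    timings = timings,
    config = config,
    outputs = character()), class = "hifimito_run")
  if (!is.null(outdir)) run <- emit_outputs(run, outdir)
  run
}

#' @export
print.hifimito_run <- function(x, ...) {
  cat(sprintf("<hifimito_run> final: %s (%d bp, %s, %d genes)\n",
              x$final$contig$id, nchar(x$final$contig$bases),
              if (x$final$circular) "circular" else "linear",
              sum(feature_df(x$final$annotation)$kind %in%
                    c("CDS", "rRNA", "tRNA"))))
  cat(sprintf("  %d candidate contig(s); anchor: %s\n",
              length(x$candidates),
              if (is.na(x$rotation_anchor)) "<none>" else x$rotation_anchor))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Write all pipeline output files
#'
#' Emits the final mitogenome (FASTA, GenBank, GFF3), every candidate's
#' sequence and annotation, the per-contig statistics table, the
#' shared-genes table, the contig-filter reports, the circularization
#' report, the recruited reads and the coverage tables (the latter two
#' only for runs started from reads), plus a run manifest with the
#' configuration, stage timings and MD5 digests of every written file.
#'
#' @param run A `hifimito_run`.
#' @param outdir Output directory (created if missing).
#' @return The run, with `outputs` set to the written paths, invisibly.
#' @export
emit_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- function(name) {
    path <- file.path(outdir, name)
    paths <<- c(paths, path)
    path
  }
  final <- run$final
  write_fasta(seq_record(final$contig$id, final$contig$bases),
              p("final_mitogenome.fasta"))
  write_genbank(seq_record(final$contig$id, final$contig$bases),
                final$annotation, p("final_mitogenome.gb"),
                circular = final$circular)
  write_gff3(final$annotation, p("final_mitogenome.gff"),
             seq_len = nchar(final$contig$bases))
  for (cid in names(run$candidates)) {
    cand <- run$candidates[[cid]]
    write_fasta(seq_record(cid, cand$contig$bases),
                p(sprintf("%s.fasta", cid)))
    write_genbank(seq_record(cid, cand$contig$bases), cand$annotation,
                  p(sprintf("%s.gb", cid)),
                  circular = cand$circularity$is_circular)
    write_gff3(cand$annotation, p(sprintf("%s.gff", cid)),
               seq_len = nchar(cand$contig$bases))
  }

  stats <- merge(run$selection,
                 run$filter[, c("contig_id", "covered_fraction")],
                 by = "contig_id", all.x = TRUE)
  stats <- stats[order(stats$selection_rank), , drop = FALSE]
  write_stats_table(stats, p("contigs_stats.tsv"),
                    reference_id = run$reference$record$id)
  write_shared_genes(run$reference$annotation,
                     lapply(run$candidates, `[[`, "annotation"),
                     p("shared_genes.tsv"))
  write_parsed_blast(run$filter, outdir)
  paths <- c(paths, file.path(outdir, c("parsed_blast.txt",
                                        "parsed_blast_all.txt")))
  circ_results <- lapply(run$candidates, `[[`, "circularity")
  trimmed <- vapply(run$candidates, function(c) nchar(c$contig$bases),
                    integer(1))
  write_circularisation_report(circ_results, trimmed,
                               p("all_contigs.circularisationCheck.txt"))
  if (!is.null(run$reads)) {
    write_fasta(run$reads, p("gbk.HiFiMapped.bam.filtered.fasta"))
    write_mappings(run$mappings, p("reads.HiFiMapped.tsv"))
  }
  if (!is.null(run$coverage)) {
    write_coverage(run$coverage, p("coverage_all_contigs.tsv"))
    fin <- run$coverage[run$coverage$contig_id == final$contig$id, ,
                        drop = FALSE]
    write_coverage(fin, p("final_mitogenome.coverage.tsv"))
  }
  manifest <- p("run_manifest.tsv")
  write_manifest(run, setdiff(paths, manifest), manifest)
  run$outputs <- paths
  invisible(run)
}

# The manifest records the configuration, stage timings, warnings and an
# MD5 digest of every emitted file, so a rerun can be checked for
# byte-identical outputs.
write_manifest <- function(run, paths, path) {
  rows <- list()
  add <- function(section, key, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      section = section, key = key, value = value, stringsAsFactors = FALSE)
  for (nm in names(run$config)) {
    v <- run$config[[nm]]
    add("config", nm, if (is.null(v)) "NULL" else format(v))
  }
  for (nm in names(run$timings))
    add("timing_sec", nm, format(round(run$timings[[nm]], 2),
                                 scientific = FALSE))
  if (!is.null(run$recruitment))
    for (nm in names(run$recruitment))
      add("recruitment", nm, format(run$recruitment[[nm]]))
  add("selection", "final_id", run$final$contig$id)
  add("selection", "rotation_anchor",
      if (is.na(run$rotation_anchor)) "NA" else run$rotation_anchor)
  for (w in run$warnings) add("warning", "message", w)
  md5 <- tools::md5sum(sort(paths))
  for (i in seq_along(md5)) add("md5", basename(names(md5)[i]), unname(md5[i]))
  write_tsv(do.call(rbind, rows), path)
}
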