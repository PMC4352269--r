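#' Build a pipeline run configuration
#'
#' @param annotations path to the source annotation file.
#' @param alignments path to the 12-column alignment table (source exon
#'   sequences vs target genome).
#' @param target_genome path to the target genome FASTA.
#' @param out_dir output directory (created if needed).
#' @param source_genome optional source genome FASTA (used by
#'   [validate_run()] for coordinate bounds checks).
#' @param format annotation format, "genepred" or "gtf".
#' @param min_score strict score filter threshold in `[0, 100]`
#'   (default 80).
#' @param max_splice_shift splice rescue radius in bp (default 10).
#' @param max_hits_per_exon stage width cap (default 500).
#' @param max_evalue E-value admission ceiling (default `Inf`).
#' @param cost a [cost_params()] object.
#' @param chrom_map optional named character vector (or 2-column TSV path)
#'   mapping source chromosome -> fixed target chromosome.
#' @param workers parallel workers for per-transcript processing.
#' @return object of class `run_config`.
#' @export
run_config <- function(annotations, alignments, target_genome, out_dir,
                       source_genome = NULL, format = c("genepred", "gtf"),
                       min_score = 80, max_splice_shift = 10L,
                       max_hits_per_exon = 500L, max_evalue = Inf,
                       cost = cost_params(), chrom_map = NULL, workers = 1L) {
  format <- match.arg(format)
  for (p in c(annotations, alignments, target_genome, source_genome)) {
    if (!file.exists(p)) stop(sprintf("input path does not exist: %s", p))
  }
  if (min_score < 0 || min_score > 100) stop("min_score must be in [0, 100]")
  if (workers < 1) stop("workers must be >= 1")
  if (is.character(chrom_map) && length(chrom_map) == 1 &&
      file.exists(chrom_map)) {
    m <- utils::read.table(chrom_map, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    chrom_map <- stats::setNames(m[[2]], m[[1]])
  }
  structure(list(annotations = annotations, alignments = alignments,
                 target_genome = target_genome, out_dir = out_dir,
                 source_genome = source_genome, format = format,
                 min_score = min_score,
                 max_splice_shift = as.integer(max_splice_shift),
                 max_hits_per_exon = as.integer(max_hits_per_exon),
                 max_evalue = max_evalue, cost = cost,
                 chrom_map = chrom_map, workers = as.integer(workers)),
            class = "run_config")
}

process_transcript <- function(tr, hits, target_genome, config) {
  stages <- build_stages(tr, hits,
                         max_hits_per_exon = config$max_hits_per_exon,
                         max_evalue = config$max_evalue)
  fixed <- if (!is.null(config$chrom_map) && tr$chrom %in% names(config$chrom_map)) {
    config$chrom_map[[tr$chrom]]
  } else NULL
  res <- solve_stages(stages, tr, params = config$cost, fixed_chrom = fixed)
  if (!res$feasible) {
    return(list(annotation = NULL, status = "infeasible",
                transcript_id = tr$transcript_id, score = res$score))
  }
  ann <- assemble_annotation(res, tr)
  ann <- apply_quality_control(target_genome, ann,
                               max_shift = config$max_splice_shift)
  if (ann$score <= config$min_score) {
    return(list(annotation = NULL, status = "low_score",
                transcript_id = tr$transcript_id, score = ann$score))
  }
  list(annotation = ann,
       status = if (ann$canonical_flag == "N") "flagged_N" else "retained",
       transcript_id = tr$transcript_id, score = ann$score)
}

#' Run the annotation-transfer pipeline end to end
#'
#' For every source transcript: build per-exon alignment stages, solve the
#' stage-wise shortest path, assemble the winning combination, apply
#' splice-site quality control and the score filter. Writes the annotation
#' table (`annotations.gp`), the transcript FASTA (`transcripts.fa`), a
#' per-transcript log (`log.tsv`) and a summary (`summary.tsv`) into
#' `out_dir`. Transcripts are independent work units; output is sorted
#' deterministically, so results are identical for any worker count.
#'
#' @param config a [run_config()].
#' @return run summary list (counts of transcripts attempted, feasible,
#'   infeasible, low_score, flagged_N, retained), invisibly.
#' @export
annotate_genome <- function(config) {
  transcripts <- read_source_annotations(config$annotations, config$format)
  target_genome <- read_genome_fasta(config$target_genome)
  hits <- parse_alignment_table(config$alignments)
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  unknown <- setdiff(unique(hits$transcript_id), ids)
  if (length(unknown)) {
    warning(sprintf("%d alignment hit transcript id(s) not in annotations (skipped): %s",
                    length(unknown), paste(utils::head(unknown, 5), collapse = ", ")))
    hits <- hits[hits$transcript_id %in% ids, , drop = FALSE]
  }
  transcripts <- transcripts[order(ids)]
  worker <- function(tr) process_transcript(tr, hits, target_genome, config)
  results <- if (config$workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(transcripts, worker, mc.cores = config$workers)
  } else {
    lapply(transcripts, worker)
  }
  anns <- Filter(Negate(is.null), lapply(results, `[[`, "annotation"))
  statuses <- vapply(results, `[[`, "", "status")
  summary <- list(attempted = length(results),
                  feasible = sum(statuses != "infeasible"),
                  infeasible = sum(statuses == "infeasible"),
                  low_score = sum(statuses == "low_score"),
                  flagged_N = sum(statuses == "flagged_N"),
                  retained = length(anns))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  write_annotation_table(anns, file.path(config$out_dir, "annotations.gp"))
  write_transcript_fasta(target_genome, anns,
                         file.path(config$out_dir, "transcripts.fa"))
  log_df <- data.frame(
    transcript_id = vapply(results, `[[`, "", "transcript_id"),
    status = statuses,
    score = sprintf("%.6f", vapply(results, `[[`, 0, "score")),
    stringsAsFactors = FALSE)
  log_df <- log_df[order(log_df$transcript_id), , drop = FALSE]
  utils::write.table(log_df, file.path(config$out_dir, "log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("%s\t%d", names(summary), unlist(summary)),
             file.path(config$out_dir, "summary.tsv"))
  invisible(summary)
}

#' Dry-run validation of pipeline inputs
#'
#' Checks formats, id cross-references and coordinate bounds without
#' writing any output.
#'
#' @param config a [run_config()].
#' @return data.frame of diagnostics (`code`, `message`); zero rows when
#'   the inputs are mutually consistent.
#' @export
validate_run <- function(config) {
  diags <- list()
  add <- function(code, message) {
    diags[[length(diags) + 1L]] <<- data.frame(code = code, message = message,
                                               stringsAsFactors = FALSE)
  }
  transcripts <- tryCatch(
    read_source_annotations(config$annotations, config$format),
    error = function(e) {
      add("annotation_parse", conditionMessage(e))
      NULL
    })
  hits <- tryCatch(parse_alignment_table(config$alignments),
                   error = function(e) {
                     add("alignment_parse", conditionMessage(e))
                     NULL
                   })
  target_genome <- tryCatch(read_genome_fasta(config$target_genome),
                            error = function(e) {
                              add("target_genome", conditionMessage(e))
                              NULL
                            })
  if (!is.null(transcripts) && !is.null(hits)) {
    ids <- vapply(transcripts, `[[`, "", "transcript_id")
    for (u in setdiff(unique(hits$transcript_id), ids)) {
      add("unknown_transcript",
          sprintf("alignment hits reference unknown transcript '%s'", u))
    }
  }
  if (!is.null(hits) && !is.null(target_genome)) {
    lens <- genome_lengths(target_genome)
    for (ch in setdiff(unique(hits$target_chrom), names(lens))) {
      add("unknown_target_chrom",
          sprintf("alignment hits reference unknown target chromosome '%s'", ch))
    }
    known <- hits$target_chrom %in% names(lens)
    oob <- known & hits$target_end > lens[hits$target_chrom]
    for (r in which(oob)) {
      add("hit_out_of_bounds",
          sprintf("hit %s|%d end %d beyond %s length %d",
                  hits$transcript_id[r], hits$exon_index[r],
                  hits$target_end[r], hits$target_chrom[r],
                  lens[[hits$target_chrom[r]]]))
    }
  }
  if (!is.null(transcripts) && !is.null(config$source_genome)) {
    src <- tryCatch(read_genome_fasta(config$source_genome),
                    error = function(e) {
                      add("source_genome", conditionMessage(e))
                      NULL
                    })
    if (!is.null(src)) {
      lens <- genome_lengths(src)
      for (tr in transcripts) {
        if (!tr$chrom %in% names(lens)) {
          add("unknown_source_chrom",
              sprintf("transcript %s on unknown chromosome '%s'",
                      tr$transcript_id, tr$chrom))
        } else if (max(tr$exons$end) > lens[[tr$chrom]]) {
          add("exon_out_of_bounds",
              sprintf("transcript %s exon end %d beyond %s length %d",
                      tr$transcript_id, max(tr$exons$end), tr$chrom,
                      lens[[tr$chrom]]))
        }
      }
    }
  }
  if (length(diags)) do.call(rbind, diags) else {
    data.frame(code = character(0), message = character(0),
               stringsAsFactors = FALSE)
  }
}
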