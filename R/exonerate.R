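# Reader and writer for Exonerate protein2genome output carrying embedded
# GFF dumps (the `--showtargetgff yes` dialect). Only the GFF-bearing form is
# supported; cigar/vulgar-only files are rejected. The human-readable
# alignment text between GFF blocks is skipped. No installed package parses
# this dialect, so the line parser is implemented here.

GFF_DUMP_START <- "# --- START OF GFF DUMP ---"
GFF_DUMP_END <- "# --- END OF GFF DUMP ---"

#' Parse Exonerate protein2genome output with embedded GFF blocks
#'
#' Reads the alignment dialect produced by Exonerate's protein2genome model
#' with target-GFF emission. Each record's GFF block must contain one `gene`
#' feature (score column populated) and a `similarity` feature whose
#' `Align <target_start> <query_start> <length>` attribute triples supply the
#' per-exon query/target mapping (`target_start` is the 1-based forward
#' coordinate of the segment's first base in transcription order; `length`
#' is in nucleotides). Records are normalized so target intervals have
#' `start <= end` on the forward strand while segment order reflects
#' transcription order.
#'
#' @param x Path to an alignment file, or a character vector of lines.
#' @return An [alignment_hits()] tibble, one row per `gene` feature.
#' @export
read_exonerate <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  in_gff <- FALSE
  gff <- character()
  gff_lineno <- integer()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == GFF_DUMP_START) { in_gff <- TRUE; next }
    if (ln == GFF_DUMP_END) { in_gff <- FALSE; next }
    if (in_gff && nzchar(ln) && !startsWith(ln, "#")) {
      gff <- c(gff, ln)
      gff_lineno <- c(gff_lineno, i)
    }
  }
  if (!length(gff)) {
    if (any(startsWith(lines, "vulgar:")) || any(startsWith(lines, "cigar:"))) {
      abort(paste("input contains only vulgar/cigar records;",
                  "re-run Exonerate with --showtargetgff yes"))
    }
    return(empty_hits())
  }

  fields <- strsplit(gff, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad)) {
    abort(sprintf("malformed GFF line at line %d: expected 9 tab-separated fields",
                  gff_lineno[bad[1L]]))
  }

  rows <- list()
  cur <- NULL
  flush_record <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$segments)) {
      # no similarity feature: fall back to exon rows, query coords unknown
      if (is.null(cur$exons)) {
        warn(sprintf("record for query '%s' has no exon/similarity features; skipped",
                     cur$query))
        return(NULL)
      }
      seg <- bind_rows(cur$exons)
      seg$q_start <- NA_integer_; seg$q_end <- NA_integer_
    } else {
      seg <- bind_rows(cur$segments)
    }
    if (any(seg$t_start < cur$t_start | seg$t_end > cur$t_end)) {
      warn(sprintf("record for query '%s' at %s:%d-%d: exon outside gene span; record rejected",
                   cur$query, cur$target, cur$t_start, cur$t_end))
      return(NULL)
    }
    seg <- seg[if (cur$strand == "+") order(seg$t_start) else
                 order(-seg$t_start), , drop = FALSE]
    nt_before <- cumsum(c(0L, seg$t_end - seg$t_start + 1L))[seq_len(nrow(seg))]
    seg$phase <- as.integer(nt_before %% 3L)
    tibble(
      hit_id = NA_character_, query_id = cur$query, target_id = cur$target,
      strand = cur$strand, score = cur$score,
      q_start = as.integer(suppressWarnings(min(seg$q_start, na.rm = TRUE))),
      q_end = as.integer(suppressWarnings(max(seg$q_end, na.rm = TRUE))),
      t_start = cur$t_start, t_end = cur$t_end,
      segments = list(as_tibble(seg))
    )
  }

  for (j in seq_along(fields)) {
    f <- fields[[j]]
    type <- f[3L]
    if (type == "gene") {
      r <- flush_record(cur)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
      query <- stringr::str_match(f[9L], "sequence\\s+(\\S+)")[, 2L]
      if (is.na(query)) {
        abort(sprintf("malformed GFF line at line %d: gene feature lacks 'sequence' attribute",
                      gff_lineno[j]))
      }
      score <- suppressWarnings(as.numeric(f[6L]))
      if (is.na(score)) {
        abort(sprintf("malformed GFF line at line %d: gene score is not numeric",
                      gff_lineno[j]))
      }
      cur <- list(
        target = f[1L], query = query, score = score,
        t_start = as.integer(f[4L]), t_end = as.integer(f[5L]),
        strand = f[7L], exons = list(), segments = NULL
      )
    } else if (type == "exon") {
      if (is.null(cur)) {
        warn(sprintf("orphan exon feature at line %d; skipped", gff_lineno[j]))
        next
      }
      cur$exons[[length(cur$exons) + 1L]] <-
        tibble(t_start = as.integer(f[4L]), t_end = as.integer(f[5L]))
    } else if (type == "similarity") {
      if (is.null(cur)) {
        warn(sprintf("orphan similarity feature at line %d; skipped", gff_lineno[j]))
        next
      }
      m <- stringr::str_match_all(f[9L], "Align\\s+(\\d+)\\s+(\\d+)\\s+(\\d+)")[[1L]]
      if (nrow(m)) {
        tpos <- as.integer(m[, 2L]); qpos <- as.integer(m[, 3L])
        len <- as.integer(m[, 4L])
        cur$segments <- list(tibble(
          t_start = if (cur$strand == "+") tpos else tpos - len + 1L,
          t_end = if (cur$strand == "+") tpos + len - 1L else tpos,
          q_start = qpos,
          q_end = qpos + nt_to_aa_len(len) - 1L
        ))
      }
    }
    # all other feature types (cds, intron, splice5, splice3, utr) skipped
  }
  r <- flush_record(cur)
  if (!is.null(r)) rows[[length(rows) + 1L]] <- r

  if (!length(rows)) return(empty_hits())
  out <- bind_rows(rows)
  out$hit_id <- sprintf("hit_%05d", seq_len(nrow(out)))
  alignment_hits(out)
}

#' Render an alignment-hit table as Exonerate-with-GFF text
#'
#' The inverse of [read_exonerate()]: used by the synthetic-data generator to
#' emit alignment files in the dialect the parser consumes. Round-tripping
#' through `read_exonerate()` reproduces the table (hit ids are positional).
#'
#' @param hits An [alignment_hits()] tibble.
#' @return Character scalar of file text.
#' @export
format_exonerate <- function(hits) {
  header <- c(
    "Command line: [exonerate --model protein2genome --showtargetgff yes]",
    "Hostname: [synthetic]"
  )
  blocks <- purrr::map_chr(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    seg <- h$segments[[1L]]
    src <- "exonerate:protein2genome:local"
    gene <- sprintf("%s\t%s\tgene\t%d\t%d\t%d\t%s\t.\tgene_id %d ; sequence %s ; gene_orientation %s",
                    h$target_id, src, h$t_start, h$t_end, as.integer(round(h$score)),
                    h$strand, i, h$query_id, h$strand)
    fwd <- seg[order(seg$t_start), , drop = FALSE]
    exons <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tinsertions 0 ; deletions 0",
                     h$target_id, src, fwd$t_start, fwd$t_end, h$strand)
    tpos <- if (h$strand == "+") seg$t_start else seg$t_end
    aligns <- paste(sprintf("Align %d %d %d", tpos, seg$q_start,
                            seg$t_end - seg$t_start + 1L), collapse = " ; ")
    sim <- sprintf("%s\t%s\tsimilarity\t%d\t%d\t%d\t%s\t.\talignment_id %d ; Query %s ; %s",
                   h$target_id, src, h$t_start, h$t_end, as.integer(round(h$score)),
                   h$strand, i, h$query_id, aligns)
    paste(c(
      "", "C4 Alignment:", "------------",
      sprintf("         Query: %s", h$query_id),
      sprintf("        Target: %s", h$target_id),
      sprintf("     Raw score: %d", as.integer(round(h$score))),
      GFF_DUMP_START,
      "##gff-version 2",
      "##source-version exonerate:protein2genome:local 2.4.0",
      gene, exons, sim,
      GFF_DUMP_END
    ), collapse = "\n")
  })
  paste0(paste(c(header, blocks, "", "-- completed exonerate analysis"),
               collapse = "\n"), "\n")
}
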