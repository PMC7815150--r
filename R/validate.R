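# Parsers for external validator outputs (Pfam 7tm_6 domain search, three
# transmembrane-helix predictors, motif scans), the three-way TMH consensus
# vote, novel-locus counting against a user annotation, and the summary
# statistics table. The external tools themselves are never run here; their
# output files are inputs.

input_lines <- function(x) {
  if (!length(x)) return(character())
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) return(readLines(x))
  as.character(unlist(strsplit(x, "\n", fixed = TRUE)))
}

#' Count reported domains per protein from an hmmsearch domain table
#'
#' Reads `--domtblout`-style per-domain rows and counts hits per target
#' protein for one profile (default `7tm_6`, the Pfam domain characteristic
#' of insect ORs). The search tool's own reporting threshold is respected;
#' no additional E-value filter is applied. Two or more domains on one
#' protein indicate a fused model.
#'
#' @param x Path to a domain table or a character vector of lines.
#' @param domain Profile name to count.
#' @return Tibble with columns `name`, `n_domains`.
#' @export
parse_domain_counts <- function(x, domain = "7tm_6") {
  lines <- input_lines(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(tibble(name = character(), n_domains = integer()))
  fields <- strsplit(trimws(lines), "\\s+")
  ok <- lengths(fields) >= 13L
  if (any(!ok)) warn(sprintf("skipped %d malformed domain-table row(s)",
                             sum(!ok)))
  fields <- fields[ok]
  tgt <- purrr::map_chr(fields, 1L)
  qry <- purrr::map_chr(fields, 4L)
  keep <- qry == domain
  tibble(name = tgt[keep]) |>
    dplyr::count(.data$name, name = "n_domains") |>
    arrange(.data$name)
}

#' Parse transmembrane-helix predictor output
#'
#' Supported dialects:
#' * `"tmhmm"` — long-format rows `<id>\\tTMHMM2.0\\tTMhelix\\t<start>\\t<end>`
#'   (inside/outside rows are skipped);
#' * `"hmmtop"` — `>HP: <len> <id> ... <IN|OUT> <n> <pos1> <pos2> ...` with
#'   `2n` boundary positions;
#' * `"phobius"` — long-format blocks `ID <name>` / `FT TRANSMEM <s> <e>` /
#'   `//`.
#'
#' @param x Path or character vector of lines.
#' @param method One of `"tmhmm"`, `"hmmtop"`, `"phobius"`.
#' @return Tibble with columns `name`, `start`, `end` (1-based residue
#'   intervals), one row per predicted helix.
#' @export
parse_tmh <- function(x, method = c("tmhmm", "hmmtop", "phobius")) {
  method <- match.arg(method)
  lines <- input_lines(x)
  empty <- tibble(name = character(), start = integer(), end = integer())
  if (method == "tmhmm") {
    m <- stringr::str_match(lines,
      "^(\\S+)\\s+TMHMM2\\.0\\s+TMhelix\\s+(\\d+)\\s+(\\d+)")
    keep <- !is.na(m[, 1L])
    if (!any(keep)) return(empty)
    return(tibble(name = m[keep, 2L], start = as.integer(m[keep, 3L]),
                  end = as.integer(m[keep, 4L])))
  }
  if (method == "hmmtop") {
    rows <- purrr::map(lines[startsWith(lines, ">HP:")], function(ln) {
      toks <- strsplit(trimws(sub("^>HP:", "", ln)), "\\s+")[[1L]]
      id <- toks[2L]
      topo_at <- which(toks %in% c("IN", "OUT"))[1L]
      if (is.na(topo_at)) return(NULL)
      n <- as.integer(toks[topo_at + 1L])
      if (is.na(n) || n == 0L) return(NULL)
      pos <- as.integer(toks[topo_at + 1L + seq_len(2L * n)])
      tibble(name = id, start = pos[c(TRUE, FALSE)], end = pos[c(FALSE, TRUE)])
    })
    out <- bind_rows(purrr::compact(rows))
    return(if (nrow(out)) out else empty)
  }
  # phobius long format
  cur <- NA_character_
  rows <- list()
  for (ln in lines) {
    if (startsWith(ln, "ID")) {
      cur <- strsplit(trimws(ln), "\\s+")[[1L]][2L]
    } else if (grepl("^FT\\s+TRANSMEM", ln)) {
      if (is.na(cur)) abort("phobius TRANSMEM row before any ID row")
      m <- stringr::str_match(ln, "FT\\s+TRANSMEM\\s+(\\d+)\\s+(\\d+)")
      rows[[length(rows) + 1L]] <- tibble(
        name = cur, start = as.integer(m[2L]), end = as.integer(m[3L]))
    } else if (startsWith(ln, "//")) {
      cur <- NA_character_
    }
  }
  out <- bind_rows(rows)
  if (nrow(out)) out else empty
}

#' Consensus transmembrane helices by three-way majority vote
#'
#' A residue is called membrane when at least two of the three methods place
#' it inside a helix; maximal runs of membrane residues at least
#' `min_helix` long become consensus helices. Requires exactly three
#' per-method helix tables.
#'
#' @param helix_sets List of exactly three tibbles (`start`, `end`) with the
#'   per-method helix intervals of one protein.
#' @param protein_length Protein length in residues.
#' @param min_helix Minimum consensus helix length (residues).
#' @return Tibble (`start`, `end`) of consensus helices.
#' @export
consensus_tmh <- function(helix_sets, protein_length, min_helix = 9L) {
  if (length(helix_sets) != 3L) {
    abort("consensus requires exactly three methods")
  }
  votes <- integer(protein_length)
  for (hs in helix_sets) {
    for (r in seq_len(nrow(hs))) {
      lo <- max(1L, hs$start[r]); hi <- min(protein_length, hs$end[r])
      if (lo <= hi) votes[lo:hi] <- votes[lo:hi] + 1L
    }
  }
  memb <- votes >= 2L
  r <- rle(memb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_helix
  tibble(start = starts[keep], end = ends[keep])
}

#' Parse motif-scan hits
#'
#' Parse-and-report support for MAST-style hit lists: whitespace-separated
#' rows `<sequence> <motif> <start> <end> <score> <p-value>`; `#` comment
#' lines are skipped.
#'
#' @param x Path or character vector of lines.
#' @return Tibble with columns `name`, `motif`, `start`, `end`, `score`,
#'   `p_value`.
#' @export
parse_motif_hits <- function(x) {
  lines <- input_lines(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(tibble(name = character(), motif = character(), start = integer(),
                  end = integer(), score = numeric(), p_value = numeric()))
  }
  f <- strsplit(trimws(lines), "\\s+")
  tibble(
    name = purrr::map_chr(f, 1L), motif = purrr::map_chr(f, 2L),
    start = as.integer(purrr::map_chr(f, 3L)),
    end = as.integer(purrr::map_chr(f, 4L)),
    score = as.numeric(purrr::map_chr(f, 5L)),
    p_value = as.numeric(purrr::map_chr(f, 6L))
  )
}

#' Count predicted loci absent from a user-provided annotation
#'
#' A predicted model is novel iff none of its exonic bases overlap any
#' user-transcript exonic base on the same strand. Also returns the user
#' annotation trimmed to transcripts overlapping predictions.
#'
#' @param models An `or_models` tibble.
#' @param user_transcripts Transcript tibble (see
#'   [read_gff_transcripts()]).
#' @return List with `n_novel`, `novel` (model names), and `trimmed_user`
#'   (user transcripts overlapping any prediction).
#' @export
count_novel_loci <- function(models, user_transcripts) {
  user_ex <- distinct_exons(user_transcripts)
  model_novel <- purrr::map_lgl(seq_len(nrow(models)), function(i) {
    ex <- models$exons[[i]]
    sel <- user_ex$scaffold == models$scaffold[i] &
      user_ex$strand == models$strand[i]
    !any(purrr::map_lgl(seq_len(nrow(ex)), function(r) {
      any(user_ex$start[sel] <= ex$end[r] & user_ex$end[sel] >= ex$start[r])
    }))
  })
  pred_ex <- distinct_exons(models_as_transcripts(models))
  user_keep <- purrr::map_lgl(seq_len(nrow(user_transcripts)), function(j) {
    ex <- user_transcripts$exons[[j]]
    sel <- pred_ex$scaffold == user_transcripts$scaffold[j] &
      pred_ex$strand == user_transcripts$strand[j]
    any(purrr::map_lgl(seq_len(nrow(ex)), function(r) {
      any(pred_ex$start[sel] <= ex$end[r] & pred_ex$end[sel] >= ex$start[r])
    }))
  })
  list(
    n_novel = sum(model_novel),
    novel = models$name[model_novel],
    trimmed_user = user_transcripts[user_keep, , drop = FALSE]
  )
}

#' Assemble the final summary statistics
#'
#' Totals of predicted genes/gene-fragments, complete/partial models, models
#' with/without a START, pseudogenous models, 7tm_6 domain counts, the
#' per-method TMH-count histogram (the data behind the bar plot), and novel
#' loci relative to a user annotation. Internal sums are asserted to
#' reconcile.
#'
#' @param x An `or_annotation` or `or_models` tibble.
#' @param domain_counts Optional tibble from [parse_domain_counts()].
#' @param tmh Optional named list of helix tables from [parse_tmh()], one
#'   per method.
#' @param user_transcripts Optional user annotation for novel-locus
#'   counting.
#' @return An object of class `or_summary`; `tidy()` returns the counts
#'   table, `autoplot()` the TMH histogram.
#' @export
summarize_annotation <- function(x, domain_counts = NULL, tmh = NULL,
                                 user_transcripts = NULL) {
  models <- if (inherits(x, "or_annotation")) x$models else x
  n <- nrow(models)
  n7 <- if (!is.null(domain_counts)) {
    cnt <- setNames(domain_counts$n_domains, domain_counts$name)
    v <- unname(cnt[models$name])
    v[is.na(v)] <- 0L
    as.integer(v)
  } else {
    rep(NA_integer_, n)
  }
  counts <- tibble(
    n_models = n,
    n_complete = sum(models$completeness == "complete"),
    n_partial = sum(models$completeness == "partial"),
    n_with_start = sum(models$has_start),
    n_without_start = sum(!models$has_start),
    n_pseudo = sum(models$pseudo),
    n_normal = sum(!models$pseudo),
    n_7tm6_ge1 = if (all(is.na(n7))) NA_integer_ else sum(n7 >= 1L),
    n_7tm6_multi = if (all(is.na(n7))) NA_integer_ else sum(n7 >= 2L),
    n_novel = NA_integer_
  )
  stopifnot(counts$n_complete + counts$n_partial == counts$n_models,
            counts$n_with_start + counts$n_without_start == counts$n_models,
            counts$n_pseudo + counts$n_normal == counts$n_models)

  novel <- NULL
  if (!is.null(user_transcripts)) {
    novel <- count_novel_loci(models, user_transcripts)
    counts$n_novel <- novel$n_novel
  }

  hist <- NULL
  if (!is.null(tmh)) {
    hist <- purrr::imap(tmh, function(tbl, method) {
      per <- dplyr::count(tbl, .data$name, name = "n_helices")
      absent <- setdiff(models$name, per$name)
      per <- bind_rows(per, tibble(name = absent, n_helices = 0L))
      dplyr::count(per, .data$n_helices, name = "n_proteins") |>
        mutate(method = method, .before = 1L)
    }) |> bind_rows()
  }

  consensus <- NULL
  if (!is.null(tmh) && length(tmh) == 3L &&
      all(nzchar(models$protein))) {
    consensus <- purrr::map(seq_len(n), function(i) {
      sets <- purrr::map(tmh, function(tbl) {
        tbl[tbl$name == models$name[i], c("start", "end"), drop = FALSE]
      })
      consensus_tmh(unname(sets), nchar(models$protein[i]))
    })
    names(consensus) <- models$name
  }

  structure(
    list(counts = counts, tmh_histogram = hist, consensus_tmh = consensus,
         novel = novel, n_7tm6 = setNames(n7, models$name)),
    class = "or_summary"
  )
}

#' @export
print.or_summary <- function(x, ...) {
  cat("<or_summary>\n")
  c0 <- x$counts
  for (nm in names(c0)) cat(sprintf("  %-18s %s\n", nm, format(c0[[nm]])))
  invisible(x)
}

#' @describeIn summarize_annotation Counts table.
#' @param x An `or_summary` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.or_summary <- function(x, ...) x$counts

#' @exportS3Method ggplot2::autoplot
autoplot.or_summary <- function(object, ...) {
  if (is.null(object$tmh_histogram)) {
    abort("no TMH predictions supplied; nothing to plot")
  }
  ggplot2::ggplot(object$tmh_histogram,
                  ggplot2::aes(x = .data$n_helices, y = .data$n_proteins,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "predicted transmembrane helices",
                  y = "proteins", fill = "method")
}
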