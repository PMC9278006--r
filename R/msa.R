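# A3M/FASTA alignments, unpaired/paired complex MSA assembly, depth (Neff).

#' Multiple sequence alignment in query coordinates
#'
#' @param rows character vector of aligned sequences.  The first row is the
#'   query (no gaps relative to itself).  Lowercase characters are A3M
#'   insertion states; the matrix view (`$rows`) has them removed so every
#'   row spans exactly the query columns.  `.` gap characters are
#'   normalized to `-`.
#' @param labels per-row identifiers.
#' @param raw_rows optional original rows with insertions preserved.
#' @return Object of class `msa_alignment`: list with `rows` (matrix view),
#'   `labels`, `raw_rows`, `query_length`.
#' @export
msa_alignment <- function(rows, labels = NULL, raw_rows = rows) {
  if (length(rows) == 0L) stop("empty alignment")
  rows <- gsub(".", "-", rows, fixed = TRUE)
  matrix_view <- gsub("[a-z]", "", rows)
  qlen <- nchar(matrix_view[[1]])
  if (any(nchar(matrix_view) != qlen)) {
    stop("ragged alignment: rows differ in length after removing ",
         "insertion states")
  }
  if (grepl("-", matrix_view[[1]], fixed = TRUE)) {
    stop("query (first row) must not contain gaps")
  }
  if (is.null(labels)) labels <- paste0("seq", seq_along(rows))
  structure(list(rows = matrix_view, labels = labels,
                 raw_rows = gsub(".", "-", raw_rows, fixed = TRUE),
                 query_length = qlen),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("msa_alignment:", length(x$rows), "rows x", x$query_length,
      "query columns\n")
  invisible(x)
}

#' Read an A3M or aligned-FASTA file
#'
#' @param path file path.
#' @return An [msa_alignment()].
#' @export
read_a3m <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[[1]]) stop("not FASTA/A3M: first line is not a header")
  rec <- cumsum(hdr)
  labels <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) paste(trimws(x), collapse = ""), character(1))
  msa_alignment(unname(seqs), labels = labels)
}

#' Write an alignment (matrix view) as A3M/FASTA
#'
#' @param aln an [msa_alignment()] or [combined_msa()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_a3m <- function(aln, path) {
  writeLines(paste0(">", aln$labels, "\n", aln$rows), path, sep = "\n")
  invisible(path)
}

#' Combine two per-chain alignments into an unpaired complex MSA
#'
#' Builds the block-diagonal complex alignment used as unpaired MSA input
#' for complex structure prediction: the query row is the concatenation of
#' the two chain queries; every other row of chain A is padded with
#' `query_length(B)` trailing gaps and every row of chain B with
#' `query_length(A)` leading gaps.  The chain-break residue index shift
#' (default 200, the convention introduced to signal a chain break to a
#' single-chain predictor) is carried as metadata.
#'
#' @param msa_a,msa_b [msa_alignment()] objects for the two chains.
#' @param residue_offset index shift recorded at the chain junction.
#' @return Object of class `combined_msa`: list with `rows`, `labels`,
#'   `origin` (per-row, one of `"query"`, `"chainA"`, `"chainB"`,
#'   `"paired"`), `len_a`, `len_b`, `residue_offset`.
#' @export
combine_unpaired <- function(msa_a, msa_b, residue_offset = 200) {
  la <- msa_a$query_length; lb <- msa_b$query_length
  query <- paste0(msa_a$rows[[1]], msa_b$rows[[1]])
  rows_a <- if (length(msa_a$rows) > 1L)
    paste0(msa_a$rows[-1], strrep("-", lb)) else character(0)
  rows_b <- if (length(msa_b$rows) > 1L)
    paste0(strrep("-", la), msa_b$rows[-1]) else character(0)
  structure(list(rows = c(query, rows_a, rows_b),
                 labels = c("query",
                            msa_a$labels[-1], msa_b$labels[-1]),
                 origin = c("query",
                            rep("chainA", length(rows_a)),
                            rep("chainB", length(rows_b))),
                 len_a = la, len_b = lb,
                 residue_offset = residue_offset),
            class = "combined_msa")
}

#' @export
print.combined_msa <- function(x, ...) {
  cat("combined_msa:", length(x$rows), "rows (",
      sum(x$origin == "chainA"), "A,", sum(x$origin == "chainB"), "B,",
      sum(x$origin == "paired"), "paired ) x", x$len_a + x$len_b,
      "columns; offset", x$residue_offset, "\n")
  invisible(x)
}

#' Append paired rows to a combined MSA
#'
#' Paired rows carry putative orthologs of both chains concatenated in one
#' sequence, providing a cross-interface coevolution signal.  A paired-only
#' alignment can be built by starting from a query-only [combine_unpaired()]
#' result.
#'
#' @param combined a [combined_msa()].
#' @param pairs data.frame (or list) with columns/elements `seq_a`, `seq_b`
#'   (aligned to the chain A / chain B query columns) and optionally
#'   `label`.
#' @return The extended [combined_msa()].
#' @export
add_paired_rows <- function(combined, pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(combined)
  seq_a <- gsub(".", "-", pairs$seq_a, fixed = TRUE)
  seq_b <- gsub(".", "-", pairs$seq_b, fixed = TRUE)
  if (any(nchar(gsub("[a-z]", "", seq_a)) != combined$len_a) ||
      any(nchar(gsub("[a-z]", "", seq_b)) != combined$len_b)) {
    stop("paired segment length does not match its chain's query length")
  }
  labels <- if ("label" %in% names(pairs)) pairs$label else
    paste0("paired", seq_len(nrow(pairs)))
  combined$rows <- c(combined$rows,
                     paste0(gsub("[a-z]", "", seq_a),
                            gsub("[a-z]", "", seq_b)))
  combined$labels <- c(combined$labels, labels)
  combined$origin <- c(combined$origin, rep("paired", nrow(pairs)))
  combined
}

row_coverage <- function(rows) {
  1 - vapply(strsplit(rows, ""), function(ch) mean(ch == "-"), numeric(1))
}

row_identity_to_query <- function(rows) {
  q <- strsplit(rows[[1]], "")[[1]]
  vapply(strsplit(rows, ""), function(ch) {
    both <- ch != "-" & q != "-"
    if (!any(both)) return(0)
    sum(ch[both] == q[both]) / sum(both)
  }, numeric(1))
}

#' Pre-pairing row filter
#'
#' Keeps rows whose coverage of the query columns and identity to the query
#' meet the thresholds applied before MSA pairing (defaults: coverage >=
#' 50%, identity >= 20%).  The query row is always kept.
#'
#' @param aln an [msa_alignment()].
#' @param min_coverage,min_identity thresholds in percent, `[0, 100]`.
#' @return The filtered [msa_alignment()].
#' @export
prefilter <- function(aln, min_coverage = 50, min_identity = 20) {
  stopifnot(min_coverage >= 0, min_coverage <= 100,
            min_identity >= 0, min_identity <= 100)
  cov <- row_coverage(aln$rows)
  idn <- row_identity_to_query(aln$rows)
  keep <- (cov >= min_coverage / 100 - 1e-12) &
    (idn >= min_identity / 100 - 1e-12)
  keep[[1]] <- TRUE
  msa_alignment(aln$rows[keep], labels = aln$labels[keep],
                raw_rows = aln$raw_rows[keep])
}

# pairwise identity between two aligned rows: matching non-gap columns
# divided by the shorter ungapped length (the cited clustering tool's
# convention)
pair_identity <- function(a, b) {
  same <- a != "-" & b != "-" & a == b
  denom <- min(sum(a != "-"), sum(b != "-"))
  if (denom == 0L) return(0)
  sum(same) / denom
}

#' Alignment depth (Neff) by greedy identity clustering
#'
#' The number of effective sequences is defined as the number of clusters
#' after greedy incremental clustering at a fixed identity threshold
#' (default 62%): rows are sorted by ungapped length (longest first), each
#' row joins the first existing cluster whose representative shares at
#' least the threshold identity (matches divided by the shorter ungapped
#' length), otherwise it founds a new cluster.
#'
#' @param aln an [msa_alignment()] or [combined_msa()]; for a combined MSA
#'   all rows are used, so pass a paired-only alignment to measure paired
#'   depth.
#' @param identity_threshold clustering identity threshold as a fraction.
#' @return Object of class `depth_summary`: list with `n_rows`, `neff`,
#'   `identity_threshold`, `cluster` (per-row cluster index in input
#'   order).
#' @export
neff <- function(aln, identity_threshold = 0.62) {
  rows <- aln$rows
  if (length(rows) == 0L) stop("empty alignment")
  chars <- strsplit(rows, "")
  unglen <- vapply(chars, function(ch) sum(ch != "-"), integer(1))
  ord <- order(-unglen)
  reps <- integer(0)              # indices (into chars) of representatives
  cluster <- integer(length(rows))
  for (i in ord) {
    assigned <- FALSE
    for (k in seq_along(reps)) {
      if (pair_identity(chars[[i]], chars[[reps[k]]]) >=
          identity_threshold - 1e-12) {
        cluster[i] <- k; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  structure(list(n_rows = length(rows), neff = length(reps),
                 identity_threshold = identity_threshold,
                 cluster = cluster),
            class = "depth_summary")
}

#' @export
print.depth_summary <- function(x, ...) {
  cat("depth_summary: Neff", x$neff, "of", x$n_rows, "rows at",
      sprintf("%.0f%%", 100 * x$identity_threshold), "identity\n")
  invisible(x)
}

#' Treat a combined MSA (or a subset of its rows) as a plain alignment
#'
#' @param combined a [combined_msa()].
#' @param origin optional subset of origin tags to keep (e.g. `"paired"`);
#'   the query row is always kept first.
#' @return An [msa_alignment()].
#' @export
as_alignment <- function(combined, origin = NULL) {
  keep <- rep(TRUE, length(combined$rows))
  if (!is.null(origin)) keep <- combined$origin %in% c("query", origin)
  keep[[1]] <- TRUE
  msa_alignment(combined$rows[keep], labels = combined$labels[keep])
}
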