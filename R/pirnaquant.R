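#' Load a piRNA reference
#'
#' Reads piRNA sequences from a FASTA file (or accepts a named character
#' vector), uppercases them and normalizes U to T. Databases of the
#' piRNABank kind carry many identifiers sharing one sequence; the reference
#' therefore also indexes unique sequences and the sorted identifiers that
#' share each one, so a read is never counted more than once across
#' duplicate database entries.
#'
#' @param x FASTA path or named character vector of sequences.
#' @return an object of class \code{pirna_reference}: list with
#'   \code{sequences} (id -> normalized sequence) and \code{seq_ids}
#'   (unique sequence -> sorted character vector of identifiers).
#' @export
pirna_reference <- function(x) {
  if (is.character(x) && is.null(names(x)) && length(x) == 1 && file.exists(x)) {
    ss <- Biostrings::readBStringSet(x)
    x <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("reference identifiers must be unique and non-empty", call. = FALSE)
  seqs <- chartr("u", "t", toupper(x))
  seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) == 0))
    stop("reference contains an empty sequence", call. = FALSE)
  if (any(grepl("[^ACGT]", seqs)))
    stop("reference sequences may contain only A/C/G/T/U", call. = FALSE)
  seq_ids <- lapply(split(names(seqs), seqs), sort)
  structure(list(sequences = seqs, seq_ids = seq_ids),
            class = "pirna_reference")
}

#' @export
print.pirna_reference <- function(x, ...) {
  cat(sprintf("piRNA reference: %d identifiers, %d unique sequences\n",
              length(x$sequences), length(x$seq_ids)))
  invisible(x)
}

#' Trim adapters and extract UMIs from raw reads
#'
#' Locates the leftmost exact occurrence of the 3' adapter in each read;
#' the insert is everything before it and the UMI is the \code{umi_len}
#' bases immediately after it. Reads without the adapter, or with fewer than
#' \code{umi_len} bases after it, fail extraction (flagged, never an error).
#'
#' @param reads character vector of raw read sequences.
#' @param adapter non-empty adapter sequence.
#' @param umi_len UMI length (>= 1).
#' @return data.frame with columns \code{raw}, \code{insert}, \code{umi},
#'   \code{extracted}; \code{insert}/\code{umi} are NA where extraction
#'   failed.
#' @export
trim_and_extract <- function(reads, adapter, umi_len = 12) {
  if (!nzchar(adapter)) stop("adapter must be non-empty", call. = FALSE)
  pos <- regexpr(adapter, reads, fixed = TRUE)
  alen <- nchar(adapter)
  ok <- pos > 0 & nchar(reads) >= pos + alen - 1 + umi_len
  insert <- ifelse(ok, substr(reads, 1, pos - 1), NA_character_)
  umi <- ifelse(ok, substr(reads, pos + alen, pos + alen + umi_len - 1),
                NA_character_)
  data.frame(raw = reads, insert = insert, umi = umi, extracted = ok,
             stringsAsFactors = FALSE)
}

#' piRNA-insert length filter
#'
#' Keeps inserts in the piRNA size range, 24-34 nt inclusive by default.
#'
#' @param insert character vector of insert sequences.
#' @param min_len,max_len inclusive length bounds.
#' @return logical vector; NA inserts fail.
#' @export
length_filter <- function(insert, min_len = 24, max_len = 34) {
  len <- nchar(insert)
  !is.na(len) & len >= min_len & len <= max_len
}

#' Exact full-length matching against the reference
#'
#' A read is assigned only when its insert equals a reference sequence
#' character-for-character and length-for-length (after U->T
#' normalization); one substitution, truncation or any non-ACGT base (such
#' as N) means no match. No reverse-complement matching is attempted: the
#' library protocol is stranded.
#'
#' @param insert character vector of insert sequences.
#' @param reference a [pirna_reference()].
#' @return character vector of matched unique reference sequences
#'   (NA = no match).
#' @export
exact_match <- function(insert, reference) {
  stopifnot(inherits(reference, "pirna_reference"))
  norm <- chartr("U", "T", toupper(insert))
  hit <- norm %in% names(reference$seq_ids)
  ifelse(hit, norm, NA_character_)
}

hamming1 <- function(a, b) {
  # both same length; TRUE if exactly one mismatch
  sum(utf8ToInt(a) != utf8ToInt(b)) == 1L
}

#' Directional UMI deduplication
#'
#' Collapses PCR duplicates within one sequence group using the directional
#' network rule: a directed edge runs from UMI a to UMI b when their Hamming
#' distance is 1 and count(a) >= 2*count(b) - 1. Cluster roots are found by
#' visiting UMIs in order of decreasing count (ties broken lexicographically)
#' and absorbing everything reachable along directed edges; the molecule
#' count is the number of roots. With no edges this equals the number of
#' distinct UMIs.
#'
#' @param umis character vector of UMIs (one element per read) of equal
#'   length.
#' @param method \code{"directional"} (default) or \code{"unique"} (count
#'   distinct UMIs, no collapsing).
#' @return integer molecule count.
#' @export
umi_dedup <- function(umis, method = c("directional", "unique")) {
  method <- match.arg(method)
  if (length(umis) == 0) return(0L)
  if (length(unique(nchar(umis))) != 1)
    stop("mixed UMI lengths within one sequence group", call. = FALSE)
  tab <- table(umis)
  u <- names(tab)
  cnt <- as.integer(tab)
  if (method == "unique" || length(u) == 1) return(length(u))
  ord <- order(-cnt, u)
  u <- u[ord]; cnt <- cnt[ord]
  m <- length(u)
  ## adjacency: edge i -> j if hamming == 1 and cnt[i] >= 2*cnt[j] - 1
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (hamming1(u[i], u[j])) {
        if (cnt[i] >= 2L * cnt[j] - 1L) adj[i, j] <- TRUE
        if (cnt[j] >= 2L * cnt[i] - 1L) adj[j, i] <- TRUE
      }
    }
  }
  visited <- rep(FALSE, m)
  roots <- 0L
  for (i in seq_len(m)) {
    if (visited[i]) next
    roots <- roots + 1L
    ## absorb everything reachable along directed edges; traversal may pass
    ## through nodes claimed by an earlier root (they stay with that root,
    ## but nodes beyond them are still absorbed, never re-rooted)
    seen <- rep(FALSE, m)
    queue <- i
    seen[i] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    visited <- visited | seen
  }
  roots
}

#' Read a FASTQ file as a character vector of sequences
#'
#' Minimal strict 4-line-record reader (plain or gzip) that reports the
#' index of the first malformed record.
#'
#' @param path FASTQ path.
#' @return character vector of read sequences (names = read ids).
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0) return(stats::setNames(character(0), character(0)))
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: truncated record ", length(lines) %/% 4 + 1,
         call. = FALSE)
  n <- length(lines) / 4
  hd <- lines[seq(1, length(lines), 4)]
  sq <- lines[seq(2, length(lines), 4)]
  pl <- lines[seq(3, length(lines), 4)]
  ql <- lines[seq(4, length(lines), 4)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+") |
                 nchar(sq) != nchar(ql))[1]
  if (!is.na(bad))
    stop("malformed FASTQ: record ", bad, call. = FALSE)
  stats::setNames(sq, sub("\\s.*$", "", sub("^@", "", hd)))
}

#' Quantify piRNAs from a small-RNA FASTQ
#'
#' Runs the full quantification chain: adapter trimming with UMI extraction,
#' 24-34 nt insert length filter, exact full-length matching to the piRNA
#' reference, and UMI deduplication per unique reference sequence. Counts
#' are keyed by unique sequence; all identifiers sharing that sequence are
#' reported, with the lexicographically smallest as representative.
#'
#' @param fastq FASTQ path (plain or gzip).
#' @param reference a [pirna_reference()] or FASTA path.
#' @param adapter 3' adapter sequence.
#' @param umi_len UMI length.
#' @param min_len,max_len inclusive insert length bounds.
#' @param dedup_method \code{"directional"} or \code{"unique"}.
#' @return an object of class \code{pirna_counts}: list with \code{counts}
#'   (data.frame: representative_id, all_ids, sequence, raw_count,
#'   dedup_count) and \code{attrition} (data.frame: stage, reads — input,
#'   extracted, length_pass, matched, deduplicated).
#' @export
quantify_pirnas <- function(fastq, reference,
                            adapter = "AACTGTAGGCACCATCAAT", umi_len = 12,
                            min_len = 24, max_len = 34,
                            dedup_method = "directional") {
  if (!inherits(reference, "pirna_reference"))
    reference <- pirna_reference(reference)
  raw <- read_fastq(fastq)
  tr <- trim_and_extract(unname(raw), adapter, umi_len)
  keep_len <- tr$extracted & length_filter(tr$insert, min_len, max_len)
  matched_seq <- rep(NA_character_, nrow(tr))
  matched_seq[keep_len] <- exact_match(tr$insert[keep_len], reference)
  is_match <- !is.na(matched_seq)

  groups <- split(tr$umi[is_match], matched_seq[is_match])
  counts <- data.frame(
    sequence = names(groups),
    raw_count = vapply(groups, length, integer(1)),
    dedup_count = vapply(groups, umi_dedup, integer(1),
                         method = dedup_method),
    stringsAsFactors = FALSE, row.names = NULL)
  ids <- reference$seq_ids[counts$sequence]
  counts$representative_id <- vapply(ids, `[`, character(1), 1)
  counts$all_ids <- vapply(ids, paste, character(1), collapse = ",")
  counts <- counts[order(counts$representative_id),
                   c("representative_id", "all_ids", "sequence",
                     "raw_count", "dedup_count")]
  rownames(counts) <- NULL

  attrition <- data.frame(
    stage = c("input", "extracted", "length_pass", "matched", "deduplicated"),
    reads = c(length(raw), sum(tr$extracted), sum(keep_len), sum(is_match),
              sum(counts$dedup_count)),
    stringsAsFactors = FALSE)
  structure(list(counts = counts, attrition = attrition),
            class = "pirna_counts")
}

#' @export
print.pirna_counts <- function(x, ...) {
  cat("piRNA quantification\n")
  for (i in seq_len(nrow(x$attrition)))
    cat(sprintf("  %-12s %d\n", x$attrition$stage[i], x$attrition$reads[i]))
  cat(sprintf("  unique sequences: %d\n", nrow(x$counts)))
  invisible(x)
}

#' Write quantification results as TSV
#' @param x a \code{pirna_counts} object.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_pirna_counts <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "pirna_quant.tsv"),
             attrition = file.path(dir, "pirna_attrition.tsv"))
  utils::write.table(x$counts, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$attrition, paths["attrition"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
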