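#' Labelled nucleotide alignment
#'
#' Container for equal-length aligned nucleotide sequences with unique labels
#' and optional per-sequence population assignments. Characters are restricted
#' to A, C, G, T, N and the gap `-`.
#'
#' @param sequences character matrix (rows = sequences, columns = sites) or a
#'   character vector of equal-length strings.
#' @param labels unique sequence identifiers; defaults to existing rownames.
#' @param populations optional population label per sequence.
#' @return an object of class `alignment` with fields `sequences` (character
#'   matrix), `labels`, `populations`.
#' @export
alignment <- function(sequences, labels = NULL, populations = NULL) {
  if (is.character(sequences) && is.null(dim(sequences))) {
    L <- unique(nchar(sequences))
    if (length(L) != 1L) stop_invalid("sequences have unequal lengths")
    sequences <- do.call(rbind, strsplit(toupper(sequences), ""))
  }
  stopifnot(is.matrix(sequences))
  sequences <- toupper(sequences)
  if (ncol(sequences) < 1L) stop_invalid("alignment has zero length")
  bad <- !(sequences %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad)) {
    w <- which(bad)[1L]
    stop_invalid("illegal character '%s' in sequence %d at site %d",
                 sequences[w], (w - 1L) %% nrow(sequences) + 1L,
                 (w - 1L) %/% nrow(sequences) + 1L)
  }
  if (is.null(labels)) labels <- rownames(sequences)
  if (is.null(labels)) labels <- paste0("s", seq_len(nrow(sequences)))
  if (anyDuplicated(labels)) stop_invalid("duplicate sequence labels")
  stopifnot(length(labels) == nrow(sequences))
  rownames(sequences) <- labels
  if (!is.null(populations)) stopifnot(length(populations) == nrow(sequences))
  structure(list(sequences = sequences, labels = labels,
                 populations = populations),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d sites\n",
              nrow(x$sequences), ncol(x$sequences)))
  if (!is.null(x$populations))
    print(table(x$populations))
  invisible(x)
}

#' Number of sequences / sites
#' @param aln an [alignment()].
#' @return integer count.
#' @export
n_sequences <- function(aln) nrow(aln$sequences)

#' @rdname n_sequences
#' @export
n_sites <- function(aln) ncol(aln$sequences)

#' Subset an alignment to one or more populations
#' @param aln an [alignment()].
#' @param pops population labels to keep.
#' @return an [alignment()].
#' @export
subset_population <- function(aln, pops) {
  if (is.null(aln$populations)) stop_invalid("alignment has no populations")
  keep <- aln$populations %in% pops
  if (!any(keep)) stop_invalid("no sequences in population(s) %s",
                               paste(pops, collapse = ","))
  alignment(aln$sequences[keep, , drop = FALSE], aln$labels[keep],
            aln$populations[keep])
}

## columns usable under the missing-data policy
.usable_sites <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  if (policy == "pairwise") return(seq_len(ncol(aln$sequences)))
  ok <- colSums(aln$sequences == "N" | aln$sequences == "-") == 0
  which(ok)
}

#' Read an aligned FASTA file
#'
#' Sequences are upper-cased and validated against the A/C/G/T/N/- alphabet;
#' unequal record lengths or illegal characters raise a format error naming
#' the offending record and position.
#'
#' @param path FASTA file path.
#' @return an [alignment()] (populations unset).
#' @export
read_fasta <- function(path) {
  ## parsed line by line rather than through a DNAbin reader: validation
  ## must see the raw characters (DNAbin coercion silently drops symbols
  ## outside the IUPAC alphabet, losing the record/column diagnostics)
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop_invalid("no sequences in %s", path)
  labels <- sub("^>\\s*", "", lines[hdr])
  labels <- sub("\\s.*$", "", labels)
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste(gsub("\\s", "", lines[(hdr[i] + 1L):ends[i]]), collapse = "")
  }, "")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (any(lens == 0)) stop_invalid("empty record '%s' in %s",
                                   labels[which(lens == 0)[1L]], path)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1L])[1L]
    stop_invalid("ragged alignment in %s: record '%s' has %d sites, expected %d",
                 path, labels[off], lens[off], lens[1L])
  }
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN-]", seqs[i])
    if (bad > 0)
      stop_invalid("illegal character '%s' in record '%s' at column %d",
                   substr(seqs[i], bad, bad), labels[i], bad)
  }
  alignment(seqs, labels = labels)
}

#' Write an alignment as wrapped FASTA
#'
#' @param aln an [alignment()].
#' @param path output file path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln$sequences))) {
    writeLines(paste0(">", aln$labels[i]), con)
    s <- paste(aln$sequences[i, ], collapse = "")
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a label-to-population map
#'
#' Two-column TSV (label, population), header optional (detected when the
#' first line's second field is literally "population").
#'
#' @param path TSV path.
#' @param aln optional [alignment()]; if given, every alignment label must be
#'   mapped (unmapped labels are an error, extra map rows a warning).
#' @return named character vector label -> population.
#' @export
read_population_map <- function(path, aln = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop_invalid("population map needs 2 columns")
  if (tolower(tab[1, 2]) == "population") tab <- tab[-1, , drop = FALSE]
  if (anyDuplicated(tab[[1]]))
    stop_invalid("duplicate labels in population map: %s",
                 paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ","))
  map <- stats::setNames(tab[[2]], tab[[1]])
  if (!is.null(aln)) {
    missing <- setdiff(aln$labels, names(map))
    if (length(missing))
      stop_invalid("unmapped alignment labels: %s",
                   paste(missing, collapse = ","))
    extra <- setdiff(names(map), aln$labels)
    if (length(extra))
      warning(sprintf("%d map entries not in alignment (ignored)",
                      length(extra)))
    map <- map[aln$labels]
  }
  map
}

#' Attach populations from a map file
#' @param aln an [alignment()].
#' @param path population map TSV path.
#' @return the alignment with populations set.
#' @export
assign_populations <- function(aln, path) {
  map <- read_population_map(path, aln)
  aln$populations <- unname(map[aln$labels])
  aln
}
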