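# Alignment container and I/O (Stockholm 1.0, aligned FASTA).
#
# Sequences are stored as an integer matrix with codes 0 = gap, 1 = A,
# 2 = C, 3 = G, 4 = U.  T is normalized to U, lowercase is folded to upper,
# the gap characters '-', '.', '_', '~' are all normalized to '-', and IUPAC
# ambiguity codes are treated as missing (gap) for all counting statistics,
# which are defined on {A,C,G,U} only.

RNA_STATES <- c("-", "A", "C", "G", "U")
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "X")
GAP_CHARS <- c("-", ".", "_", "~")

#' Construct an RNA alignment object
#'
#' Low-level constructor.  Most users will call [read_alignment()] instead.
#'
#' @param seqs character vector of aligned sequences (equal length).
#' @param names sequence identifiers, unique, same length as `seqs`.
#' @param structure optional consensus structure: either a WUSS string of
#'   alignment length or a data frame with columns `i`, `j` (1-based,
#'   `i < j`).
#' @return An object of class `rna_alignment` with elements `mat` (S x L
#'   integer matrix, 0 = gap, 1:4 = A,C,G,U), `names`, and `structure`
#'   (a data frame with columns `i`, `j`, `pseudoknot`, `short_range`, or
#'   `NULL`).
#' @export
rna_alignment <- function(seqs, names = NULL, structure = NULL) {
  if (is.null(names)) names <- paste0("seq", seq_along(seqs))
  if (length(names) != length(seqs))
    stop("`names` and `seqs` lengths differ")
  if (anyDuplicated(names))
    stop("duplicate sequence names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
  mat <- encode_seqs(seqs)
  rownames(mat) <- names
  if (is.character(structure)) {
    if (nchar(structure) != ncol(mat))
      stop("structure string length != alignment length")
    structure <- parse_wuss(structure)
  }
  if (!is.null(structure)) validate_structure(structure, ncol(mat))
  out <- list(mat = mat, names = names, structure = structure)
  class(out) <- "rna_alignment"
  out
}

# character sequences -> integer matrix
encode_seqs <- function(seqs) {
  chars <- toupper(do.call(rbind, strsplit(seqs, "", fixed = TRUE)))
  chars[chars == "T"] <- "U"
  chars[chars %in% GAP_CHARS] <- "-"
  chars[chars %in% IUPAC_AMBIG] <- "-"
  bad <- setdiff(unique(as.vector(chars)), RNA_STATES)
  if (length(bad))
    stop("unknown characters in alignment: ", paste(bad, collapse = " "))
  mat <- match(chars, RNA_STATES) - 1L
  dim(mat) <- dim(chars)
  mat
}

decode_row <- function(x) paste(RNA_STATES[x + 1L], collapse = "")

validate_structure <- function(structure, L) {
  stopifnot(all(c("i", "j") %in% names(structure)))
  if (nrow(structure)) {
    if (any(structure$i >= structure$j)) stop("structure pairs need i < j")
    if (any(structure$j > L) || any(structure$i < 1L))
      stop("structure pair out of alignment bounds")
    cols <- c(structure$i, structure$j)
    if (anyDuplicated(cols))
      stop("column participates in more than one pair")
  }
  invisible(structure)
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat(sprintf("RNA alignment: %d sequences x %d columns\n",
              n_seq(x), n_col(x)))
  if (!is.null(x$structure))
    cat(sprintf("  consensus structure: %d pairs (%d pseudoknot, %d short-range)\n",
                nrow(x$structure), sum(x$structure$pseudoknot),
                sum(x$structure$short_range)))
  invisible(x)
}

#' Number of sequences / columns in an alignment
#' @param aln an `rna_alignment`.
#' @return integer scalar.
#' @export
n_seq <- function(aln) nrow(aln$mat)

#' @rdname n_seq
#' @export
n_col <- function(aln) ncol(aln$mat)

#' @export
as.character.rna_alignment <- function(x, ...) {
  out <- apply(x$mat, 1L, decode_row)
  names(out) <- x$names
  out
}

#' Read a multiple sequence alignment
#'
#' Reads Stockholm 1.0 (including the `#=GC SS_cons` consensus structure
#' line, parsed as WUSS) or aligned FASTA.  Validation and normalization are
#' as in [rna_alignment()].
#'
#' @param path file path.
#' @param format `"auto"` (sniff first non-blank line), `"stockholm"`, or
#'   `"afa"`.
#' @return An `rna_alignment`.
#' @export
read_alignment <- function(path, format = c("auto", "stockholm", "afa")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    if (!length(first)) stop("empty alignment file: ", path)
    format <- if (startsWith(first[1], "# STOCKHOLM")) "stockholm" else "afa"
  }
  switch(format,
         stockholm = read_stockholm(path),
         afa = read_afa(path))
}

read_afa <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  nm <- sub("\\s.*$", "", names(set))
  rna_alignment(unname(seqs), names = nm)
}

read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqs <- character(0)
  ss <- ""
  order <- character(0)
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "//")) break
    if (startsWith(ln, "#")) {
      if (startsWith(ln, "#=GC SS_cons")) {
        ss <- paste0(ss, trimws(sub("^#=GC SS_cons", "", ln)))
      }
      next
    }
    fields <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(fields) != 2L)
      stop("malformed Stockholm sequence line: ", ln)
    nm <- fields[1]
    if (!nm %in% order) {
      order <- c(order, nm)
      seqs[nm] <- fields[2]
    } else {
      seqs[nm] <- paste0(seqs[nm], fields[2])  # interleaved blocks
    }
  }
  if (!length(seqs)) stop("no sequences found in ", path)
  structure <- if (nzchar(ss)) ss else NULL
  rna_alignment(unname(seqs[order]), names = order, structure = structure)
}

#' Write an alignment
#'
#' Stockholm output includes the consensus structure as `#=GC SS_cons`
#' (regenerated in WUSS notation) and any provenance strings attached to the
#' alignment as `#=GF` comment lines.
#'
#' @param aln an `rna_alignment`.
#' @param path output file path.
#' @param format `"stockholm"` or `"afa"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("stockholm", "afa")) {
  format <- match.arg(format)
  seqs <- as.character(aln)
  if (format == "afa") {
    out <- as.vector(rbind(paste0(">", aln$names), unname(seqs)))
    writeLines(out, path)
    return(invisible(path))
  }
  out <- c("# STOCKHOLM 1.0")
  prov <- attr(aln, "provenance")
  if (!is.null(prov))
    out <- c(out, paste("#=GF CC", prov))
  width <- max(nchar(aln$names), 12L) + 2L
  out <- c(out, sprintf(paste0("%-", width, "s%s"), aln$names, unname(seqs)))
  if (!is.null(aln$structure))
    out <- c(out, sprintf(paste0("%-", width, "s%s"), "#=GC SS_cons",
                          write_wuss(aln$structure, n_col(aln))))
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Average pairwise sequence identity
#'
#' Mean over all sequence pairs of the fraction of identical residues among
#' columns where both sequences carry a residue.  Pairs with no jointly
#' occupied column are excluded with a warning.
#'
#' @param aln an `rna_alignment` with at least two sequences.
#' @return fraction in \[0, 1\].
#' @export
average_pairwise_identity <- function(aln) {
  S <- n_seq(aln)
  if (S < 2L) stop("need at least 2 sequences")
  m <- aln$mat
  ids <- numeric(0)
  dropped <- 0L
  for (s in seq_len(S - 1L)) {
    for (t in (s + 1L):S) {
      both <- m[s, ] > 0L & m[t, ] > 0L
      nb <- sum(both)
      if (nb == 0L) { dropped <- dropped + 1L; next }
      ids <- c(ids, sum(m[s, both] == m[t, both]) / nb)
    }
  }
  if (dropped > 0L)
    warning(dropped, " sequence pair(s) with no jointly occupied columns excluded")
  if (!length(ids)) stop("no sequence pair with jointly occupied columns")
  mean(ids)
}

#' Per-column residue counts and occupancy
#'
#' @param aln an `rna_alignment`.
#' @return A list with `counts` (L x 4 matrix of A,C,G,U counts), `gaps`
#'   (length-L gap counts) and `occupancy` (fraction of rows with a
#'   residue).  `counts[i, ] + gaps[i]` sums to the number of sequences for
#'   every column.
#' @export
column_profiles <- function(aln) {
  m <- aln$mat
  counts <- vapply(1:4, function(a) colSums(m == a), numeric(ncol(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  colnames(counts) <- RNA_STATES[2:5]
  gaps <- colSums(m == 0L)
  list(counts = counts, gaps = gaps,
       occupancy = 1 - gaps / nrow(m))
}

#' Joint residue counts for one column pair
#'
#' Counts are over the 16 residue pairs, restricted to rows carrying a
#' residue at both columns (the convention of the pairwise statistics).
#'
#' @param aln an `rna_alignment`.
#' @param i,j column indices (1-based).
#' @return 4 x 4 matrix of counts; rows index the residue at `i`, columns
#'   the residue at `j`.
#' @export
pair_counts <- function(aln, i, j) {
  m <- aln$mat
  keep <- m[, i] > 0L & m[, j] > 0L
  tab <- matrix(0L, 4L, 4L, dimnames = list(RNA_STATES[2:5], RNA_STATES[2:5]))
  if (any(keep)) {
    t0 <- table(factor(m[keep, i], levels = 1:4),
                factor(m[keep, j], levels = 1:4))
    tab[] <- as.integer(t0)
  }
  tab
}
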