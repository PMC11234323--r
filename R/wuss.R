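# WUSS consensus-structure notation.
#
# All bracket alphabets are accepted: <>, (), [], {} for nested pairs, and
# Aa, Bb, ... letter pairs for pseudoknots.  Letter pairs are stored but
# always flagged as pseudoknots.  Watson-Crick-intended pairs closer than
# four columns (j - i <= 3) are accepted but flagged `short_range`, since
# genuine helical pairs must be separated by at least three unpaired
# nucleotides.

WUSS_OPEN <- c("<", "(", "[", "{")
WUSS_CLOSE <- c(">", ")", "]", "}")

#' Parse a WUSS consensus structure string
#'
#' @param ss a WUSS string, one character per alignment column.
#' @return data frame with columns `i`, `j` (1-based, `i < j`),
#'   `pseudoknot` (letter-annotated pair) and `short_range`
#'   (`j - i <= 3`).  Short-range pairs trigger a warning.
#' @export
parse_wuss <- function(ss) {
  chars <- strsplit(ss, "", fixed = TRUE)[[1]]
  stacks <- list()
  pairs_i <- integer(0); pairs_j <- integer(0); pk <- logical(0)
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    if (ch %in% WUSS_OPEN) {
      key <- ch
      stacks[[key]] <- c(stacks[[key]], pos)
    } else if (ch %in% WUSS_CLOSE) {
      key <- WUSS_OPEN[match(ch, WUSS_CLOSE)]
      st <- stacks[[key]]
      if (!length(st)) stop("unbalanced '", ch, "' at column ", pos)
      pairs_i <- c(pairs_i, st[length(st)])
      pairs_j <- c(pairs_j, pos)
      pk <- c(pk, FALSE)
      stacks[[key]] <- st[-length(st)]
    } else if (grepl("^[A-Z]$", ch)) {
      stacks[[ch]] <- c(stacks[[ch]], pos)
    } else if (grepl("^[a-z]$", ch)) {
      key <- toupper(ch)
      st <- stacks[[key]]
      if (!length(st)) stop("unbalanced pseudoknot '", ch, "' at column ", pos)
      pairs_i <- c(pairs_i, st[length(st)])
      pairs_j <- c(pairs_j, pos)
      pk <- c(pk, TRUE)
      stacks[[key]] <- st[-length(st)]
    }
    # all other characters (.,:_-~ etc.) are unpaired annotation
  }
  left <- vapply(stacks, length, integer(1))
  if (length(left) && any(left > 0L))
    stop("unbalanced structure: unclosed ",
         paste(names(stacks)[left > 0L], collapse = " "))
  ord <- order(pairs_i)
  out <- data.frame(i = pairs_i[ord], j = pairs_j[ord],
                    pseudoknot = pk[ord],
                    short_range = (pairs_j - pairs_i)[ord] <= 3L)
  if (any(out$short_range))
    warning(sum(out$short_range),
            " pair(s) at separation <= 3 columns flagged short_range")
  out
}

#' Render a pair table as a WUSS string
#'
#' Nested pairs are written with `<>`; pseudoknot pairs with successive
#' letter alphabets.
#'
#' @param pairs data frame with columns `i`, `j` and optionally
#'   `pseudoknot`.
#' @param L alignment length.
#' @return single WUSS string of length `L`.
#' @export
write_wuss <- function(pairs, L) {
  out <- rep(".", L)
  if (is.null(pairs$pseudoknot)) pairs$pseudoknot <- FALSE
  nested <- pairs[!pairs$pseudoknot, , drop = FALSE]
  out[nested$i] <- "<"
  out[nested$j] <- ">"
  pkp <- pairs[pairs$pseudoknot, , drop = FALSE]
  if (nrow(pkp)) {
    layer <- LETTERS[(seq_len(nrow(pkp)) - 1L) %% 26L + 1L]
    out[pkp$i] <- layer
    out[pkp$j] <- tolower(layer)
  }
  paste(out, collapse = "")
}
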