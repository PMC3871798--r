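#' Parse a Vienna dot-bracket record
#'
#' Reads a FASTA-like record: an optional `>` header line, one sequence
#' line, and one dot-bracket line of the same length. Only `.`, `(` and `)`
#' are accepted in the structure line: fixed structures are non-crossing by
#' definition, so extended pseudoknot bracket dialects are rejected loudly
#' rather than silently flattened.
#'
#' @param text Character vector of lines, or a single string containing
#'   newlines.
#' @return A validated [structured_rna] with relations built.
#' @examples
#' parse_vienna(c(">hp", "GGAAACC", "((...))"))
#' @export
parse_vienna <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty Vienna record")
  id <- "rna"
  if (startsWith(lines[1L], ">")) {
    id <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  if (length(lines) < 2L) stop("Vienna record needs a sequence line and a structure line")
  seq <- lines[1L]
  db <- lines[2L]
  if (nchar(db) != nchar(seq)) {
    stop(sprintf("structure line length (%d) does not match sequence length (%d)",
                 nchar(db), nchar(seq)))
  }
  pairs <- dotbracket_pairs(db)
  structured_rna(seq, pairs, id = id)
}

dotbracket_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  bad <- setdiff(unique(chars), c(".", "(", ")"))
  if (length(bad)) {
    stop("unsupported structure character(s): ", paste(bad, collapse = " "),
         " (only '.', '(' and ')' are accepted)")
  }
  stack <- integer(0)
  left <- integer(0); right <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      left <- c(left, j); right <- c(right, i)
    }
  }
  if (length(stack)) stop("unbalanced '(' at position ", stack[1L])
  cbind(left = left, right = right)
}

#' Read Vienna dot-bracket records from a file
#'
#' @param path File with one or more records (`>id` / sequence / structure).
#' @return A list of [structured_rna], one per record.
#' @export
read_vienna <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) starts <- 1L
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(k) parse_vienna(lines[starts[k]:ends[k]]))
}

#' Serialise a structure as a Vienna record
#'
#' @param s A [structured_rna].
#' @param path Optional file; when `NULL` the lines are returned.
#' @return Character vector of the three record lines, invisibly when
#'   written to a file.
#' @export
write_vienna <- function(s, path = NULL) {
  out <- c(paste0(">", s$id), s$seq, as_dotbracket(s))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read a bpseq file
#'
#' bpseq rows are `position nucleotide partner`, 1-based, with partner 0 for
#' unpaired positions. Each pair must be annotated consistently from both
#' ends.
#'
#' @param path File path.
#' @param id Label for the molecule (defaults to the file name).
#' @return A validated [structured_rna].
#' @export
read_bpseq <- function(path, id = NULL) {
  tab <- utils::read.table(path, col.names = c("pos", "nt", "partner"),
                           colClasses = c("integer", "character", "integer"))
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  l <- nrow(tab)
  if (!identical(tab$pos, seq_len(l))) stop("bpseq positions must be 1..", l, " in order")
  if (any(tab$partner < 0L | tab$partner > l)) stop("bpseq partner index out of range")
  paired <- which(tab$partner > 0L)
  for (i in paired) {
    if (tab$partner[tab$partner[i]] != i) {
      stop("inconsistent bpseq pairing at position ", i)
    }
    if (tab$partner[i] == i) stop("position ", i, " paired with itself")
  }
  keep <- paired[tab$pos[paired] < tab$partner[paired]]
  pairs <- if (length(keep)) cbind(tab$pos[keep], tab$partner[keep]) else NULL
  structured_rna(paste(tab$nt, collapse = ""), pairs, id = id)
}

#' Write an alignment in Stockholm 1.0 format
#'
#' One row per sequence plus a `#=GR ... SS` line carrying the gapped
#' structure annotation: pairs matched in the alignment are written as
#' brackets, broken pairs as dots.
#'
#' @param a An [rna_alignment] (see [align_structures]).
#' @param path Optional output file.
#' @return The Stockholm lines (invisibly when written to a file).
#' @export
write_stockholm <- function(a, path = NULL) {
  stopifnot(inherits(a, "rna_alignment"))
  out <- c("# STOCKHOLM 1.0")
  if (nchar(a$aligned_a) > 0L || nchar(a$aligned_b) > 0L) {
    if (nchar(a$aligned_a) != nchar(a$aligned_b)) {
      stop("internal error: gapped rows of unequal length")
    }
    nm <- format(c(a$id_a, paste("#=GR", a$id_a, "SS"),
                   a$id_b, paste("#=GR", a$id_b, "SS")))
    out <- c(out,
             paste(nm[1L], a$aligned_a),
             paste(nm[2L], a$structure_a),
             paste(nm[3L], a$aligned_b),
             paste(nm[4L], a$structure_b))
  }
  out <- c(out, "//")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read a Stockholm alignment written by [write_stockholm]
#'
#' @param path File path or character vector of lines.
#' @return A list with `names`, `seqs` (gapped rows) and `ss` (gapped
#'   structure annotations), each keyed by sequence name.
#' @export
read_stockholm <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  if (!length(lines) || lines[1L] != "# STOCKHOLM 1.0") stop("not a Stockholm 1.0 file")
  seqs <- character(0); ss <- character(0)
  for (ln in lines[-1L]) {
    if (ln == "//" || !nzchar(ln)) next
    if (startsWith(ln, "#=GR")) {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) >= 4L && f[3L] == "SS") ss[f[2L]] <- f[4L]
    } else if (!startsWith(ln, "#")) {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) >= 2L) seqs[f[1L]] <- f[2L]
    }
  }
  list(names = names(seqs), seqs = seqs, ss = ss)
}
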